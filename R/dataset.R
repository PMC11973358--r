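# Directory-per-class image dataset loading.

#' Load a directory-per-class image dataset
#'
#' Expects `root/<class>/*.png`; class indices follow the sorted class
#' directory names.
#'
#' @param root dataset root directory.
#' @param preprocess optional [preprocess_config()]; when given, every
#'   image is run through [preprocess_image()].
#' @return list with `images`, `labels` (0-based), `paths`,
#'   `class_names`.
#' @export
load_image_dataset <- function(root, preprocess = NULL) {
  if (!dir.exists(root)) stopf("no such dataset directory: '%s'", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stopf("'%s' has no class subdirectories", root)
  imgs <- list(); labels <- integer(); paths <- character()
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[k]), pattern = "\\.png$",
                             full.names = TRUE))
    for (f in files) {
      im <- read_image(f)
      if (!is.null(preprocess)) im <- preprocess_image(im, preprocess)
      imgs[[length(imgs) + 1L]] <- im
      labels <- c(labels, k - 1L)
      paths <- c(paths, normalizePath(f))
    }
  }
  list(images = imgs, labels = labels, paths = paths, class_names = classes)
}
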