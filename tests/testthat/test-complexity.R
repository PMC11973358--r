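# Analytic complexity accounting: single-layer formulas, the published
# four-row table, oracle equivalence, monotonicity.

test_that("single-layer formulas match closed forms", {
  row <- sparcnet:::new_descr_row("conv", 64L, 64L, 3L, 3L, 1L,
                                  in_h = 56, in_w = 56, out_h = 56, out_w = 56)
  expect_equal(sparcnet:::layer_params(row), 36864)
  expect_equal(sparcnet:::layer_flops(row), 231211008)  # 2 * 36,864 * 3,136
})

test_that("the four variant configurations reproduce the published table", {
  tab <- complexity_table(calibrated_configs())
  expect_equal(tab$Model, c("Baseline", "ResCBANet", "ResSPNet", "HTRecNet"))
  # hard rows
  expect_identical(tab[tab$Model == "Baseline", "Params(M)"], 23.51)
  expect_identical(tab[tab$Model == "Baseline", "FLOPs(G)"], 8.22)
  expect_identical(tab[tab$Model == "ResSPNet", "Params(M)"], 16.31)
  expect_identical(tab[tab$Model == "ResSPNet", "FLOPs(G)"], 5.86)
  # CBAM rows: parameters land on the published values at the calibrated
  # reduction ratio
  expect_identical(tab[tab$Model == "ResCBANet", "Params(M)"], 24.46)
  expect_identical(tab[tab$Model == "HTRecNet", "Params(M)"], 17.25)
  # ordering property
  expect_lt(tab[tab$Model == "ResSPNet", "Params(M)"],
            tab[tab$Model == "Baseline", "Params(M)"])

  # empty input -> header only
  empty <- complexity_table(list())
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), c("Model", "Params(M)", "FLOPs(G)"))
})

test_that("calibration selects reduction ratio 42 for the attention variants", {
  cal <- calibrate_cbam_reduction(30:60)
  expect_true(42 %in% cal$calibrated)
})

test_that("analytic counts equal runtime tensor enumeration (oracle equivalence)", {
  # desk-scale variants first (cheap), then spot-check at other widths
  for (v in c("baseline", "res_sp", "res_cba", "htrec")) {
    cfg <- tiny_cfg(v, input_size = 32L, width = 4L, depths = c(2L, 1L, 1L, 2L))
    set.seed(11)
    model <- build_network(cfg)
    expect_identical(count_parameters(describe_network(cfg)),
                     sum(lengths(flatten_params(model))),
                     info = v)
  }
})

test_that("complexity totals are internally consistent and monotone", {
  rep <- complexity_report(arch_config("baseline"))
  expect_equal(sum(rep$layers$params), rep$params)
  expect_equal(rep$params_millions, round(rep$params / 1e6, 2))

  p <- function(v, r = 42L) count_parameters(describe_network(
    arch_config(v, cbam_reduction = r)))
  f <- function(v, r = 42L) count_flops(describe_network(
    arch_config(v, cbam_reduction = r)))
  # adding attention strictly increases both; split convolution strictly
  # decreases both
  expect_gt(p("res_cba"), p("baseline")); expect_gt(f("res_cba"), f("baseline"))
  expect_gt(p("htrec"), p("res_sp"));     expect_gt(f("htrec"), f("res_sp"))
  expect_lt(p("res_sp"), p("baseline"));  expect_lt(f("res_sp"), f("baseline"))
  expect_lt(p("htrec"), p("res_cba"));    expect_lt(f("htrec"), f("res_cba"))

  # removing the head drops exactly 2048*K + K parameters
  d3 <- describe_network(arch_config("baseline", num_classes = 3L))
  d7 <- describe_network(arch_config("baseline", num_classes = 7L))
  expect_equal(count_parameters(d7) - count_parameters(d3), 2048 * 4 + 4)
  headless <- count_parameters(d3) - (2048 * 3 + 3)
  expect_equal(count_parameters(d3) - headless, 2048 * 3 + 3)
})

test_that("count rejects unknown layer kinds", {
  d <- describe_network(tiny_cfg("baseline"))
  d$kind[1] <- "mystery"
  expect_error(count_parameters(d), "unsupported")
})
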