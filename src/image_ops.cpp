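// Pixel-level image operations: bilinear sampling, median filtering,
// separable Gaussian smoothing.  Images are H x W x C double arrays
// (any channel count); coordinates follow the half-pixel convention.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Sample (hf, wf) from one channel plane with replicate edges.
static inline double bilerp(const double* p, int H, int W, double hf, double wf) {
  int h0 = (int)std::floor(hf), w0 = (int)std::floor(wf);
  double dh = hf - h0, dw = wf - w0;
  int h0c = clampi(h0, 0, H - 1), h1c = clampi(h0 + 1, 0, H - 1);
  int w0c = clampi(w0, 0, W - 1), w1c = clampi(w0 + 1, 0, W - 1);
  double v00 = p[h0c + (std::size_t)H * w0c], v01 = p[h0c + (std::size_t)H * w1c];
  double v10 = p[h1c + (std::size_t)H * w0c], v11 = p[h1c + (std::size_t)H * w1c];
  return (1 - dh) * ((1 - dw) * v00 + dw * v01) + dh * ((1 - dw) * v10 + dw * v11);
}

// [[Rcpp::export(rng = false)]]
NumericVector bilinear_resize_cpp(NumericVector img, int out_h, int out_w) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d.size() >= 3 ? d[2] : 1;
  NumericVector out((std::size_t)out_h * out_w * C);
  out.attr("dim") = IntegerVector::create(out_h, out_w, C);
  double sh = (double)H / out_h, sw = (double)W / out_w;
  for (int c = 0; c < C; ++c) {
    const double* p = img.begin() + (std::size_t)c * H * W;
    double* o = out.begin() + (std::size_t)c * out_h * out_w;
    for (int w = 0; w < out_w; ++w) {
      double wf = (w + 0.5) * sw - 0.5;
      for (int h = 0; h < out_h; ++h) {
        double hf = (h + 0.5) * sh - 0.5;
        o[h + (std::size_t)out_h * w] = bilerp(p, H, W, hf, wf);
      }
    }
  }
  return out;
}

// Warp: output(h, w) = input(map_h(h, w), map_w(h, w)); replicate edges.
// [[Rcpp::export(rng = false)]]
NumericVector bilinear_warp_cpp(NumericVector img, NumericMatrix map_h,
                                NumericMatrix map_w) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d.size() >= 3 ? d[2] : 1;
  int Ho = map_h.nrow(), Wo = map_h.ncol();
  NumericVector out((std::size_t)Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* p = img.begin() + (std::size_t)c * H * W;
    double* o = out.begin() + (std::size_t)c * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        o[h + (std::size_t)Ho * w] = bilerp(p, H, W, map_h(h, w), map_w(h, w));
  }
  return out;
}

// k x k median with replicate padding, per channel.
// [[Rcpp::export(rng = false)]]
NumericVector median_filter_cpp(NumericVector img, int k) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d.size() >= 3 ? d[2] : 1;
  int r = k / 2;
  NumericVector out((std::size_t)H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  std::vector<double> buf((std::size_t)k * k);
  for (int c = 0; c < C; ++c) {
    const double* p = img.begin() + (std::size_t)c * H * W;
    double* o = out.begin() + (std::size_t)c * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        std::size_t m = 0;
        for (int dw = -r; dw <= r; ++dw) {
          int wi = clampi(w + dw, 0, W - 1);
          for (int dh = -r; dh <= r; ++dh) {
            int hi = clampi(h + dh, 0, H - 1);
            buf[m++] = p[hi + (std::size_t)H * wi];
          }
        }
        std::size_t mid = m / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + m);
        double med = buf[mid];
        if (m % 2 == 0) {  // even kernel area cannot occur for odd k, kept for safety
          double lo = *std::max_element(buf.begin(), buf.begin() + mid);
          med = 0.5 * (med + lo);
        }
        o[h + (std::size_t)H * w] = med;
      }
    }
  }
  return out;
}

// Separable Gaussian blur of a single-channel matrix, replicate edges.
// [[Rcpp::export(rng = false)]]
NumericMatrix gaussian_blur_cpp(NumericMatrix x, double sigma) {
  int H = x.nrow(), W = x.ncol();
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + r];
  }
  for (double& v : kern) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int w = 0; w < W; ++w)  // vertical pass
    for (int h = 0; h < H; ++h) {
      double a = 0.0;
      for (int i = -r; i <= r; ++i) a += kern[i + r] * x(clampi(h + i, 0, H - 1), w);
      tmp(h, w) = a;
    }
  for (int w = 0; w < W; ++w)  // horizontal pass
    for (int h = 0; h < H; ++h) {
      double a = 0.0;
      for (int i = -r; i <= r; ++i) a += kern[i + r] * tmp(h, clampi(w + i, 0, W - 1));
      out(h, w) = a;
    }
  return out;
}
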