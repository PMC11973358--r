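// Dense kernels for the in-package neural-network engine.
//
// Tensor layout convention (column-major R arrays): dim = c(H, W, C, N),
// i.e. element (h, w, c, n) sits at offset h + H*(w + W*(c + C*n)).
// Convolution weights: dim = c(Kh, Kw, Cin/groups, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather one (sample, group) slab into a column matrix:
// rows = Kh*Kw*Cinpg (kh fastest, then kw, then ci), cols = Ho*Wo (ho fastest).
static void im2col(const double* x, int H, int W, int Cin,
                   int n, int g, int Cinpg,
                   int Kh, int Kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int ci = 0; ci < Cinpg; ++ci) {
    const double* xc = x + (std::size_t)(g * Cinpg + ci + Cin * n) * H * W;
    for (int kw = 0; kw < Kw; ++kw) {
      for (int kh = 0; kh < Kh; ++kh) {
        int row = kh + Kh * (kw + Kw * ci);
        double* dst = col.memptr() + row;  // stride between cols = col.n_rows
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          bool wok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) v = xc[hi + (std::size_t)H * wi];
            dst[(std::size_t)col.n_rows * (ho + Ho * wo)] = v;
          }
        }
      }
    }
  }
}

// Scatter-add the column matrix back onto the input gradient.
static void col2im_add(double* gx, int H, int W, int Cin,
                       int n, int g, int Cinpg,
                       int Kh, int Kw, int stride, int pad,
                       int Ho, int Wo, const arma::mat& col) {
  for (int ci = 0; ci < Cinpg; ++ci) {
    double* xc = gx + (std::size_t)(g * Cinpg + ci + Cin * n) * H * W;
    for (int kw = 0; kw < Kw; ++kw) {
      for (int kh = 0; kh < Kh; ++kh) {
        int row = kh + Kh * (kw + Kw * ci);
        const double* src = col.memptr() + row;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (std::size_t)H * wi] +=
              src[(std::size_t)col.n_rows * (ho + Ho * wo)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Kh = wd[0], Kw = wd[1], Cinpg = wd[2], Cout = wd[3];
  if (Cin != Cinpg * groups) stop("conv2d: input channels incompatible with groups");
  if (Cout % groups != 0) stop("conv2d: output channels not divisible by groups");
  int Coutpg = Cout / groups;
  int Ho = out_extent(H, Kh, stride, pad), Wo = out_extent(W, Kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output spatial size < 1");

  NumericVector out((std::size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  int rows = Kh * Kw * Cinpg;
  arma::mat col(rows, (std::size_t)Ho * Wo);
  const arma::mat Wfull(const_cast<double*>(w.begin()), rows, Cout, false, true);

  const double* bptr = nullptr;
  NumericVector bv;
  if (bias.isNotNull()) { bv = bias.get(); bptr = bv.begin(); }

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, Cin, n, g, Cinpg, Kh, Kw, stride, pad, Ho, Wo, col);
      arma::mat Wg = Wfull.cols(g * Coutpg, (g + 1) * Coutpg - 1);
      arma::mat o = Wg.t() * col;  // Coutpg x (Ho*Wo)
      for (int co = 0; co < Coutpg; ++co) {
        double* dst = out.begin() +
          (std::size_t)(g * Coutpg + co + Cout * n) * Ho * Wo;
        const double* srow = o.memptr() + co;
        double b = bptr ? bptr[g * Coutpg + co] : 0.0;
        for (std::size_t p = 0; p < (std::size_t)Ho * Wo; ++p)
          dst[p] = srow[p * Coutpg] + b;
      }
    }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gout,
                    bool has_bias, int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Kh = wd[0], Kw = wd[1], Cinpg = wd[2], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  int Coutpg = Cout / groups;
  int rows = Kh * Kw * Cinpg;

  NumericVector gx((std::size_t)H * W * Cin * N);
  gx.attr("dim") = xd;
  NumericVector gw((std::size_t)rows * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(has_bias ? Cout : 0);

  arma::mat col(rows, (std::size_t)Ho * Wo);
  arma::mat gcol(rows, (std::size_t)Ho * Wo);
  const arma::mat Wfull(const_cast<double*>(w.begin()), rows, Cout, false, true);
  arma::mat Gw(gw.begin(), rows, Cout, false, true);
  arma::mat go(Coutpg, (std::size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      // gather gout slab as Coutpg x (Ho*Wo)
      for (int co = 0; co < Coutpg; ++co) {
        const double* src = gout.begin() +
          (std::size_t)(g * Coutpg + co + Cout * n) * Ho * Wo;
        double* drow = go.memptr() + co;
        for (std::size_t p = 0; p < (std::size_t)Ho * Wo; ++p)
          drow[p * Coutpg] = src[p];
      }
      im2col(x.begin(), H, W, Cin, n, g, Cinpg, Kh, Kw, stride, pad, Ho, Wo, col);
      Gw.cols(g * Coutpg, (g + 1) * Coutpg - 1) += col * go.t();
      arma::mat Wg = Wfull.cols(g * Coutpg, (g + 1) * Coutpg - 1);
      gcol = Wg * go;
      col2im_add(gx.begin(), H, W, Cin, n, g, Cinpg, Kh, Kw, stride, pad, Ho, Wo, gcol);
      if (has_bias) {
        for (int co = 0; co < Coutpg; ++co) {
          double s = 0.0;
          const double* drow = go.memptr() + co;
          for (std::size_t p = 0; p < (std::size_t)Ho * Wo; ++p)
            s += drow[p * Coutpg];
          gb[g * Coutpg + co] += s;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(rng = false)]]
List maxpool_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_extent(H, k, stride, pad), Wo = out_extent(W, k, stride, pad);
  NumericVector out((std::size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((std::size_t)Ho * Wo * C * N);  // 0-based offset within (H,W) plane
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xp = x.begin() + (std::size_t)cn * H * W;
    double* op = out.begin() + (std::size_t)cn * Ho * Wo;
    int* ip = idx.begin() + (std::size_t)cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -std::numeric_limits<double>::infinity();
        int besti = -1;
        for (int kw = 0; kw < k; ++kw) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            double v = xp[hi + (std::size_t)H * wi];
            if (v > best) { best = v; besti = hi + H * wi; }
          }
        }
        op[ho + (std::size_t)Ho * wo] = best;
        ip[ho + (std::size_t)Ho * wo] = besti;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(rng = false)]]
NumericVector maxpool_bwd_cpp(IntegerVector idx, NumericVector gout,
                              int H, int W) {
  IntegerVector gd = gout.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  NumericVector gx((std::size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* gp = gout.begin() + (std::size_t)cn * Ho * Wo;
    const int* ip = idx.begin() + (std::size_t)cn * Ho * Wo;
    double* xp = gx.begin() + (std::size_t)cn * H * W;
    for (std::size_t p = 0; p < (std::size_t)Ho * Wo; ++p)
      if (ip[p] >= 0) xp[ip[p]] += gp[p];
  }
  return gx;
}

// Max over the spatial extent (dims 1:2) with argmax; returns C x N matrices.
// [[Rcpp::export(rng = false)]]
List spatial_max_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericMatrix out(C, N);
  IntegerMatrix idx(C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (std::size_t)(c + C * n) * H * W;
      double best = xp[0]; int bi = 0;
      for (int p = 1; p < H * W; ++p)
        if (xp[p] > best) { best = xp[p]; bi = p; }
      out(c, n) = best; idx(c, n) = bi;
    }
  }
  return List::create(_["max"] = out, _["idx"] = idx);
}

// Max over channels (dim 3) with argmax; returns (H,W,1,N) array + channel index.
// [[Rcpp::export(rng = false)]]
List channel_max_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector out((std::size_t)H * W * N);
  out.attr("dim") = IntegerVector::create(H, W, 1, N);
  IntegerVector idx((std::size_t)H * W * N);
  idx.attr("dim") = IntegerVector::create(H, W, 1, N);
  std::size_t plane = (std::size_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (std::size_t)n * C * plane;
    double* op = out.begin() + (std::size_t)n * plane;
    int* ip = idx.begin() + (std::size_t)n * plane;
    for (std::size_t p = 0; p < plane; ++p) { op[p] = xn[p]; ip[p] = 0; }
    for (int c = 1; c < C; ++c) {
      const double* xc = xn + (std::size_t)c * plane;
      for (std::size_t p = 0; p < plane; ++p)
        if (xc[p] > op[p]) { op[p] = xc[p]; ip[p] = c; }
    }
  }
  return List::create(_["max"] = out, _["idx"] = idx);
}
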