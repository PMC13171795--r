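// Compiled kernels for the CNN layers: padding (zero / reflect) with exact
// adjoints, im2col-based 2-D convolution, depthwise convolution for the PI
// feature paths, and 2x2 max pooling. All arrays use R's column-major layout
// with dim (H, W, C, N).
#include <RcppArmadillo.h>
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// mirror index without repeating the edge sample; requires n >= 2
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_pad2d(const NumericVector& x, int pt, int pb, int pl, int pr,
                        int mode) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (mode == 1 && (H < 2 || W < 2) && (pt || pb || pl || pr))
    stop("reflect padding requires spatial dims >= 2");
  int Hp = H + pt + pb, Wp = W + pl + pr;
  NumericVector out((R_xlen_t)Hp * Wp * C * N);
  out.attr("dim") = IntegerVector::create(Hp, Wp, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + ((size_t)n * C + c) * (size_t)H * W;
      double* os = op + ((size_t)n * C + c) * (size_t)Hp * Wp;
      for (int j = 0; j < Wp; ++j) {
        int sj = j - pl;
        bool jin = (sj >= 0 && sj < W);
        int rj = jin ? sj : reflect_idx(sj, W);
        for (int i = 0; i < Hp; ++i) {
          int si = i - pt;
          bool iin = (si >= 0 && si < H);
          double v;
          if (iin && jin) {
            v = xs[si + (size_t)sj * H];
          } else if (mode == 1) {
            int ri = iin ? si : reflect_idx(si, H);
            v = xs[ri + (size_t)rj * H];
          } else {
            v = 0.0;
          }
          os[i + (size_t)j * Hp] = v;
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_pad2d: folds gradient contributions from the padded border
// back onto the interior source pixels (crop for zero padding, scatter-add
// for reflect). Needed so finite-difference gradient checks pass exactly.
// [[Rcpp::export]]
NumericVector cpp_pad2d_adjoint(const NumericVector& dxp, int H, int W,
                                int pt, int pb, int pl, int pr, int mode) {
  int Hp, Wp, C, N;
  get_dims4(dxp, Hp, Wp, C, N);
  if (Hp != H + pt + pb || Wp != W + pl + pr) stop("padded dims mismatch");
  NumericVector out((R_xlen_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = dxp.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* gs = gp + ((size_t)n * C + c) * (size_t)Hp * Wp;
      double* os = op + ((size_t)n * C + c) * (size_t)H * W;
      for (int j = 0; j < Wp; ++j) {
        int sj = j - pl;
        for (int i = 0; i < Hp; ++i) {
          int si = i - pt;
          double g = gs[i + (size_t)j * Hp];
          if (si >= 0 && si < H && sj >= 0 && sj < W) {
            os[si + (size_t)sj * H] += g;
          } else if (mode == 1) {
            os[reflect_idx(si, H) + (size_t)reflect_idx(sj, W) * H] += g;
          } // zero padding: border gradient is discarded
        }
      }
    }
  }
  return out;
}

static void fill_col(arma::mat& col, const double* xs, int Hp, int Wp, int C,
                     int kh, int kw, int Ho, int Wo) {
  // col is (kh*kw*C) x (Ho*Wo); row r = i + kh*j + kh*kw*c, column p = ho + Ho*wo
  for (int c = 0; c < C; ++c) {
    const double* xc = xs + (size_t)c * Hp * Wp;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * j + kh * kw * c;
        double* cr = col.memptr() + r; // stride = col.n_rows
        for (int wo = 0; wo < Wo; ++wo) {
          const double* src = xc + (i + (size_t)(wo + j) * Hp);
          size_t pbase = (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            cr[(pbase + ho) * col.n_rows] = src[ho];
          }
        }
      }
    }
  }
}

// x is already padded: (Hp, Wp, C, N); w: (kh, kw, C, F); b: length F (or 0)
// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(const NumericVector& x, const NumericVector& w,
                             const NumericVector& b) {
  int Hp, Wp, C, N;
  get_dims4(x, Hp, Wp, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be (kh, kw, C, F)");
  int kh = wd[0], kw = wd[1], Cw = wd[2], F = wd[3];
  if (Cw != C) stop("weight channel mismatch");
  if (kh > Hp || kw > Wp) stop("kernel larger than (padded) input");
  int Ho = Hp - kh + 1, Wo = Wp - kw + 1, P = Ho * Wo, K = kh * kw * C;
  bool has_b = b.size() == F;
  arma::mat Wm(const_cast<double*>(w.begin()), K, F, false, true);
  NumericVector out((R_xlen_t)P * F * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * C * Hp * Wp;
    fill_col(col, xs, Hp, Wp, C, kh, kw, Ho, Wo);
    arma::mat Y = col.t() * Wm; // P x F, matches (Ho, Wo, F) layout
    if (has_b) Y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), F, false, true);
    std::copy(Y.memptr(), Y.memptr() + (size_t)P * F,
              out.begin() + (size_t)n * P * F);
  }
  return out;
}

// returns gradients w.r.t. padded input, weights, bias; dx computation can
// be skipped for the first layer of a network (need_dx = false)
// [[Rcpp::export]]
List cpp_conv2d_bwd(const NumericVector& x, const NumericVector& w,
                    const NumericVector& dy, bool need_dx = true) {
  int Hp, Wp, C, N;
  get_dims4(x, Hp, Wp, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], F = wd[3];
  int Ho = Hp - kh + 1, Wo = Wp - kw + 1, P = Ho * Wo, K = kh * kw * C;
  arma::mat Wm(const_cast<double*>(w.begin()), K, F, false, true);
  NumericVector dx((R_xlen_t)Hp * Wp * C * N);
  dx.attr("dim") = IntegerVector::create(Hp, Wp, C, N);
  NumericVector dw((R_xlen_t)K * F);
  dw.attr("dim") = wd;
  NumericVector db(F);
  arma::mat dWm(dw.begin(), K, F, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * C * Hp * Wp;
    fill_col(col, xs, Hp, Wp, C, kh, kw, Ho, Wo);
    arma::mat dYm(const_cast<double*>(dy.begin()) + (size_t)n * P * F, P, F,
                  false, true);
    dWm += col * dYm;
    for (int f = 0; f < F; ++f) db[f] += arma::accu(dYm.col(f));
    if (!need_dx) continue;
    arma::mat dcol = Wm * dYm.t(); // K x P
    // col2im scatter-add into dx
    double* dxs = dx.begin() + (size_t)n * C * Hp * Wp;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxs + (size_t)c * Hp * Wp;
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          int r = i + kh * j + kh * kw * c;
          const double* dr = dcol.memptr() + r;
          for (int wo = 0; wo < Wo; ++wo) {
            double* dst = dxc + (i + (size_t)(wo + j) * Hp);
            size_t pbase = (size_t)wo * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              dst[ho] += dr[(pbase + ho) * K];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// depthwise valid convolution: x (Hp, Wp, C, N), k (kh, kw, C) -> (Ho, Wo, C, N)
// [[Rcpp::export]]
NumericVector cpp_depthwise_fwd(const NumericVector& x, const NumericVector& k) {
  int Hp, Wp, C, N;
  get_dims4(x, Hp, Wp, C, N);
  IntegerVector kd = k.attr("dim");
  if (kd.size() != 3 || kd[2] != C) stop("kernel bank must be (kh, kw, C)");
  int kh = kd[0], kw = kd[1];
  if (kh > Hp || kw > Wp) stop("kernel larger than (padded) input");
  int Ho = Hp - kh + 1, Wo = Wp - kw + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * (size_t)Hp * Wp;
      const double* ks = k.begin() + (size_t)c * kh * kw;
      double* os = out.begin() + ((size_t)n * C + c) * (size_t)Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int j = 0; j < kw; ++j)
            for (int i = 0; i < kh; ++i)
              acc += ks[i + (size_t)j * kh] * xs[ho + i + (size_t)(wo + j) * Hp];
          os[ho + (size_t)wo * Ho] = acc;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_depthwise_bwd(const NumericVector& x, const NumericVector& k,
                       const NumericVector& dy) {
  int Hp, Wp, C, N;
  get_dims4(x, Hp, Wp, C, N);
  IntegerVector kd = k.attr("dim");
  int kh = kd[0], kw = kd[1];
  int Ho = Hp - kh + 1, Wo = Wp - kw + 1;
  NumericVector dx((R_xlen_t)Hp * Wp * C * N);
  dx.attr("dim") = IntegerVector::create(Hp, Wp, C, N);
  NumericVector dk((R_xlen_t)kh * kw * C);
  dk.attr("dim") = kd;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * (size_t)Hp * Wp;
      const double* ks = k.begin() + (size_t)c * kh * kw;
      const double* gs = dy.begin() + ((size_t)n * C + c) * (size_t)Ho * Wo;
      double* dxs = dx.begin() + ((size_t)n * C + c) * (size_t)Hp * Wp;
      double* dks = dk.begin() + (size_t)c * kh * kw;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double g = gs[ho + (size_t)wo * Ho];
          if (g == 0.0) continue;
          for (int j = 0; j < kw; ++j) {
            for (int i = 0; i < kh; ++i) {
              dks[i + (size_t)j * kh] += g * xs[ho + i + (size_t)(wo + j) * Hp];
              dxs[ho + i + (size_t)(wo + j) * Hp] += g * ks[i + (size_t)j * kh];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dk"] = dk);
}

// 2x2 max pooling, stride 2; ties broken toward the first (top-left) element
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const NumericVector& x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("max pooling requires even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N); // absolute 0-based index into x
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t base = ((size_t)n * C + c) * (size_t)H * W;
      size_t obase = ((size_t)n * C + c) * (size_t)Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        const double* c0 = xp + base + (size_t)(2 * wo) * H;
        const double* c1 = c0 + H;
        for (int ho = 0; ho < Ho; ++ho) {
          size_t best = base + (2 * ho) + (size_t)(2 * wo) * H;
          double bv = c0[2 * ho];
          if (c0[2 * ho + 1] > bv) { bv = c0[2 * ho + 1]; best += 1; }
          size_t b1 = base + (2 * ho) + (size_t)(2 * wo + 1) * H;
          if (c1[2 * ho] > bv) { bv = c1[2 * ho]; best = b1; }
          if (c1[2 * ho + 1] > bv) { bv = c1[2 * ho + 1]; best = b1 + 1; }
          op[obase + ho + (size_t)wo * Ho] = bv;
          ip[obase + ho + (size_t)wo * Ho] = (int)best;
        }
      }
    }
  }
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(const NumericVector& dy, const IntegerVector& idx,
                               const IntegerVector& xdim) {
  R_xlen_t total = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(total);
  dx.attr("dim") = xdim;
  double* dp = dx.begin();
  const double* gp = dy.begin();
  const int* ip = idx.begin();
  for (R_xlen_t p = 0; p < dy.size(); ++p) dp[ip[p]] += gp[p];
  return dx;
}

// in-place ReLU; returns the clipped array (same object)
// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector y) {
  double* p = y.begin();
  R_xlen_t m = y.size();
  for (R_xlen_t i = 0; i < m; ++i) p[i] = std::max(p[i], 0.0);
  return y;
}

// zero the gradient wherever the forward activation was clipped
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, const NumericVector& y) {
  double* g = dy.begin();
  const double* a = y.begin();
  R_xlen_t m = dy.size();
  for (R_xlen_t i = 0; i < m; ++i) g[i] = (a[i] > 0) ? g[i] : 0.0;
  return dy;
}
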