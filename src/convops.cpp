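// Convolution / pooling / upsampling primitives for the molecular image
// autoencoder. Feature maps are R arrays with dim (H, W, C, B); kernels are
// (ks, ks, Cin, Cout). Stride is 1 with 'same' zero padding pad = (ks-1)/2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col_into(arma::mat& col, const double* x, int H, int W,
                               int C, int ks) {
  const int pad = (ks - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < ks; ++kw) {
      for (int kh = 0; kh < ks; ++kh) {
        const int cc = kh + ks * kw + ks * ks * c;
        double* dst = col.colptr(cc);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kw - pad;
          if (sj < 0 || sj >= W) {
            std::fill(dst + H * j, dst + H * (j + 1), 0.0);
            continue;
          }
          const double* src = xc + H * sj;
          double* d = dst + H * j;
          const int lo = std::max(0, pad - kh);
          const int hi = std::min(H, H + pad - kh);
          for (int i = 0; i < lo; ++i) d[i] = 0.0;
          for (int i = lo; i < hi; ++i) d[i] = src[i + kh - pad];
          for (int i = hi; i < H; ++i) d[i] = 0.0;
        }
      }
    }
  }
}

// scatter-add of a (H*W) x (ks*ks*C) gradient back to the input map
static inline void col2im(const arma::mat& dcol, double* dx, int H, int W,
                          int C, int ks) {
  const int pad = (ks - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kw = 0; kw < ks; ++kw) {
      for (int kh = 0; kh < ks; ++kh) {
        const int cc = kh + ks * kw + ks * ks * c;
        const double* src = dcol.colptr(cc);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kw - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + kh - pad;
            if (si < 0 || si >= H) continue;
            xc[si + H * sj] += src[i + H * j];
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 3) {
    IntegerVector d4(4);
    d4[0] = d[0]; d4[1] = d[1]; d4[2] = d[2]; d4[3] = 1;
    return d4;
  }
  return d;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int ks = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d_fwd: channel mismatch");
  arma::mat wm(w.begin(), ks * ks * Cin, Cout, false);
  NumericVector out((size_t)H * W * Cout * B);
  out.attr("dim") = IntegerVector::create(H, W, Cout, B);
  arma::mat col(H * W, ks * ks * Cin);
  for (int bb = 0; bb < B; ++bb) {
    im2col_into(col, x.begin() + (size_t)H * W * C * bb, H, W, C, ks);
    arma::mat y(out.begin() + (size_t)H * W * Cout * bb, H * W, Cout,
                false, true);
    y = col * wm;
    for (int co = 0; co < Cout; ++co) y.col(co) += b[co];
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int ks = wd[0], Cin = wd[2], Cout = wd[3];
  arma::mat wm(w.begin(), ks * ks * Cin, Cout, false);
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = xd;
  NumericVector dwv(ks * ks * Cin * Cout);
  dwv.attr("dim") = wd;
  arma::mat dw(dwv.begin(), ks * ks * Cin, Cout, false);
  NumericVector db(Cout);
  arma::mat col(H * W, ks * ks * Cin);
  arma::mat dcol(H * W, ks * ks * Cin);
  for (int bb = 0; bb < B; ++bb) {
    im2col_into(col, x.begin() + (size_t)H * W * C * bb, H, W, C, ks);
    arma::mat dym(dy.begin() + (size_t)H * W * Cout * bb, H * W, Cout, false);
    dw += col.t() * dym;
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dym.col(co));
    dcol = dym * wm.t();
    col2im(dcol, dx.begin() + (size_t)H * W * C * bb, H, W, C, ks);
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// [[Rcpp::export(name = ".avgpool2_fwd")]]
NumericVector avgpool2_fwd(NumericVector x) {
  IntegerVector xd = dims4(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      const double* xi = x.begin() + (size_t)H * W * (c + (size_t)C * bb);
      double* yo = out.begin() + (size_t)Ho * Wo * (c + (size_t)C * bb);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          yo[i + Ho * j] = 0.25 * (xi[2 * i + H * (2 * j)] +
                                   xi[2 * i + 1 + H * (2 * j)] +
                                   xi[2 * i + H * (2 * j + 1)] +
                                   xi[2 * i + 1 + H * (2 * j + 1)]);
    }
  return out;
}

// [[Rcpp::export(name = ".avgpool2_bwd")]]
NumericVector avgpool2_bwd(NumericVector dy) {
  IntegerVector yd = dims4(dy);
  const int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  const int H = Ho * 2, W = Wo * 2;
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      const double* dyo = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * bb);
      double* dxi = dx.begin() + (size_t)H * W * (c + (size_t)C * bb);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double g = 0.25 * dyo[i + Ho * j];
          dxi[2 * i + H * (2 * j)] += g;
          dxi[2 * i + 1 + H * (2 * j)] += g;
          dxi[2 * i + H * (2 * j + 1)] += g;
          dxi[2 * i + 1 + H * (2 * j + 1)] += g;
        }
    }
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = dims4(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = H * 2, Wo = W * 2;
  NumericVector out((size_t)Ho * Wo * C * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      const double* xi = x.begin() + (size_t)H * W * (c + (size_t)C * bb);
      double* yo = out.begin() + (size_t)Ho * Wo * (c + (size_t)C * bb);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          yo[i + Ho * j] = xi[(i / 2) + H * (j / 2)];
    }
  return out;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dims4(dy);
  const int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      const double* dyo = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * bb);
      double* dxi = dx.begin() + (size_t)H * W * (c + (size_t)C * bb);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          dxi[(i / 2) + H * (j / 2)] += dyo[i + Ho * j];
    }
  return dx;
}

// Fused batch norm (+ optional ReLU). Statistics are per channel over
// (H, W, B). In training mode batch statistics are computed and returned;
// in eval mode the supplied running statistics are used.
// [[Rcpp::export(name = ".bn_fwd_cpp")]]
List bn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                bool train, NumericVector rmean, NumericVector rvar,
                bool relu) {
  IntegerVector xd = dims4(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const size_t hw = (size_t)H * W;
  NumericVector mu(C), va(C);
  if (train) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int bb = 0; bb < B; ++bb) {
        const double* xc = x.begin() + hw * (c + (size_t)C * bb);
        for (size_t k = 0; k < hw; ++k) { s += xc[k]; s2 += xc[k] * xc[k]; }
      }
      const double m = (double)hw * B;
      mu[c] = s / m;
      va[c] = std::max(0.0, s2 / m - mu[c] * mu[c]);
    }
  } else {
    mu = clone(rmean);
    va = clone(rvar);
  }
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector inv(C);
  for (int c = 0; c < C; ++c) {
    inv[c] = 1.0 / std::sqrt(va[c] + 1e-5);
    const double a = gamma[c] * inv[c];
    const double b0 = beta[c] - a * mu[c];
    for (int bb = 0; bb < B; ++bb) {
      const double* xc = x.begin() + hw * (c + (size_t)C * bb);
      double* yc = y.begin() + hw * (c + (size_t)C * bb);
      for (size_t k = 0; k < hw; ++k) {
        double v = a * xc[k] + b0;
        yc[k] = (relu && v < 0) ? 0.0 : v;
      }
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["var"] = va,
                      _["inv"] = inv);
}

// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(NumericVector x, NumericVector y, NumericVector gamma,
                NumericVector mu, NumericVector inv, NumericVector dy,
                bool relu) {
  IntegerVector xd = dims4(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const size_t hw = (size_t)H * W;
  const double m = (double)hw * B;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0.0, s2 = 0.0;
    for (int bb = 0; bb < B; ++bb) {
      const double* xc = x.begin() + hw * (c + (size_t)C * bb);
      const double* yc = y.begin() + hw * (c + (size_t)C * bb);
      const double* dyc = dy.begin() + hw * (c + (size_t)C * bb);
      for (size_t k = 0; k < hw; ++k) {
        const double d = (relu && yc[k] <= 0) ? 0.0 : dyc[k];
        const double xh = (xc[k] - mu[c]) * inv[c];
        s1 += d;
        s2 += d * xh;
      }
    }
    dgamma[c] = s2;
    dbeta[c] = s1;
    const double gs1 = gamma[c] * s1 / m;
    const double gs2 = gamma[c] * s2 / m;
    for (int bb = 0; bb < B; ++bb) {
      const double* xc = x.begin() + hw * (c + (size_t)C * bb);
      const double* yc = y.begin() + hw * (c + (size_t)C * bb);
      const double* dyc = dy.begin() + hw * (c + (size_t)C * bb);
      double* dxc = dx.begin() + hw * (c + (size_t)C * bb);
      for (size_t k = 0; k < hw; ++k) {
        const double d = (relu && yc[k] <= 0) ? 0.0 : dyc[k];
        const double xh = (xc[k] - mu[c]) * inv[c];
        dxc[k] = inv[c] * (gamma[c] * d - gs1 - xh * gs2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
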