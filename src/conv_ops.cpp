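// Low-level numeric kernels for the scmnet autograd engine.
//
// Tensor layout convention throughout: column-major R arrays with
// dim = (H, W, C, N); a single (H, W) channel plane is therefore a
// contiguous column-major H x W matrix, which im2col exploits.
// Convolution weights are (K, K, C_per_group, C_out).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix M (K*K*Cpg x oH*oW) for sample n, group g.
static void im2col(const double* x, int H, int W, int C,
                   int cpg, int c0, int K, int stride, int pad,
                   int oH, int oW, arma::mat& M) {
  for (int ow = 0; ow < oW; ++ow) {
    for (int oh = 0; oh < oH; ++oh) {
      const int col = oh + oH * ow;
      double* mcol = M.colptr(col);
      for (int ci = 0; ci < cpg; ++ci) {
        const double* plane = x + (size_t)(c0 + ci) * H * W;
        for (int kw = 0; kw < K; ++kw) {
          const int w = ow * stride - pad + kw;
          for (int kh = 0; kh < K; ++kh) {
            const int h = oh * stride - pad + kh;
            const int row = kh + K * (kw + K * ci);
            mcol[row] = (h >= 0 && h < H && w >= 0 && w < W)
              ? plane[h + (size_t)H * w] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add of columns back into the (padded) input: inverse of im2col.
static void col2im(const arma::mat& M, double* gx, int H, int W, int C,
                   int cpg, int c0, int K, int stride, int pad,
                   int oH, int oW) {
  for (int ow = 0; ow < oW; ++ow) {
    for (int oh = 0; oh < oH; ++oh) {
      const int col = oh + oH * ow;
      const double* mcol = M.colptr(col);
      for (int ci = 0; ci < cpg; ++ci) {
        double* plane = gx + (size_t)(c0 + ci) * H * W;
        for (int kw = 0; kw < K; ++kw) {
          const int w = ow * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            const int h = oh * stride - pad + kh;
            if (h < 0 || h >= H) continue;
            plane[h + (size_t)H * w] += mcol[kh + K * (kw + K * ci)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w,
                         int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], cpg = wd[2], Cout = wd[3];
  if (wd[1] != K) stop("square kernels only");
  if (C % groups != 0 || Cout % groups != 0 || C / groups != cpg)
    stop("channel/group mismatch");
  const int oH = out_size(H, K, stride, pad), oW = out_size(W, K, stride, pad);
  if (oH < 1 || oW < 1) stop("non-positive output size");
  const int npg = Cout / groups;

  NumericVector out((size_t)oH * oW * Cout * N);
  out.attr("dim") = IntegerVector::create(oH, oW, Cout, N);
  arma::mat M(K * K * cpg, oH * oW);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* on = out.begin() + (size_t)n * oH * oW * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, C, cpg, g * cpg, K, stride, pad, oH, oW, M);
      const arma::mat Wm(const_cast<double*>(w.begin()) +
                         (size_t)g * npg * K * K * cpg,
                         K * K * cpg, npg, false, true);
      arma::mat Ob(on + (size_t)g * npg * oH * oW, oH * oW, npg, false, true);
      Ob = M.t() * Wm;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gout,
                         int stride, int pad, int groups,
                         bool need_gx, bool need_gw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], cpg = wd[2], Cout = wd[3];
  const int oH = out_size(H, K, stride, pad), oW = out_size(W, K, stride, pad);
  const int npg = Cout / groups;

  NumericVector gx(need_gx ? (size_t)H * W * C * N : 0);
  NumericVector gw(need_gw ? (size_t)K * K * cpg * Cout : 0);
  if (need_gx) gx.attr("dim") = xd;
  if (need_gw) gw.attr("dim") = wd;

  arma::mat M(K * K * cpg, oH * oW);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* gn = gout.begin() + (size_t)n * oH * oW * Cout;
    for (int g = 0; g < groups; ++g) {
      const arma::mat Gb(const_cast<double*>(gn) + (size_t)g * npg * oH * oW,
                         oH * oW, npg, false, true);
      const arma::mat Wm(const_cast<double*>(w.begin()) +
                         (size_t)g * npg * K * K * cpg,
                         K * K * cpg, npg, false, true);
      if (need_gw || need_gx)
        im2col(xn, H, W, C, cpg, g * cpg, K, stride, pad, oH, oW, M);
      if (need_gw) {
        arma::mat Gw(gw.begin() + (size_t)g * npg * K * K * cpg,
                     K * K * cpg, npg, false, true);
        Gw += M * Gb;
      }
      if (need_gx) {
        arma::mat dM = Wm * Gb.t();
        col2im(dM, gx.begin() + (size_t)n * H * W * C,
               H, W, C, cpg, g * cpg, K, stride, pad, oH, oW);
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int oH = out_size(H, k, stride, pad), oW = out_size(W, k, stride, pad);
  NumericVector out((size_t)oH * oW * C * N);
  IntegerVector idx((size_t)oH * oW * C * N);  // 0-based flat index into x
  out.attr("dim") = IntegerVector::create(oH, oW, C, N);

  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      const double* plane = x.begin() + base;
      for (int ow = 0; ow < oW; ++ow) {
        for (int oh = 0; oh < oH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          int barg = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int w = ow * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = oh * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              const double v = plane[h + (size_t)H * w];
              if (v > best) { best = v; barg = h + H * w; }
            }
          }
          // output layout is (oH, oW, C, N): recompute destination
          const size_t dst = (size_t)oh + oH * (ow + (size_t)oW * (c + (size_t)C * n));
          out[dst] = best;
          idx[dst] = (int)(base + barg);
          ++o;
        }
      }
    }
  }
  (void)o;
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector gout, IntegerVector idx,
                                   IntegerVector xdim) {
  size_t nx = 1;
  for (int i = 0; i < xdim.size(); ++i) nx *= xdim[i];
  NumericVector gx(nx);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[idx[i]] += gout[i];
  return gx;
}

// Reduce-sum over the axes flagged in `drop` (length 4), keeping dims of 1.
// [[Rcpp::export]]
NumericVector cpp_reduce_sum(NumericVector x, LogicalVector drop) {
  IntegerVector xd = x.attr("dim");
  int d[4], od[4];
  for (int i = 0; i < 4; ++i) { d[i] = xd[i]; od[i] = drop[i] ? 1 : xd[i]; }
  NumericVector out((size_t)od[0] * od[1] * od[2] * od[3]);
  out.attr("dim") = IntegerVector::create(od[0], od[1], od[2], od[3]);
  const size_t s1 = od[0], s2 = (size_t)od[0] * od[1], s3 = s2 * od[2];
  size_t i = 0;
  for (int n = 0; n < d[3]; ++n) {
    const size_t on = drop[3] ? 0 : (size_t)n * s3;
    for (int c = 0; c < d[2]; ++c) {
      const size_t oc = on + (drop[2] ? 0 : (size_t)c * s2);
      for (int w = 0; w < d[1]; ++w) {
        const size_t ow = oc + (drop[1] ? 0 : w * s1);
        if (!drop[0]) {
          double* op = out.begin() + ow;
          const double* xp = x.begin() + i;
          for (int h = 0; h < d[0]; ++h) op[h] += xp[h];
          i += d[0];
        } else {
          double acc = 0.0;
          const double* xp = x.begin() + i;
          for (int h = 0; h < d[0]; ++h) acc += xp[h];
          out[ow] += acc;
          i += d[0];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_reduce_max(NumericVector x, LogicalVector drop) {
  IntegerVector xd = x.attr("dim");
  int d[4], od[4];
  for (int i = 0; i < 4; ++i) { d[i] = xd[i]; od[i] = drop[i] ? 1 : xd[i]; }
  NumericVector out((size_t)od[0] * od[1] * od[2] * od[3],
                    -std::numeric_limits<double>::infinity());
  out.attr("dim") = IntegerVector::create(od[0], od[1], od[2], od[3]);
  const size_t s1 = od[0], s2 = (size_t)od[0] * od[1], s3 = s2 * od[2];
  size_t i = 0;
  for (int n = 0; n < d[3]; ++n) {
    const size_t on = drop[3] ? 0 : (size_t)n * s3;
    for (int c = 0; c < d[2]; ++c) {
      const size_t oc = on + (drop[2] ? 0 : (size_t)c * s2);
      for (int w = 0; w < d[1]; ++w) {
        const size_t ow = oc + (drop[1] ? 0 : w * s1);
        const double* xp = x.begin() + i;
        if (!drop[0]) {
          double* op = out.begin() + ow;
          for (int h = 0; h < d[0]; ++h) if (xp[h] > op[h]) op[h] = xp[h];
        } else {
          double m = out[ow];
          for (int h = 0; h < d[0]; ++h) if (xp[h] > m) m = xp[h];
          out[ow] = m;
        }
        i += d[0];
      }
    }
  }
  return out;
}

// Broadcast x (dims with 1s) up to `todim`.
// [[Rcpp::export]]
NumericVector cpp_bcast(NumericVector x, IntegerVector todim) {
  IntegerVector xd = x.attr("dim");
  int d[4], t[4];
  for (int i = 0; i < 4; ++i) { d[i] = xd[i]; t[i] = todim[i]; }
  NumericVector out((size_t)t[0] * t[1] * t[2] * t[3]);
  out.attr("dim") = todim;
  const size_t x1 = d[0], x2 = (size_t)d[0] * d[1], x3 = x2 * d[2];
  size_t o = 0;
  for (int n = 0; n < t[3]; ++n) {
    const size_t xn = (d[3] == 1 ? 0 : (size_t)n * x3);
    for (int c = 0; c < t[2]; ++c) {
      const size_t xc = xn + (d[2] == 1 ? 0 : (size_t)c * x2);
      for (int w = 0; w < t[1]; ++w) {
        const size_t xw = xc + (d[1] == 1 ? 0 : w * x1);
        const double* xp = x.begin() + xw;
        double* op = out.begin() + o;
        if (d[0] == 1) {
          const double v = xp[0];
          for (int h = 0; h < t[0]; ++h) op[h] = v;
        } else {
          for (int h = 0; h < t[0]; ++h) op[h] = xp[h];
        }
        o += t[0];
      }
    }
  }
  return out;
}

// Bilinear resize of an (H, W, C) image to (oh, ow).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector img, int oh, int ow) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out((size_t)oh * ow * C);
  out.attr("dim") = IntegerVector::create(oh, ow, C);
  const double sh = (double)H / oh, sw = (double)W / ow;
  for (int c = 0; c < C; ++c) {
    const double* plane = img.begin() + (size_t)c * H * W;
    double* op = out.begin() + (size_t)c * oh * ow;
    for (int x = 0; x < ow; ++x) {
      const double fx = (x + 0.5) * sw - 0.5;
      int x0 = (int)std::floor(fx);
      const double ax = fx - x0;
      int x1 = std::min(std::max(x0 + 1, 0), W - 1);
      x0 = std::min(std::max(x0, 0), W - 1);
      for (int y = 0; y < oh; ++y) {
        const double fy = (y + 0.5) * sh - 0.5;
        int y0 = (int)std::floor(fy);
        const double ay = fy - y0;
        int y1 = std::min(std::max(y0 + 1, 0), H - 1);
        y0 = std::min(std::max(y0, 0), H - 1);
        const double v =
          (1 - ay) * ((1 - ax) * plane[y0 + (size_t)H * x0] +
                      ax * plane[y0 + (size_t)H * x1]) +
          ay * ((1 - ax) * plane[y1 + (size_t)H * x0] +
                ax * plane[y1 + (size_t)H * x1]);
        op[y + (size_t)oh * x] = v;
      }
    }
  }
  return out;
}

// Inverse-map affine warp: output pixel (r, c) samples input at
// (a11*r + a12*c + a13, a21*r + a22*c + a23), bilinear, constant fill.
// [[Rcpp::export]]
NumericVector cpp_affine_warp(NumericVector img, NumericVector A, double fill) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out((size_t)H * W * C);
  out.attr("dim") = d;
  const double a11 = A[0], a21 = A[1], a12 = A[2], a22 = A[3],
               a13 = A[4], a23 = A[5];
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const double sr = a11 * r + a12 * c + a13;
      const double sc = a21 * r + a22 * c + a23;
      const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      const double ar = sr - r0, ac = sc - c0;
      for (int ch = 0; ch < C; ++ch) {
        const double* plane = img.begin() + (size_t)ch * H * W;
        double v;
        if (r0 < -1 || r0 >= H || c0 < -1 || c0 >= W) {
          v = fill;
        } else {
          auto px = [&](int rr, int cc) -> double {
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) return fill;
            return plane[rr + (size_t)H * cc];
          };
          v = (1 - ar) * ((1 - ac) * px(r0, c0) + ac * px(r0, c0 + 1)) +
              ar * ((1 - ac) * px(r0 + 1, c0) + ac * px(r0 + 1, c0 + 1));
        }
        out[r + (size_t)H * (c + (size_t)W * ch)] = v;
      }
    }
  }
  return out;
}
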