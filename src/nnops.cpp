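// Convolution kernels for the CNN engine, with hand-written backward passes.
// Layouts follow R column-major arrays:
//   2D activations  [H, W, C]
//   2D kernels      [kh, kw, Cin, Cout]
//   3D activations  [X, Y, Z, C]
//   3D kernels      [k, k, k, Cin, Cout]
// "same" padding of floor(k/2); output size ceil(n/stride) per spatial axis.
//
// Three code paths, chosen per call:
//   - k == 1: plain GEMM over the channel dimension (position gather when
//     strided);
//   - stride == 1: direct accumulation loops (one pass per kernel tap and
//     channel pair), which beats im2col at the small channel counts this
//     engine runs at;
//   - otherwise: im2col + GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int stride) { return (n + stride - 1) / stride; }

// ======================= 2D =======================

static void conv2d_direct_fw(const double* x, const double* w,
                             const double* b, double* y, int H, int W,
                             int Cin, int Cout, int k) {
  const int pad = k / 2;
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int co = 0; co < Cout; ++co) {
    double* yc = y + HW * co;
    for (R_xlen_t p = 0; p < HW; ++p) yc[p] = b[co];
  }
  for (int co = 0; co < Cout; ++co) {
    double* yc = y + HW * co;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x + HW * ci;
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          const double alpha = w[ki + k * (kj + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co))];
          if (alpha == 0.0) continue;
          const int di = ki - pad, dj = kj - pad;
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int j = j0; j < j1; ++j) {
            double* __restrict__ yrow = yc + (R_xlen_t)H * j;
            const double* __restrict__ xrow = xc + (R_xlen_t)H * (j + dj) + di;
            for (int i = i0; i < i1; ++i) yrow[i] += alpha * xrow[i];
          }
        }
    }
  }
}

// dx += dy (*) w-flipped ; dw += x (corr) dy ; db += sum(dy)
static void conv2d_direct_bw(const double* x, const double* w,
                             const double* dy, double* dx, double* dw,
                             double* db, int H, int W, int Cin, int Cout,
                             int k) {
  const int pad = k / 2;
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int co = 0; co < Cout; ++co) {
    const double* dyc = dy + HW * co;
    double acc = 0.0;
    for (R_xlen_t p = 0; p < HW; ++p) acc += dyc[p];
    db[co] = acc;
  }
  for (int co = 0; co < Cout; ++co) {
    const double* dyc = dy + HW * co;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x + HW * ci;
      double* dxc = dx + HW * ci;
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          const int di = ki - pad, dj = kj - pad;
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const double alpha = w[ki + k * (kj + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co))];
          double acc = 0.0;
          for (int j = j0; j < j1; ++j) {
            const double* __restrict__ dyrow = dyc + (R_xlen_t)H * j;
            const double* __restrict__ xrow = xc + (R_xlen_t)H * (j + dj) + di;
            double* __restrict__ dxrow = dxc + (R_xlen_t)H * (j + dj) + di;
            for (int i = i0; i < i1; ++i) {
              acc += xrow[i] * dyrow[i];
              dxrow[i] += alpha * dyrow[i];
            }
          }
          dw[ki + k * (kj + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co))] = acc;
        }
    }
  }
}

static arma::mat im2col2d(const double* x, int H, int W, int C, int k,
                          int stride) {
  const int pad = k / 2;
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);
  arma::mat M((size_t)Ho * Wo, (size_t)k * k * C);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        double* col = M.colptr(ki + (size_t)k * (kj + (size_t)k * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int j = wo * stride + kj - pad;
          bool jok = (j >= 0 && j < W);
          double* dst = col + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int i = ho * stride + ki - pad;
            dst[ho] = (jok && i >= 0 && i < H)
              ? x[i + (R_xlen_t)H * (j + (R_xlen_t)W * c)] : 0.0;
          }
        }
      }
  return M;
}

static void col2im2d(const arma::mat& dM, double* dx, int H, int W, int C,
                     int k, int stride) {
  const int pad = k / 2;
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const double* col = dM.colptr(ki + (size_t)k * (kj + (size_t)k * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int j = wo * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          const double* src = col + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int i = ho * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            dx[i + (R_xlen_t)H * (j + (R_xlen_t)W * c)] += src[ho];
          }
        }
      }
}

// [[Rcpp::export(name = ".conv2d_fw_cpp")]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                            int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int k = wd[0], Cout = wd[3];
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);
  NumericVector out((R_xlen_t)Ho * Wo * Cout);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  if (stride == 1 && k > 1) {
    conv2d_direct_fw(REAL(x), REAL(w), REAL(b), REAL(out), H, W, C, Cout, k);
    return out;
  }
  arma::mat Wm(const_cast<double*>(REAL(w)), (size_t)k * k * C, Cout, false,
               true);
  arma::mat Y;
  if (k == 1 && stride == 1) {
    arma::mat X(const_cast<double*>(REAL(x)), (size_t)H * W, C, false, true);
    Y = X * Wm;
  } else {
    Y = im2col2d(REAL(x), H, W, C, k, stride) * Wm;
  }
  double* po = REAL(out);
  for (int o = 0; o < Cout; ++o) {
    const double bo = REAL(b)[o];
    const double* yc = Y.colptr(o);
    for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
      po[p + (R_xlen_t)Ho * Wo * o] = yc[p] + bo;
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw_cpp")]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector dy,
                   int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int k = wd[0], Cout = wd[3];
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);
  NumericVector dx((R_xlen_t)H * W * C);
  dx.attr("dim") = xd;
  NumericVector dwv(w.size());
  dwv.attr("dim") = wd;
  NumericVector db(Cout);
  if (stride == 1 && k > 1) {
    conv2d_direct_bw(REAL(x), REAL(w), REAL(dy), REAL(dx), REAL(dwv),
                     REAL(db), H, W, C, Cout, k);
    return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
  }
  arma::mat Wm(const_cast<double*>(REAL(w)), (size_t)k * k * C, Cout, false,
               true);
  arma::mat dY(const_cast<double*>(REAL(dy)), (size_t)Ho * Wo, Cout, false,
               true);
  arma::rowvec dbv = arma::sum(dY, 0);
  std::copy(dbv.begin(), dbv.end(), REAL(db));
  if (k == 1 && stride == 1) {
    arma::mat X(const_cast<double*>(REAL(x)), (size_t)H * W, C, false, true);
    arma::mat dW = X.t() * dY;
    std::copy(dW.begin(), dW.end(), REAL(dwv));
    arma::mat dX = dY * Wm.t();
    std::copy(dX.begin(), dX.end(), REAL(dx));
  } else {
    arma::mat M = im2col2d(REAL(x), H, W, C, k, stride);
    arma::mat dW = M.t() * dY;
    std::copy(dW.begin(), dW.end(), REAL(dwv));
    arma::mat dM = dY * Wm.t();
    col2im2d(dM, REAL(dx), H, W, C, k, stride);
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// ======================= 3D =======================

static void conv3d_direct_fw(const double* x, const double* w,
                             const double* b, double* y, int X, int Y,
                             int Z, int Cin, int Cout, int k) {
  const int pad = k / 2;
  const R_xlen_t XY = (R_xlen_t)X * Y;
  const R_xlen_t XYZ = XY * Z;
  for (int co = 0; co < Cout; ++co) {
    double* yc = y + XYZ * co;
    for (R_xlen_t p = 0; p < XYZ; ++p) yc[p] = b[co];
  }
  for (int co = 0; co < Cout; ++co) {
    double* yc = y + XYZ * co;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x + XYZ * ci;
      for (int kk = 0; kk < k; ++kk)
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki) {
            const double alpha =
              w[ki + k * (kj + (R_xlen_t)k * (kk + (R_xlen_t)k *
                 (ci + (R_xlen_t)Cin * co)))];
            const int di = ki - pad, dj = kj - pad, dk = kk - pad;
            const int z0 = std::max(0, -dk), z1 = std::min(Z, Z - dk);
            const int j0 = std::max(0, -dj), j1 = std::min(Y, Y - dj);
            const int i0 = std::max(0, -di), i1 = std::min(X, X - di);
            for (int z = z0; z < z1; ++z)
              for (int j = j0; j < j1; ++j) {
                double* __restrict__ yrow = yc + (R_xlen_t)X * j + XY * z;
                const double* __restrict__ xrow = xc + (R_xlen_t)X * (j + dj) +
                  XY * (z + dk) + di;
                for (int i = i0; i < i1; ++i) yrow[i] += alpha * xrow[i];
              }
          }
    }
  }
}

static void conv3d_direct_bw(const double* x, const double* w,
                             const double* dy, double* dx, double* dw,
                             double* db, int X, int Y, int Z, int Cin,
                             int Cout, int k) {
  const int pad = k / 2;
  const R_xlen_t XY = (R_xlen_t)X * Y;
  const R_xlen_t XYZ = XY * Z;
  for (int co = 0; co < Cout; ++co) {
    const double* dyc = dy + XYZ * co;
    double acc = 0.0;
    for (R_xlen_t p = 0; p < XYZ; ++p) acc += dyc[p];
    db[co] = acc;
  }
  for (int co = 0; co < Cout; ++co) {
    const double* dyc = dy + XYZ * co;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x + XYZ * ci;
      double* dxc = dx + XYZ * ci;
      for (int kk = 0; kk < k; ++kk)
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki) {
            const int di = ki - pad, dj = kj - pad, dk = kk - pad;
            const int z0 = std::max(0, -dk), z1 = std::min(Z, Z - dk);
            const int j0 = std::max(0, -dj), j1 = std::min(Y, Y - dj);
            const int i0 = std::max(0, -di), i1 = std::min(X, X - di);
            const double alpha =
              w[ki + k * (kj + (R_xlen_t)k * (kk + (R_xlen_t)k *
                 (ci + (R_xlen_t)Cin * co)))];
            double acc = 0.0;
            for (int z = z0; z < z1; ++z)
              for (int j = j0; j < j1; ++j) {
                const double* __restrict__ dyrow = dyc + (R_xlen_t)X * j + XY * z;
                const double* __restrict__ xrow = xc + (R_xlen_t)X * (j + dj) +
                  XY * (z + dk) + di;
                double* __restrict__ dxrow = dxc + (R_xlen_t)X * (j + dj) +
                  XY * (z + dk) + di;
                for (int i = i0; i < i1; ++i) {
                  acc += xrow[i] * dyrow[i];
                  dxrow[i] += alpha * dyrow[i];
                }
              }
            dw[ki + k * (kj + (R_xlen_t)k * (kk + (R_xlen_t)k *
               (ci + (R_xlen_t)Cin * co)))] = acc;
          }
    }
  }
}

static arma::mat im2col3d(const double* x, int X, int Y, int Z, int C,
                          int k, int stride) {
  const int pad = k / 2;
  const int Xo = out_size(X, stride), Yo = out_size(Y, stride),
            Zo = out_size(Z, stride);
  arma::mat M((size_t)Xo * Yo * Zo, (size_t)k * k * k * C);
  for (int c = 0; c < C; ++c)
    for (int kk = 0; kk < k; ++kk)
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          double* col = M.colptr(ki + (size_t)k * (kj + (size_t)k *
                                  (kk + (size_t)k * c)));
          for (int zo = 0; zo < Zo; ++zo) {
            int z = zo * stride + kk - pad;
            bool zok = (z >= 0 && z < Z);
            for (int yo = 0; yo < Yo; ++yo) {
              int yy = yo * stride + kj - pad;
              bool yok = (yy >= 0 && yy < Y);
              double* dst = col + (size_t)Xo * (yo + (size_t)Yo * zo);
              for (int xo = 0; xo < Xo; ++xo) {
                int xx = xo * stride + ki - pad;
                dst[xo] = (zok && yok && xx >= 0 && xx < X)
                  ? x[xx + (R_xlen_t)X * (yy + (R_xlen_t)Y *
                      ((R_xlen_t)z + (R_xlen_t)Z * c))] : 0.0;
              }
            }
          }
        }
  return M;
}

static void col2im3d(const arma::mat& dM, double* dx, int X, int Y, int Z,
                     int C, int k, int stride) {
  const int pad = k / 2;
  const int Xo = out_size(X, stride), Yo = out_size(Y, stride),
            Zo = out_size(Z, stride);
  for (int c = 0; c < C; ++c)
    for (int kk = 0; kk < k; ++kk)
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          const double* col = dM.colptr(ki + (size_t)k * (kj + (size_t)k *
                                        (kk + (size_t)k * c)));
          for (int zo = 0; zo < Zo; ++zo) {
            int z = zo * stride + kk - pad;
            if (z < 0 || z >= Z) continue;
            for (int yo = 0; yo < Yo; ++yo) {
              int yy = yo * stride + kj - pad;
              if (yy < 0 || yy >= Y) continue;
              const double* src = col + (size_t)Xo * (yo + (size_t)Yo * zo);
              for (int xo = 0; xo < Xo; ++xo) {
                int xx = xo * stride + ki - pad;
                if (xx < 0 || xx >= X) continue;
                dx[xx + (R_xlen_t)X * (yy + (R_xlen_t)Y *
                   ((R_xlen_t)z + (R_xlen_t)Z * c))] += src[xo];
              }
            }
          }
        }
}

// [[Rcpp::export(name = ".conv3d_fw_cpp")]]
NumericVector conv3d_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                            int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int k = wd[0], Cout = wd[4];
  const int Xo = out_size(X, stride), Yo = out_size(Y, stride),
            Zo = out_size(Z, stride);
  const R_xlen_t npos = (R_xlen_t)Xo * Yo * Zo;
  NumericVector out(npos * Cout);
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Cout);
  if (stride == 1 && k > 1) {
    conv3d_direct_fw(REAL(x), REAL(w), REAL(b), REAL(out), X, Y, Z, C,
                     Cout, k);
    return out;
  }
  arma::mat Wm(const_cast<double*>(REAL(w)), (size_t)k * k * k * C, Cout,
               false, true);
  arma::mat Yv;
  if (k == 1 && stride == 1) {
    arma::mat Xm(const_cast<double*>(REAL(x)), (size_t)X * Y * Z, C, false,
                 true);
    Yv = Xm * Wm;
  } else {
    Yv = im2col3d(REAL(x), X, Y, Z, C, k, stride) * Wm;
  }
  double* po = REAL(out);
  for (int o = 0; o < Cout; ++o) {
    const double bo = REAL(b)[o];
    const double* yc = Yv.colptr(o);
    for (R_xlen_t p = 0; p < npos; ++p) po[p + npos * o] = yc[p] + bo;
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_bw_cpp")]]
List conv3d_bw_cpp(NumericVector x, NumericVector w, NumericVector dy,
                   int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int k = wd[0], Cout = wd[4];
  const int Xo = out_size(X, stride), Yo = out_size(Y, stride),
            Zo = out_size(Z, stride);
  NumericVector dx((R_xlen_t)X * Y * Z * C);
  dx.attr("dim") = xd;
  NumericVector dwv(w.size());
  dwv.attr("dim") = wd;
  NumericVector db(Cout);
  if (stride == 1 && k > 1) {
    conv3d_direct_bw(REAL(x), REAL(w), REAL(dy), REAL(dx), REAL(dwv),
                     REAL(db), X, Y, Z, C, Cout, k);
    return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
  }
  arma::mat Wm(const_cast<double*>(REAL(w)), (size_t)k * k * k * C, Cout,
               false, true);
  arma::mat dY(const_cast<double*>(REAL(dy)), (size_t)Xo * Yo * Zo, Cout,
               false, true);
  arma::rowvec dbv = arma::sum(dY, 0);
  std::copy(dbv.begin(), dbv.end(), REAL(db));
  if (k == 1 && stride == 1) {
    arma::mat Xm(const_cast<double*>(REAL(x)), (size_t)X * Y * Z, C, false,
                 true);
    arma::mat dW = Xm.t() * dY;
    std::copy(dW.begin(), dW.end(), REAL(dwv));
    arma::mat dX = dY * Wm.t();
    std::copy(dX.begin(), dX.end(), REAL(dx));
  } else {
    arma::mat M = im2col3d(REAL(x), X, Y, Z, C, k, stride);
    arma::mat dW = M.t() * dY;
    std::copy(dW.begin(), dW.end(), REAL(dwv));
    arma::mat dM = dY * Wm.t();
    col2im3d(dM, REAL(dx), X, Y, Z, C, k, stride);
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// ======================= 2x2 max pooling =======================

// [[Rcpp::export(name = ".maxpool2d_fw_cpp")]]
List maxpool2d_fw_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C);
  IntegerVector idx((R_xlen_t)Ho * Wo * C); // 0-based linear index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double* px = REAL(x);
  double* py = REAL(y);
  int* pi = INTEGER(idx);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -1e300; R_xlen_t bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            R_xlen_t ii = (2 * ho + di) +
              (R_xlen_t)H * ((2 * wo + dj) + (R_xlen_t)W * c);
            if (px[ii] > best) { best = px[ii]; bi = ii; }
          }
        R_xlen_t o = ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * c);
        py[o] = best; pi[o] = (int)bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2d_bw_cpp")]]
NumericVector maxpool2d_bw_cpp(NumericVector dy, IntegerVector idx,
                               IntegerVector dimx) {
  NumericVector dx((R_xlen_t)dimx[0] * dimx[1] * dimx[2]);
  dx.attr("dim") = dimx;
  double* pdx = REAL(dx);
  const double* pdy = REAL(dy);
  const int* pi = INTEGER(idx);
  for (R_xlen_t p = 0; p < dy.size(); ++p) pdx[pi[p]] += pdy[p];
  return dx;
}

// ======================= activations =======================

// [[Rcpp::export(name = ".relu_fw_cpp")]]
NumericVector relu_fw_cpp(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* px = REAL(x);
  double* po = REAL(out);
  for (R_xlen_t i = 0; i < x.size(); ++i) po[i] = px[i] > 0 ? px[i] : 0.0;
  return out;
}

// [[Rcpp::export(name = ".relu_bw_cpp")]]
NumericVector relu_bw_cpp(NumericVector dy, NumericVector y) {
  NumericVector out(dy.size());
  out.attr("dim") = dy.attr("dim");
  const double* pd = REAL(dy);
  const double* py = REAL(y);
  double* po = REAL(out);
  for (R_xlen_t i = 0; i < dy.size(); ++i) po[i] = py[i] > 0 ? pd[i] : 0.0;
  return out;
}
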