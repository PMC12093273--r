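// Numerical kernels for the neural-network layers and for connected-component
// labeling. Convolutions use im2col + GEMM so the heavy lifting is a single
// BLAS call; arrays are R-native column-major with layout (X, Y, Z, C, N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword out_dim(arma::uword n, arma::uword k, arma::uword s,
                                  arma::uword p) {
  return (n + 2 * p - k) / s + 1;
}

// Gather the receptive fields of a 5-d input into a (kx*ky*kz*C) x (Xo*Yo*Zo*N)
// matrix. Out-of-range (padded) positions contribute zeros.
static arma::mat im2col(const arma::vec &x, const arma::uvec &dims,
                        const arma::uvec &k, const arma::uvec &s,
                        const arma::uvec &p, const arma::uvec &od) {
  const arma::uword X = dims[0], Y = dims[1], Z = dims[2], C = dims[3],
                    N = dims[4];
  const arma::uword Xo = od[0], Yo = od[1], Zo = od[2];
  const arma::uword K = k[0] * k[1] * k[2] * C;
  arma::mat cols(K, Xo * Yo * Zo * N, arma::fill::zeros);
  for (arma::uword n = 0; n < N; ++n) {
    for (arma::uword zo = 0; zo < Zo; ++zo) {
      for (arma::uword yo = 0; yo < Yo; ++yo) {
        for (arma::uword xo = 0; xo < Xo; ++xo) {
          const arma::uword col =
              xo + Xo * (yo + Yo * (zo + Zo * n));
          double *dst = cols.colptr(col);
          for (arma::uword c = 0; c < C; ++c) {
            for (arma::uword kz = 0; kz < k[2]; ++kz) {
              const long z = (long)(zo * s[2] + kz) - (long)p[2];
              for (arma::uword ky = 0; ky < k[1]; ++ky) {
                const long y = (long)(yo * s[1] + ky) - (long)p[1];
                for (arma::uword kx = 0; kx < k[0]; ++kx) {
                  const long xi = (long)(xo * s[0] + kx) - (long)p[0];
                  const arma::uword row =
                      kx + k[0] * (ky + k[1] * (kz + k[2] * c));
                  if (xi >= 0 && xi < (long)X && y >= 0 && y < (long)Y &&
                      z >= 0 && z < (long)Z) {
                    dst[row] = x[(arma::uword)xi +
                                 X * ((arma::uword)y +
                                      Y * ((arma::uword)z + Z * (c + C * n)))];
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add of a column matrix back onto the input grid (adjoint of im2col).
static void col2im(const arma::mat &cols, arma::vec &x, const arma::uvec &dims,
                   const arma::uvec &k, const arma::uvec &s,
                   const arma::uvec &p, const arma::uvec &od) {
  const arma::uword X = dims[0], Y = dims[1], Z = dims[2], C = dims[3],
                    N = dims[4];
  const arma::uword Xo = od[0], Yo = od[1], Zo = od[2];
  for (arma::uword n = 0; n < N; ++n) {
    for (arma::uword zo = 0; zo < Zo; ++zo) {
      for (arma::uword yo = 0; yo < Yo; ++yo) {
        for (arma::uword xo = 0; xo < Xo; ++xo) {
          const arma::uword col = xo + Xo * (yo + Yo * (zo + Zo * n));
          const double *src = cols.colptr(col);
          for (arma::uword c = 0; c < C; ++c) {
            for (arma::uword kz = 0; kz < k[2]; ++kz) {
              const long z = (long)(zo * s[2] + kz) - (long)p[2];
              for (arma::uword ky = 0; ky < k[1]; ++ky) {
                const long y = (long)(yo * s[1] + ky) - (long)p[1];
                for (arma::uword kx = 0; kx < k[0]; ++kx) {
                  const long xi = (long)(xo * s[0] + kx) - (long)p[0];
                  if (xi >= 0 && xi < (long)X && y >= 0 && y < (long)Y &&
                      z >= 0 && z < (long)Z) {
                    const arma::uword row =
                        kx + k[0] * (ky + k[1] * (kz + k[2] * c));
                    x[(arma::uword)xi +
                      X * ((arma::uword)y +
                           Y * ((arma::uword)z + Z * (c + C * n)))] += src[row];
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}

static arma::uvec uvec3(const IntegerVector &v) {
  arma::uvec out(3);
  for (int i = 0; i < 3; ++i) out[i] = (arma::uword)v[i];
  return out;
}

// [[Rcpp::export]]
NumericVector nm_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                            IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  arma::uvec dims(5), k(3), s = uvec3(stride), p = uvec3(pad);
  for (int i = 0; i < 5; ++i) dims[i] = (arma::uword)xd[i];
  for (int i = 0; i < 3; ++i) k[i] = (arma::uword)wd[i];
  const arma::uword Cin = (arma::uword)wd[3], Cout = (arma::uword)wd[4];
  if (dims[3] != Cin) stop("channel mismatch between input and kernel");
  arma::uvec od(3);
  for (int i = 0; i < 3; ++i) od[i] = out_dim(dims[i], k[i], s[i], p[i]);
  const arma::uword N = dims[4], M = od[0] * od[1] * od[2] * N;
  const arma::uword K = k[0] * k[1] * k[2] * Cin;

  arma::vec xv(x.begin(), x.size(), false);
  arma::mat cols = im2col(xv, dims, k, s, p, od);
  arma::mat W(w.begin(), K, Cout, false);
  arma::mat Y = W.t() * cols; // Cout x M

  NumericVector out(od[0] * od[1] * od[2] * Cout * N);
  out.attr("dim") = IntegerVector::create(od[0], od[1], od[2], Cout, N);
  const arma::uword XYZ = od[0] * od[1] * od[2];
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < Cout; ++c)
      for (arma::uword v = 0; v < XYZ; ++v)
        out[v + XYZ * (c + Cout * n)] = Y(c, v + XYZ * n) + b[c];
  return out;
}

// [[Rcpp::export]]
List nm_conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  arma::uvec dims(5), k(3), s = uvec3(stride), p = uvec3(pad), od(3);
  for (int i = 0; i < 5; ++i) dims[i] = (arma::uword)xd[i];
  for (int i = 0; i < 3; ++i) k[i] = (arma::uword)wd[i];
  for (int i = 0; i < 3; ++i) od[i] = (arma::uword)yd[i];
  const arma::uword Cin = (arma::uword)wd[3], Cout = (arma::uword)wd[4];
  const arma::uword N = dims[4], XYZ = od[0] * od[1] * od[2];
  const arma::uword K = k[0] * k[1] * k[2] * Cin, M = XYZ * N;

  // dy reshaped to Cout x M with column order matching im2col
  arma::mat dY(Cout, M);
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < Cout; ++c)
      for (arma::uword v = 0; v < XYZ; ++v)
        dY(c, v + XYZ * n) = dy[v + XYZ * (c + Cout * n)];

  arma::vec xv(x.begin(), x.size(), false);
  arma::mat cols = im2col(xv, dims, k, s, p, od);
  arma::mat W(w.begin(), K, Cout, false);

  arma::mat dW = cols * dY.t(); // K x Cout
  arma::vec db = arma::sum(dY, 1);
  arma::mat dcols = W * dY; // K x M

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::vec dxv(dx.begin(), dx.size(), false);
  col2im(dcols, dxv, dims, k, s, p, od);

  NumericVector dwv(w.size());
  dwv.attr("dim") = wd;
  std::copy(dW.begin(), dW.end(), dwv.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Transposed convolution, kernel 2x2x2, stride 2 (non-overlapping upsampling).
// [[Rcpp::export]]
NumericVector nm_convt3d_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3], N = xd[4];
  const int Cout = wd[4];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector out((double)Xo * Yo * Zo * Cout * N);
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Cout, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double bias = b[co];
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y)
          for (int xq = 0; xq < Xo; ++xq)
            out[(size_t)xq +
                (size_t)Xo * (y + (size_t)Yo * (z + (size_t)Zo *
                                                        (co + (size_t)Cout * n)))] =
                bias;
      for (int ci = 0; ci < Cin; ++ci)
        for (int z = 0; z < Z; ++z)
          for (int y = 0; y < Y; ++y)
            for (int xq = 0; xq < X; ++xq) {
              const double v =
                  x[(size_t)xq +
                    (size_t)X * (y + (size_t)Y * (z + (size_t)Z *
                                                          (ci + (size_t)Cin * n)))];
              if (v == 0.0) continue;
              for (int k2 = 0; k2 < 2; ++k2)
                for (int k1 = 0; k1 < 2; ++k1)
                  for (int k0 = 0; k0 < 2; ++k0) {
                    const double wv =
                        w[k0 + 2 * (k1 + 2 * (k2 + 2 * (ci + Cin * co)))];
                    out[(size_t)(2 * xq + k0) +
                        (size_t)Xo *
                            ((2 * y + k1) +
                             (size_t)Yo * ((2 * z + k2) +
                                           (size_t)Zo * (co + (size_t)Cout * n)))] +=
                        v * wv;
                  }
            }
    }
  return out;
}

// [[Rcpp::export]]
List nm_convt3d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3], N = xd[4];
  const int Cout = wd[4];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector dx(x.size()), dw(w.size()), db(Cout);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double accb = 0.0;
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y)
          for (int xq = 0; xq < Xo; ++xq)
            accb += dy[(size_t)xq +
                       (size_t)Xo *
                           (y + (size_t)Yo *
                                    (z + (size_t)Zo * (co + (size_t)Cout * n)))];
      db[co] += accb;
      for (int ci = 0; ci < Cin; ++ci)
        for (int z = 0; z < Z; ++z)
          for (int y = 0; y < Y; ++y)
            for (int xq = 0; xq < X; ++xq) {
              const size_t xi =
                  (size_t)xq +
                  (size_t)X * (y + (size_t)Y * (z + (size_t)Z *
                                                        (ci + (size_t)Cin * n)));
              const double xv = x[xi];
              double acc = 0.0;
              for (int k2 = 0; k2 < 2; ++k2)
                for (int k1 = 0; k1 < 2; ++k1)
                  for (int k0 = 0; k0 < 2; ++k0) {
                    const size_t yi =
                        (size_t)(2 * xq + k0) +
                        (size_t)Xo *
                            ((2 * y + k1) +
                             (size_t)Yo * ((2 * z + k2) +
                                           (size_t)Zo * (co + (size_t)Cout * n)));
                    const size_t wi =
                        k0 + 2 * (k1 + 2 * (k2 + 2 * ((size_t)ci + (size_t)Cin * co)));
                    acc += w[wi] * dy[yi];
                    dw[wi] += xv * dy[yi];
                  }
              dx[xi] += acc;
            }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Connected-component labeling of a binary 3D grid under 6/18/26-connectivity.
// [[Rcpp::export]]
List nm_label_components(IntegerVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2];
  // neighbor offsets for the requested connectivity
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int nnz = (dx != 0) + (dy != 0) + (dz != 0);
        if (nnz == 0) continue;
        if (connectivity == 6 && nnz > 1) continue;
        if (connectivity == 18 && nnz > 2) continue;
        nb.push_back({dx, dy, dz});
      }
  IntegerVector labels((size_t)X * Y * Z);
  labels.attr("dim") = d;
  int next = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < (size_t)X * Y * Z; ++i) {
    if (mask[i] == 0 || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int cx = cur % X, cy = (cur / X) % Y, cz = cur / ((size_t)X * Y);
      for (const auto &o : nb) {
        const int nx = cx + o[0], ny = cy + o[1], nz = cz + o[2];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
          continue;
        const size_t ni = (size_t)nx + (size_t)X * (ny + (size_t)Y * nz);
        if (mask[ni] != 0 && labels[ni] == 0) {
          labels[ni] = next;
          stack.push_back(ni);
        }
      }
    }
  }
  return List::create(_["labels"] = labels, _["n"] = next);
}
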