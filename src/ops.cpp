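// Low-level numerical kernels for the 3-D segmentation networks.
//
// Tensor layout: a batch of B patches of spatial shape (X, Y, Z) with C
// channels is a (B*nvox) x C double matrix, nvox = X*Y*Z, voxel index
// v = x + X*(y + Y*z) (x fastest), patch b occupying rows [b*nvox, (b+1)*nvox).
// All convolutions are stride-1, zero-padded "same", kernel 3x3x3; 1x1x1
// convolutions are plain matrix products and live on the R side.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int voxid(int x, int y, int z, int X, int Y) {
  return x + X * (y + Y * z);
}

// im2col for one patch in single precision:
// col(v, o*Cin + c) = X(neigh(v, o), c), zero outside the patch.
// Offset index o = (dx+1) + 3*(dy+1) + 9*(dz+1), dx/dy/dz in {-1,0,1}.
// Only out-of-bounds rows are zeroed (the bulk is overwritten anyway).
static void im2col3f(const arma::fmat& Xm, int row0, int X, int Y, int Z,
                     arma::fmat& col) {
  const int Cin = Xm.n_cols;
  for (int o = 0; o < 27; ++o) {
    const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
    const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
    const int y0 = std::max(0, -dy), y1 = std::min(Y, Y - dy);
    const int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
    for (int c = 0; c < Cin; ++c) {
      const float* src = Xm.colptr(c) + row0;
      float* dst = col.colptr(o * Cin + c);
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y) {
          float* drow = dst + voxid(0, y, z, X, Y);
          if (z < z0 || z >= z1 || y < y0 || y >= y1) {
            std::fill(drow, drow + X, 0.0f);
          } else {
            const float* srow = src + voxid(x0 + dx, y + dy, z + dz, X, Y);
            if (x0 > 0) std::fill(drow, drow + x0, 0.0f);
            std::copy(srow, srow + (x1 - x0), drow + x0);
            if (x1 < X) std::fill(drow + x1, drow + X, 0.0f);
          }
        }
    }
  }
}

static arma::fmat to_f(const NumericMatrix& M) {
  arma::fmat F(M.nrow(), M.ncol());
  const double* s = M.begin();
  float* d = F.memptr();
  const R_xlen_t n = (R_xlen_t)M.nrow() * M.ncol();
  for (R_xlen_t i = 0; i < n; ++i) d[i] = (float)s[i];
  return F;
}

static NumericMatrix to_d(const arma::fmat& F) {
  NumericMatrix M(F.n_rows, F.n_cols);
  const float* s = F.memptr();
  double* d = M.begin();
  const R_xlen_t n = (R_xlen_t)F.n_rows * F.n_cols;
  for (R_xlen_t i = 0; i < n; ++i) d[i] = (double)s[i];
  return M;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3_fw(NumericMatrix Xin, IntegerVector dims, int B,
                           NumericMatrix Win, NumericVector b) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int nvox = X * Y * Z;
  arma::fmat Xm = to_f(Xin), W = to_f(Win);
  const int Cin = Xm.n_cols, Cout = W.n_cols;
  arma::fmat out(B * nvox, Cout);
  arma::fmat col(nvox, 27 * Cin);
  for (int p = 0; p < B; ++p) {
    im2col3f(Xm, p * nvox, X, Y, Z, col);
    out.rows(p * nvox, (p + 1) * nvox - 1) = col * W;
  }
  for (int c = 0; c < Cout; ++c) out.col(c) += (float)b[c];
  return to_d(out);
}

// [[Rcpp::export]]
List cpp_conv3_bw(NumericMatrix Xin, IntegerVector dims, int B,
                  NumericMatrix Win, NumericMatrix dYin) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int nvox = X * Y * Z;
  arma::fmat Xm = to_f(Xin), W = to_f(Win), dY = to_f(dYin);
  const int Cin = Xm.n_cols;
  arma::fmat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::fmat dX(Xm.n_rows, Cin, arma::fill::zeros);
  arma::fmat col(nvox, 27 * Cin);
  for (int p = 0; p < B; ++p) {
    const int r0 = p * nvox, r1 = (p + 1) * nvox - 1;
    im2col3f(Xm, r0, X, Y, Z, col);
    dW += col.t() * dY.rows(r0, r1);
    arma::fmat G = dY.rows(r0, r1) * W.t();  // nvox x 27*Cin
    // scatter: dX(neigh(v,o), c) += G(v, o*Cin + c)
    for (int o = 0; o < 27; ++o) {
      const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
      const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
      for (int c = 0; c < Cin; ++c) {
        const float* src = G.colptr(o * Cin + c);
        float* dst = dX.colptr(c) + r0;
        for (int z = std::max(0, -dz); z < std::min(Z, Z - dz); ++z)
          for (int y = std::max(0, -dy); y < std::min(Y, Y - dy); ++y) {
            const int vrow = voxid(x0, y, z, X, Y);
            const int srow = voxid(x0 + dx, y + dy, z + dz, X, Y);
            for (int i = 0; i < x1 - x0; ++i) dst[srow + i] += src[vrow + i];
          }
      }
    }
  }
  arma::frowvec db = arma::sum(dY, 0);
  return List::create(_["dX"] = to_d(dX), _["dW"] = to_d(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2x2 max-pool, stride 2; records the flat source row of each maximum.
// [[Rcpp::export]]
List cpp_maxpool_fw(const arma::mat& Xm, IntegerVector dims, int B) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const int nvox = X * Y * Z, novox = Xo * Yo * Zo, C = Xm.n_cols;
  arma::mat out(B * novox, C);
  IntegerMatrix idx(B * novox, C);
  for (int p = 0; p < B; ++p) {
    for (int c = 0; c < C; ++c) {
      const double* src = Xm.colptr(c) + p * nvox;
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y)
          for (int x = 0; x < Xo; ++x) {
            double best = -1e300; int bestv = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const int v = voxid(2 * x + dx, 2 * y + dy, 2 * z + dz, X, Y);
                  if (src[v] > best) { best = src[v]; bestv = v; }
                }
            const int ov = p * novox + voxid(x, y, z, Xo, Yo);
            out(ov, c) = best;
            idx(ov, c) = p * nvox + bestv;  // 0-based row in Xm
          }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bw(const arma::mat& dY, IntegerMatrix idx, int nrowX) {
  const int C = dY.n_cols, n = dY.n_rows;
  arma::mat dX(nrowX, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < n; ++i) dX(idx(i, c), c) += dY(i, c);
  return dX;
}

// [[Rcpp::export]]
arma::mat cpp_avgpool_fw(const arma::mat& Xm, IntegerVector dims, int B) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const int nvox = X * Y * Z, novox = Xo * Yo * Zo, C = Xm.n_cols;
  arma::mat out(B * novox, C, arma::fill::zeros);
  for (int p = 0; p < B; ++p)
    for (int c = 0; c < C; ++c) {
      const double* src = Xm.colptr(c) + p * nvox;
      double* dst = out.colptr(c) + p * novox;
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y)
          for (int x = 0; x < Xo; ++x) {
            double s = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx)
                  s += src[voxid(2 * x + dx, 2 * y + dy, 2 * z + dz, X, Y)];
            dst[voxid(x, y, z, Xo, Yo)] = s / 8.0;
          }
    }
  return out;
}

// Nearest-neighbour x2 upsampling along all three axes.
// [[Rcpp::export]]
arma::mat cpp_upsample_fw(const arma::mat& Xm, IntegerVector dims, int B) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const int nvox = X * Y * Z, novox = Xo * Yo * Zo, C = Xm.n_cols;
  arma::mat out(B * novox, C);
  for (int p = 0; p < B; ++p)
    for (int c = 0; c < C; ++c) {
      const double* src = Xm.colptr(c) + p * nvox;
      double* dst = out.colptr(c) + p * novox;
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y) {
          const int srow = voxid(0, y / 2, z / 2, X, Y);
          const int drow = voxid(0, y, z, Xo, Yo);
          for (int x = 0; x < Xo; ++x) dst[drow + x] = src[srow + x / 2];
        }
    }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_upsample_bw(const arma::mat& dY, IntegerVector dims_in, int B) {
  const int X = dims_in[0], Y = dims_in[1], Z = dims_in[2];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const int nvox = X * Y * Z, novox = Xo * Yo * Zo, C = dY.n_cols;
  arma::mat dX(B * nvox, C, arma::fill::zeros);
  for (int p = 0; p < B; ++p)
    for (int c = 0; c < C; ++c) {
      double* dst = dX.colptr(c) + p * nvox;
      const double* src = dY.colptr(c) + p * novox;
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y) {
          const int drow = voxid(0, y / 2, z / 2, X, Y);
          const int srow = voxid(0, y, z, Xo, Yo);
          for (int x = 0; x < Xo; ++x) dst[drow + x / 2] += src[srow + x];
        }
    }
  return dX;
}

// [[Rcpp::export]]
List cpp_colstats(const arma::mat& Xm) {
  arma::rowvec mu = arma::mean(Xm, 0);
  arma::rowvec va = arma::var(Xm, 1, 0);  // population variance
  return List::create(_["mean"] = arma::vec(mu.t()), _["var"] = arma::vec(va.t()));
}

// [[Rcpp::export]]
arma::mat cpp_bn_fw(const arma::mat& Xm, const arma::vec& mean,
                    const arma::vec& invstd, const arma::vec& gamma,
                    const arma::vec& beta) {
  arma::mat out(Xm.n_rows, Xm.n_cols);
  for (unsigned c = 0; c < Xm.n_cols; ++c) {
    const double a = gamma[c] * invstd[c];
    const double b = beta[c] - a * mean[c];
    out.col(c) = a * Xm.col(c) + b;
  }
  return out;
}

// Batch-norm backward using batch statistics (training mode).
// [[Rcpp::export]]
List cpp_bn_bw(const arma::mat& Xm, const arma::mat& dY, const arma::vec& mean,
               const arma::vec& invstd, const arma::vec& gamma) {
  const double N = (double)Xm.n_rows;
  const int C = Xm.n_cols;
  arma::mat dX(Xm.n_rows, C);
  arma::vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    arma::vec xhat = (Xm.col(c) - mean[c]) * invstd[c];
    const double db = arma::accu(dY.col(c));
    const double dg = arma::dot(dY.col(c), xhat);
    dgamma[c] = dg; dbeta[c] = db;
    dX.col(c) = (gamma[c] * invstd[c]) * (dY.col(c) - db / N - xhat * (dg / N));
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
arma::mat cpp_relu_fw(const arma::mat& Xm) {
  return arma::clamp(Xm, 0.0, arma::datum::inf);
}

// [[Rcpp::export]]
arma::mat cpp_relu_bw(const arma::mat& Ym, const arma::mat& dY) {
  return dY % (Ym > 0);
}

// [[Rcpp::export]]
arma::mat cpp_sigmoid(const arma::mat& Xm) {
  return 1.0 / (1.0 + arma::exp(-Xm));
}

// Sliding box-mean with replicate padding, separable along the three axes.
// Window w covers offsets [-floor(w/2), w - 1 - floor(w/2)].
// [[Rcpp::export]]
NumericVector cpp_boxmean(NumericVector arr, IntegerVector dims, int w) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int lo = w / 2, hi = w - 1 - w / 2;
  std::vector<double> a(arr.begin(), arr.end()), tmp(a.size());
  // pass along axis with length L, stride s, line count and line starts
  auto pass = [&](int axis) {
    const int L = dims[axis];
    std::vector<double> line(L), out(L);
    for (int z = 0; z < (axis == 2 ? 1 : Z); ++z)
      for (int y = 0; y < (axis == 1 ? 1 : Y); ++y)
        for (int x = 0; x < (axis == 0 ? 1 : X); ++x) {
          for (int i = 0; i < L; ++i) {
            const int xi = axis == 0 ? i : x, yi = axis == 1 ? i : y,
                      zi = axis == 2 ? i : z;
            line[i] = a[voxid(xi, yi, zi, X, Y)];
          }
          for (int i = 0; i < L; ++i) {
            double s = 0;
            for (int t = i - lo; t <= i + hi; ++t)
              s += line[std::min(std::max(t, 0), L - 1)];
            out[i] = s / w;
          }
          for (int i = 0; i < L; ++i) {
            const int xi = axis == 0 ? i : x, yi = axis == 1 ? i : y,
                      zi = axis == 2 ? i : z;
            tmp[voxid(xi, yi, zi, X, Y)] = out[i];
          }
        }
    a.swap(tmp);
  };
  pass(0); pass(1); pass(2);
  NumericVector res(a.begin(), a.end());
  res.attr("dim") = dims;
  return res;
}

// For every row of A (n x 3 voxel coordinates), the minimum Euclidean
// distance to any row of B, axes scaled by `spacing`.
// [[Rcpp::export]]
arma::vec cpp_nnmin(const arma::mat& A, const arma::mat& Bm,
                    const arma::vec& spacing) {
  const int nA = A.n_rows, nB = Bm.n_rows;
  arma::vec out(nA);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int i = 0; i < nA; ++i) {
    const double ax = A(i, 0) * sx, ay = A(i, 1) * sy, az = A(i, 2) * sz;
    double best = arma::datum::inf;
    for (int j = 0; j < nB; ++j) {
      const double dx = ax - Bm(j, 0) * sx, dy = ay - Bm(j, 1) * sy,
                   dz = az - Bm(j, 2) * sz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
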