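// 2-D cross-correlation ("conv") with same padding, plus exact backward passes.
// Layout conventions (match R's column-major arrays):
//   feature stacks: cube [H, W, C]
//   weights: mat [C_out, s*s*C_in]; column index r = ki + s*kj + s*s*ci
//   (ki = kernel row offset, kj = kernel col offset, ci = input channel),
//   i.e. W = t(matrix(kernel_array, s*s*C_in, C_out)) for kernel dims [s,s,C_in,C_out].
// padding: 0 = zeros, 1 = circular (wrap). Circular padding keeps integer
// translations exactly equivariant, which the equivariance test harness relies on.
//
// The im2col gather and its transpose scatter are written with whole-submatrix
// (or circular-shift) operations per kernel offset, and the forward pass can
// cache the im2col matrix for reuse in the backward pass.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// S(h, w) = x(h + di, w + dj), zero or circular boundary
static mat shifted_plane(const mat& x, int di, int dj, int padding) {
  const int H = x.n_rows, W = x.n_cols;
  if (padding == 1) {
    return shift(shift(x, -di, 0), -dj, 1);
  }
  mat S(H, W, fill::zeros);
  const int r0 = std::max(0, -di), r1 = std::min(H, H - di);
  const int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
  if (r1 > r0 && c1 > c0) {
    S.submat(r0, c0, r1 - 1, c1 - 1) =
      x.submat(r0 + di, c0 + dj, r1 - 1 + di, c1 - 1 + dj);
  }
  return S;
}

// transpose of shifted_plane: acc(h + di, w + dj) += R(h, w)
static void scatter_plane(mat& acc, const mat& R, int di, int dj,
                          int padding) {
  const int H = acc.n_rows, W = acc.n_cols;
  if (padding == 1) {
    acc += shift(shift(R, di, 0), dj, 1);
    return;
  }
  const int r0 = std::max(0, -di), r1 = std::min(H, H - di);
  const int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
  if (r1 > r0 && c1 > c0) {
    acc.submat(r0 + di, c0 + dj, r1 - 1 + di, c1 - 1 + dj) +=
      R.submat(r0, c0, r1 - 1, c1 - 1);
  }
}

// im2col matrix: rows s*s*C_in (ki fastest, then kj, then ci), cols H*W
static mat im2col(const cube& x, int s, int padding) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (s - 1) / 2;
  mat X(s * s * C, H * W);
  for (int ci = 0; ci < C; ++ci) {
    for (int kj = 0; kj < s; ++kj) {
      for (int ki = 0; ki < s; ++ki) {
        X.row(ki + s * kj + s * s * ci) =
          vectorise(shifted_plane(x.slice(ci), ki - p, kj - p, padding)).t();
      }
    }
  }
  return X;
}

static cube mat_to_cube(const mat& Y, int H, int W) {
  cube out(H, W, Y.n_rows);
  for (uword co = 0; co < Y.n_rows; ++co) {
    out.slice(co) = reshape(Y.row(co).t(), H, W);
  }
  return out;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const arma::mat& W,
                          const arma::vec& bias, int s, int padding) {
  mat Y = W * im2col(x, s, padding);
  Y.each_col() += bias;
  return mat_to_cube(Y, x.n_rows, x.n_cols);
}

// forward pass that also returns the im2col matrix for the backward pass
// [[Rcpp::export]]
Rcpp::List conv2d_fwd_tape_cpp(const arma::cube& x, const arma::mat& W,
                               const arma::vec& bias, int s, int padding) {
  mat X = im2col(x, s, padding);
  mat Y = W * X;
  Y.each_col() += bias;
  return Rcpp::List::create(
    Rcpp::Named("out") = mat_to_cube(Y, x.n_rows, x.n_cols),
    Rcpp::Named("X") = X);
}

// backward pass from the cached im2col matrix
// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(const arma::mat& X, const arma::mat& W,
                          const arma::cube& gy, int s, int padding) {
  const int H = gy.n_rows, Wd = gy.n_cols;
  const int C_out = gy.n_slices;
  const int C_in = X.n_rows / (s * s);
  const int p = (s - 1) / 2;
  mat dY(C_out, H * Wd);
  for (int co = 0; co < C_out; ++co) {
    dY.row(co) = vectorise(gy.slice(co)).t();
  }
  mat dW = dY * X.t();
  vec db = sum(dY, 1);
  mat dXcol = W.t() * dY;
  cube dx(H, Wd, C_in, fill::zeros);
  for (int ci = 0; ci < C_in; ++ci) {
    mat& dxc = dx.slice(ci);
    for (int kj = 0; kj < s; ++kj) {
      for (int ki = 0; ki < s; ++ki) {
        mat R = reshape(dXcol.row(ki + s * kj + s * s * ci).t(), H, Wd);
        scatter_plane(dxc, R, ki - p, kj - p, padding);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dx);
}
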