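// Dense 3D convolution primitives used by the residual dense encoder.
//
// Feature maps are stored as C x N matrices where N = d1*d2*d3 voxels in
// column-major (first-index-fastest) order, matching how an R array of
// dim c(d1, d2, d3) flattens. Convolutions use odd kernels with zero
// padding of (k-1)/2 so spatial dimensions are preserved (required by the
// elementwise global residual). The im2col buffer is laid out tap-major:
// row (t * C_in + c) holds channel c at kernel tap t, so a weight matrix
// of shape C_out x (C_in * k^3) turns the convolution into one GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col3d(const arma::mat& x, int d1, int d2, int d3, int k) {
  const int cin = x.n_rows;
  const int n = d1 * d2 * d3;
  const int p = (k - 1) / 2;
  const int k3 = k * k * k;
  arma::mat col(cin * k3, n, arma::fill::zeros);

  int t = 0;
  for (int dz = -p; dz <= p; ++dz) {
    for (int dy = -p; dy <= p; ++dy) {
      for (int dx = -p; dx <= p; ++dx, ++t) {
        const int r0 = t * cin;
        for (int iz = 0; iz < d3; ++iz) {
          const int sz = iz + dz;
          if (sz < 0 || sz >= d3) continue;
          for (int iy = 0; iy < d2; ++iy) {
            const int sy = iy + dy;
            if (sy < 0 || sy >= d2) continue;
            const int x0 = std::max(0, -dx);
            const int x1 = std::min(d1, d1 - dx);
            if (x0 >= x1) continue;
            const int dst0 = x0 + d1 * (iy + d2 * iz);
            const int src0 = (x0 + dx) + d1 * (sy + d2 * sz);
            // contiguous run over the fastest axis
            col.submat(r0, dst0, r0 + cin - 1, dst0 + (x1 - x0) - 1) =
              x.cols(src0, src0 + (x1 - x0) - 1);
          }
        }
      }
    }
  }
  return col;
}

static arma::mat col2im3d(const arma::mat& dcol, int cin, int d1, int d2,
                          int d3, int k) {
  const int n = d1 * d2 * d3;
  const int p = (k - 1) / 2;
  arma::mat dx(cin, n, arma::fill::zeros);

  int t = 0;
  for (int dz = -p; dz <= p; ++dz) {
    for (int dy = -p; dy <= p; ++dy) {
      for (int dxo = -p; dxo <= p; ++dxo, ++t) {
        const int r0 = t * cin;
        for (int iz = 0; iz < d3; ++iz) {
          const int sz = iz + dz;
          if (sz < 0 || sz >= d3) continue;
          for (int iy = 0; iy < d2; ++iy) {
            const int sy = iy + dy;
            if (sy < 0 || sy >= d2) continue;
            const int x0 = std::max(0, -dxo);
            const int x1 = std::min(d1, d1 - dxo);
            if (x0 >= x1) continue;
            const int dst0 = x0 + d1 * (iy + d2 * iz);
            const int src0 = (x0 + dxo) + d1 * (sy + d2 * sz);
            dx.cols(src0, src0 + (x1 - x0) - 1) +=
              dcol.submat(r0, dst0, r0 + cin - 1, dst0 + (x1 - x0) - 1);
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::mat conv3d_fw_cpp(const arma::mat& x, const arma::mat& w,
                        const arma::vec& b, const IntegerVector& dims,
                        int k) {
  arma::mat col = im2col3d(x, dims[0], dims[1], dims[2], k);
  arma::mat y = w * col;
  y.each_col() += b;
  return y;
}

// Elementwise rectifier and its backward pass, kept in C++ because the
// decoder applies them to C x N matrices spanning the full output grid.
// [[Rcpp::export]]
arma::mat relu_cpp(const arma::mat& x) {
  arma::mat y(x.n_rows, x.n_cols);
  const double* px = x.memptr();
  double* py = y.memptr();
  const arma::uword n = x.n_elem;
  for (arma::uword i = 0; i < n; ++i) py[i] = px[i] > 0.0 ? px[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
arma::mat drelu_cpp(const arma::mat& dy, const arma::mat& h) {
  arma::mat dx(dy.n_rows, dy.n_cols);
  const double* pd = dy.memptr();
  const double* ph = h.memptr();
  double* po = dx.memptr();
  const arma::uword n = dy.n_elem;
  for (arma::uword i = 0; i < n; ++i) po[i] = ph[i] > 0.0 ? pd[i] : 0.0;
  return dx;
}

// [[Rcpp::export]]
List conv3d_bw_cpp(const arma::mat& x, const arma::mat& w,
                   const arma::mat& dy, const IntegerVector& dims, int k) {
  // The im2col buffer is recomputed rather than cached between the forward
  // and backward passes: it is k^3 times the activation size and memory-,
  // not compute-, bound.
  arma::mat col = im2col3d(x, dims[0], dims[1], dims[2], k);
  arma::mat dw = dy * col.t();
  arma::vec db = arma::sum(dy, 1);
  arma::mat dcol = w.t() * dy;
  arma::mat dx = col2im3d(dcol, x.n_rows, dims[0], dims[1], dims[2], k);
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}
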