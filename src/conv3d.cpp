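#include <Rcpp.h>
#include <vector>

// Separable 3D convolution (zero-padded) of a voxels-by-time matrix whose
// rows follow column-major (x fastest) voxel order.  Hot path for Gaussian
// smoothing of 4D series and Monte-Carlo null fields.

namespace {

void conv_lines(double* data, int n_lines, int line_len, R_xlen_t stride,
                R_xlen_t line_step, const double* k, int r,
                std::vector<double>& buf) {
  for (int l = 0; l < n_lines; ++l) {
    double* base = data + static_cast<R_xlen_t>(l) * line_step;
    for (int i = 0; i < line_len; ++i) buf[i] = base[static_cast<R_xlen_t>(i) * stride];
    for (int i = 0; i < line_len; ++i) {
      int lo = i - r < 0 ? 0 : i - r;
      int hi = i + r >= line_len ? line_len - 1 : i + r;
      double acc = 0.0;
      for (int j = lo; j <= hi; ++j) acc += k[j - i + r] * buf[j];
      base[static_cast<R_xlen_t>(i) * stride] = acc;
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".conv3d_sep")]]
Rcpp::NumericMatrix conv3d_sep(Rcpp::NumericMatrix X, Rcpp::IntegerVector dims,
                               Rcpp::NumericVector kx, Rcpp::NumericVector ky,
                               Rcpp::NumericVector kz) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t V = static_cast<R_xlen_t>(d1) * d2 * d3;
  if (X.nrow() != V) Rcpp::stop("grid error: rows != prod(dims)");
  Rcpp::NumericMatrix out = Rcpp::clone(X);
  const int rx = (kx.size() - 1) / 2, ry = (ky.size() - 1) / 2,
            rz = (kz.size() - 1) / 2;
  std::vector<double> buf(std::max(d1, std::max(d2, d3)));
  std::vector<double> col(V);
  for (int t = 0; t < out.ncol(); ++t) {
    double* c = &out(0, t);
    // x axis: d2*d3 contiguous lines of length d1
    if (kx.size() > 1)
      conv_lines(c, d2 * d3, d1, 1, d1, kx.begin(), rx, buf);
    // y axis: for each z-slab, d1 lines of length d2 with stride d1
    if (ky.size() > 1)
      for (int z = 0; z < d3; ++z)
        conv_lines(c + static_cast<R_xlen_t>(z) * d1 * d2, d1, d2, d1, 1,
                   ky.begin(), ry, buf);
    // z axis: d1*d2 lines of length d3 with stride d1*d2
    if (kz.size() > 1)
      conv_lines(c, d1 * d2, d3, static_cast<R_xlen_t>(d1) * d2, 1,
                 kz.begin(), rz, buf);
  }
  return out;
}
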