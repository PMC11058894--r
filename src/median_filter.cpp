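#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// Running median filter over a 3D volume with box radii (rx, ry, rz) and
// replicated edges. A 2D filter is the rz = 0 case with nz = 1 (or any nz,
// applied slice-wise from R). Kernel size is always odd, so the median is the
// middle order statistic.
// [[Rcpp::export]]
NumericVector median_filter_box(NumericVector vol, IntegerVector dims,
                                int rx, int ry, int rz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != vol.size())
    stop("dims do not match volume length");
  NumericVector out(vol.size());
  const int ksize = (2 * rx + 1) * (2 * ry + 1) * (2 * rz + 1);
  std::vector<double> buf(ksize);
  const int mid = ksize / 2;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int m = 0;
        for (int dk = -rz; dk <= rz; ++dk) {
          const int kk = clampi(k + dk, 0, nz - 1);
          for (int dj = -ry; dj <= ry; ++dj) {
            const int jj = clampi(j + dj, 0, ny - 1);
            const R_xlen_t base = (R_xlen_t)(kk * ny + jj) * nx;
            for (int di = -rx; di <= rx; ++di) {
              const int ii = clampi(i + di, 0, nx - 1);
              buf[m++] = vol[base + ii];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        out[(R_xlen_t)(k * ny + j) * nx + i] = buf[mid];
      }
    }
  }
  return out;
}
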