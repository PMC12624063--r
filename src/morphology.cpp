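#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Binary dilation of a 3D mask by an explicit list of integer voxel offsets.
// `mask` is a logical vector in column-major order with dimensions `dim`
// (length 3); `offsets` is an n x 3 integer matrix of (di, dj, dk) offsets.
// Offsets falling outside the grid are clipped (dilation is truncated at the
// image border, the usual convention for binary morphology on finite grids).
// [[Rcpp::export]]
LogicalVector dilate_mask_cpp(LogicalVector mask, IntegerVector dim,
                              IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  LogicalVector out(n, false);
  const int noff = offsets.nrow();
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[idx]) continue;
        for (int o = 0; o < noff; ++o) {
          const int ii = i + offsets(o, 0);
          const int jj = j + offsets(o, 1);
          const int kk = k + offsets(o, 2);
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          out[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)] = true;
        }
      }
    }
  }
  return out;
}

// Connected-component labeling of each axial slice independently.
// Slices are taken along the third array dimension; components are never
// merged across slices and labels are unique over the whole volume.
// connectivity: 4 (edge neighbors) or 8 (edge + diagonal neighbors) in-plane.
// [[Rcpp::export]]
IntegerVector label_slices_cpp(LogicalVector mask, IntegerVector dim,
                               int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerVector labels(n, 0);
  const int ndirs = (connectivity == 4) ? 4 : 8;
  const int dx[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  int next_label = 0;
  std::queue<std::pair<int, int> > q;
  for (int k = 0; k < nz; ++k) {
    const R_xlen_t base = (R_xlen_t)nx * ny * k;
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = base + i + (R_xlen_t)nx * j;
        if (!mask[idx] || labels[idx] != 0) continue;
        ++next_label;
        labels[idx] = next_label;
        q.push(std::make_pair(i, j));
        while (!q.empty()) {
          const int ci = q.front().first, cj = q.front().second;
          q.pop();
          for (int d = 0; d < ndirs; ++d) {
            const int ii = ci + dx[d], jj = cj + dy[d];
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
            const R_xlen_t nidx = base + ii + (R_xlen_t)nx * jj;
            if (mask[nidx] && labels[nidx] == 0) {
              labels[nidx] = next_label;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return labels;
}
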