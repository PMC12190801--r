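#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D connected-component labelling on a logical array, BFS with an explicit
// queue.  connectivity is 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  const int nn = (int)offx.size();

  std::vector<R_xlen_t> queue;
  int current = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int z = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v % ((R_xlen_t)nx * ny));
      int y = rem / nx, x = rem % nx;
      for (int k = 0; k < nn; ++k) {
        int xx = x + offx[k], yy = y + offy[k], zz = z + offz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          queue.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Slice-wise hole filling: for every z-slice, background voxels (mask == 0)
// not reachable from the slice border by 4-connected background steps are
// holes and get filled.  4-connected background corresponds to 8-connected
// foreground.
// [[Rcpp::export(name = ".fill_holes_slicewise")]]
LogicalVector fill_holes_slicewise(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  LogicalVector out = clone(mask);

  std::vector<char> reached((size_t)nx * ny);
  std::vector<int> queue;
  const int dx4[4] = {1, -1, 0, 0};
  const int dy4[4] = {0, 0, 1, -1};

  for (int z = 0; z < nz; ++z) {
    const R_xlen_t base = (R_xlen_t)z * nx * ny;
    std::fill(reached.begin(), reached.end(), 0);
    queue.clear();
    // seed from all four borders of the slice
    for (int x = 0; x < nx; ++x) {
      for (int y : {0, ny - 1}) {
        int idx = y * nx + x;
        if (!mask[base + idx] && !reached[idx]) { reached[idx] = 1; queue.push_back(idx); }
      }
    }
    for (int y = 0; y < ny; ++y) {
      for (int x : {0, nx - 1}) {
        int idx = y * nx + x;
        if (!mask[base + idx] && !reached[idx]) { reached[idx] = 1; queue.push_back(idx); }
      }
    }
    while (!queue.empty()) {
      int v = queue.back(); queue.pop_back();
      int y = v / nx, x = v % nx;
      for (int k = 0; k < 4; ++k) {
        int xx = x + dx4[k], yy = y + dy4[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
        int w = yy * nx + xx;
        if (!mask[base + w] && !reached[w]) { reached[w] = 1; queue.push_back(w); }
      }
    }
    for (int idx = 0; idx < nx * ny; ++idx)
      if (!mask[base + idx] && !reached[idx]) out[base + idx] = true;
  }
  out.attr("dim") = dims;
  return out;
}
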