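#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation, 8-connectivity.
// Hybrid raster/queue algorithm (two raster sweeps, then FIFO propagation).
// Requires marker <= mask pointwise; checked in the R wrapper.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J = clone(marker);
  std::queue<int> fifo;

  // forward sweep: neighbours preceding (r,c) in column-major scan order
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = J(r, c);
      if (c > 0) {
        if (r > 0)      m = std::max(m, J(r - 1, c - 1));
                        m = std::max(m, J(r,     c - 1));
        if (r < nr - 1) m = std::max(m, J(r + 1, c - 1));
      }
      if (r > 0)        m = std::max(m, J(r - 1, c));
      J(r, c) = std::min(m, mask(r, c));
    }
  }
  // backward sweep + queue seeding
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double m = J(r, c);
      int qr[4], qc[4], k = 0;
      if (c < nc - 1) {
        if (r > 0)      { qr[k] = r - 1; qc[k] = c + 1; ++k; }
                          qr[k] = r;     qc[k] = c + 1; ++k;
        if (r < nr - 1) { qr[k] = r + 1; qc[k] = c + 1; ++k; }
      }
      if (r < nr - 1)   { qr[k] = r + 1; qc[k] = c;     ++k; }
      for (int q = 0; q < k; ++q) m = std::max(m, J(qr[q], qc[q]));
      J(r, c) = std::min(m, mask(r, c));
      for (int q = 0; q < k; ++q) {
        if (J(qr[q], qc[q]) < J(r, c) && J(qr[q], qc[q]) < mask(qr[q], qc[q])) {
          fifo.push(r + c * nr);
          break;
        }
      }
    }
  }
  // FIFO propagation
  static const int dr[8] = { -1, -1, -1, 0, 0, 1, 1, 1 };
  static const int dc[8] = { -1, 0, 1, -1, 1, -1, 0, 1 };
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int r = p % nr, c = p / nr;
    double Jp = J(r, c);
    for (int q = 0; q < 8; ++q) {
      int r2 = r + dr[q], c2 = c + dc[q];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (J(r2, c2) < Jp && J(r2, c2) != mask(r2, c2)) {
        J(r2, c2) = std::min(Jp, mask(r2, c2));
        fifo.push(r2 + c2 * nr);
      }
    }
  }
  return J;
}

// Connected-component labelling of a 3D logical array, 26-connectivity
// (8-connectivity when the third dimension is 1). Labels are assigned in
// column-major scan order of the first voxel of each component, giving a
// stable, deterministic numbering.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  int nr = dims[0], nc = dims[1], np = dims[2];
  R_xlen_t n = (R_xlen_t)nr * nc * np;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n);
  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] != TRUE || lab[i] != 0) continue;
    ++next_label;
    lab[i] = next_label;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int r = (int)(p % nr);
      R_xlen_t rest = p / nr;
      int c = (int)(rest % nc);
      int z = (int)(rest / nc);
      for (int dz = -1; dz <= 1; ++dz) {
        int z2 = z + dz; if (z2 < 0 || z2 >= np) continue;
        for (int dc2 = -1; dc2 <= 1; ++dc2) {
          int c2 = c + dc2; if (c2 < 0 || c2 >= nc) continue;
          for (int dr2 = -1; dr2 <= 1; ++dr2) {
            int r2 = r + dr2; if (r2 < 0 || r2 >= nr) continue;
            if (dz == 0 && dc2 == 0 && dr2 == 0) continue;
            R_xlen_t q = r2 + (R_xlen_t)nr * (c2 + (R_xlen_t)nc * z2);
            if (mask[q] == TRUE && lab[q] == 0) {
              lab[q] = next_label;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next_label;
  return lab;
}
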