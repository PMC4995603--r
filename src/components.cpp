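#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D connected-component labelling by breadth-first search.
// connectivity: 6 (faces), 18 (faces+edges), 26 (faces+edges+corners).
// Returns an integer grid, 0 for background, components numbered from 1
// in order of first (column-major) encounter.

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector fg, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (fg.size() != n) stop("foreground length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nnz = (a != 0) + (b != 0) + (c != 0);
        if (nnz == 0) continue;
        if (connectivity == 6 && nnz > 1) continue;
        if (connectivity == 18 && nnz > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const int noff = (int)dx.size();

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!fg[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int z = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v % ((R_xlen_t)nx * ny));
      int y = rem / nx;
      int x = rem % nx;
      for (int k = 0; k < noff; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (fg[w] && lab[w] == 0) {
          lab[w] = next;
          queue.push_back(w);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
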