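#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a logical grid: 4-connectivity in-plane,
// plus face adjacency across slices for 3-D grids (6-connectivity).
// Returns integer labels, 0 for background, components numbered from 1 in
// first-encounter (column-major scan) order.

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nr = dims[0];
  const int nc = dims[1];
  const int ns = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t total = (R_xlen_t)nr * nc * ns;
  if (mask.size() != total) stop("mask length does not match dims");

  IntegerVector labels(total, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t idx = 0; idx < total; ++idx) {
    if (!mask[idx] || labels[idx] != 0) continue;
    ++next_label;
    stack.push_back(idx);
    labels[idx] = next_label;
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i = cur % nr;
      const int j = (cur / nr) % nc;
      const int k = cur / ((R_xlen_t)nr * nc);
      const int di[6] = { -1, 1, 0, 0, 0, 0 };
      const int dj[6] = { 0, 0, -1, 1, 0, 0 };
      const int dk[6] = { 0, 0, 0, 0, -1, 1 };
      for (int d = 0; d < 6; ++d) {
        const int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc || kk < 0 || kk >= ns)
          continue;
        const R_xlen_t nb = ii + (R_xlen_t)nr * (jj + (R_xlen_t)nc * kk);
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = next_label;
          stack.push_back(nb);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}
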