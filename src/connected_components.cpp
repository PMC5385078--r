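#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// BFS connected-component labeling on a logical matrix.
// connectivity: 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
// Labels are assigned in raster scan order (column-major, as R stores
// matrices), starting at 1, so labeling is deterministic.
// [[Rcpp::export(name = ".cc_label")]]
List cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<int> sizes;
  std::vector<int> queue;
  queue.reserve(256);

  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  int ndir = connectivity;

  int next_label = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++next_label;
      int count = 0;
      queue.clear();
      queue.push_back(c * nr + r);
      labels(r, c) = next_label;
      while (!queue.empty()) {
        int idx = queue.back();
        queue.pop_back();
        ++count;
        int cr = idx % nr, cc2 = idx / nr;
        for (int d = 0; d < ndir; ++d) {
          int rr = cr + dr[d], cc3 = cc2 + dc[d];
          if (rr < 0 || rr >= nr || cc3 < 0 || cc3 >= nc) continue;
          if (mask(rr, cc3) && labels(rr, cc3) == 0) {
            labels(rr, cc3) = next_label;
            queue.push_back(cc3 * nr + rr);
          }
        }
      }
      sizes.push_back(count);
    }
  }
  return List::create(_["labels"] = labels,
                      _["sizes"] = wrap(sizes));
}
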