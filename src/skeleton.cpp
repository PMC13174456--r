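#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Zhang-Suen morphological thinning of a binary mask (row, col matrix).
// Produces the 1-px-wide, 8-connected skeleton used for epidermal graphs.
// [[Rcpp::export(name = ".thin_zhang_suen")]]
IntegerMatrix thin_zhang_suen(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(clone(mask));
  std::vector<std::pair<int,int>> kill;
  kill.reserve(1024);
  bool changed = true;
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c);
  };
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1);
          int p4 = at(r, c + 1),     p5 = at(r + 1, c + 1);
          int p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
          int p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i)
          img(kill[i].first, kill[i].second) = 0;
      }
    }
  }
  return img;
}

// 8-connected component labeling (BFS); labels 1..K in raster-scan order of
// each component's first-seen pixel.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(r + c * nr);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            q.push(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}
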