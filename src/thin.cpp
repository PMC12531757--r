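#include <Rcpp.h>
using namespace Rcpp;

// Morphological thinning of a binary image: Zhang-Suen two-subiteration
// thinning followed by removal of residual redundant pixels (staircase /
// 2x2 block remnants). A pixel is removable in the cleanup when it is not
// an endpoint, is 8-simple (Yokoi connectivity number C8 == 1) and touches
// the 4-connected background; sequential removal of such pixels preserves
// topology.

static inline int at(const LogicalMatrix &m, int r, int c, int nr, int nc) {
  if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
  return m(r, c) ? 1 : 0;
}

// neighbours in Zhang-Suen order: P2..P9 = N, NE, E, SE, S, SW, W, NW
static inline void nbrs(const LogicalMatrix &m, int r, int c, int nr, int nc,
                        int p[8]) {
  p[0] = at(m, r - 1, c, nr, nc);
  p[1] = at(m, r - 1, c + 1, nr, nc);
  p[2] = at(m, r, c + 1, nr, nc);
  p[3] = at(m, r + 1, c + 1, nr, nc);
  p[4] = at(m, r + 1, c, nr, nc);
  p[5] = at(m, r + 1, c - 1, nr, nc);
  p[6] = at(m, r, c - 1, nr, nc);
  p[7] = at(m, r - 1, c - 1, nr, nc);
}

// Yokoi connectivity number for 8-connectivity.
// x1..x8 = E, NE, N, NW, W, SW, S, SE.
static inline int yokoi8(const LogicalMatrix &m, int r, int c, int nr,
                         int nc) {
  int x[9];
  x[1] = at(m, r, c + 1, nr, nc);
  x[2] = at(m, r - 1, c + 1, nr, nc);
  x[3] = at(m, r - 1, c, nr, nc);
  x[4] = at(m, r - 1, c - 1, nr, nc);
  x[5] = at(m, r, c - 1, nr, nc);
  x[6] = at(m, r + 1, c - 1, nr, nc);
  x[7] = at(m, r + 1, c, nr, nc);
  x[8] = at(m, r + 1, c + 1, nr, nc);
  int c8 = 0;
  for (int k = 1; k <= 7; k += 2) {
    int k1 = (k % 8) + 1, k2 = (k1 % 8) + 1;
    c8 += (1 - x[k]) - (1 - x[k]) * (1 - x[k1]) * (1 - x[k2]);
  }
  return c8;
}

// [[Rcpp::export(name = ".zs_thin_cpp")]]
LogicalMatrix zs_thin_cpp(LogicalMatrix input) {
  int nr = input.nrow(), nc = input.ncol();
  LogicalMatrix m = clone(input);
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      del.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m(r, c)) continue;
          int p[8];
          nbrs(m, r, c, nr, nc, p);
          int b = 0;
          for (int i = 0; i < 8; ++i) b += p[i];
          if (b < 2 || b > 6) continue;
          int a = 0;
          for (int i = 0; i < 8; ++i)
            if (p[i] == 0 && p[(i + 1) % 8] == 1) ++a;
          if (a != 1) continue;
          bool ok;
          if (step == 0)
            ok = (p[0] * p[2] * p[4] == 0) && (p[2] * p[4] * p[6] == 0);
          else
            ok = (p[0] * p[2] * p[6] == 0) && (p[0] * p[4] * p[6] == 0);
          if (ok) del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i)
        m(del[i].first, del[i].second) = false;
    }
  }
  // cleanup: sequential removal of simple non-endpoint pixels adjacent to
  // the 4-connected background
  changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!m(r, c)) continue;
        int p[8];
        nbrs(m, r, c, nr, nc, p);
        int b = 0;
        for (int i = 0; i < 8; ++i) b += p[i];
        if (b < 2 || b > 6) continue;
        int bg4 = (1 - p[0]) + (1 - p[2]) + (1 - p[4]) + (1 - p[6]);
        if (bg4 == 0) continue;
        if (yokoi8(m, r, c, nr, nc) == 1) {
          m(r, c) = false;
          changed = true;
        }
      }
    }
  }
  return m;
}
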