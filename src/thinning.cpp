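#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen thinning of a binary image, plus a cleanup pass that removes
// deletable pixels from any remaining 2x2 foreground block so the skeleton
// is strictly one pixel wide.

static inline int px(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c);
}

// neighbours in circular order P2..P9 starting north, clockwise
static void neighbours(const IntegerMatrix &m, int r, int c, int out[8]) {
  out[0] = px(m, r - 1, c);     // N
  out[1] = px(m, r - 1, c + 1); // NE
  out[2] = px(m, r, c + 1);     // E
  out[3] = px(m, r + 1, c + 1); // SE
  out[4] = px(m, r + 1, c);     // S
  out[5] = px(m, r + 1, c - 1); // SW
  out[6] = px(m, r, c - 1);     // W
  out[7] = px(m, r - 1, c - 1); // NW
}

static inline int transitions(const int p[8]) {
  int a = 0;
  for (int i = 0; i < 8; ++i) a += (p[i] == 0 && p[(i + 1) % 8] == 1);
  return a;
}

static inline int bsum(const int p[8]) {
  int b = 0;
  for (int i = 0; i < 8; ++i) b += p[i];
  return b;
}

// [[Rcpp::export(name = ".cpp_thin")]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  IntegerMatrix m = clone(mask);
  int nr = m.nrow(), nc = m.ncol();
  bool changed = true;
  int p[8];
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!m(r, c)) continue;
          neighbours(m, r, c, p);
          int B = bsum(p);
          if (B < 2 || B > 6) continue;
          if (transitions(p) != 1) continue;
          // p[0]=N p[2]=E p[4]=S p[6]=W
          if (sub == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) m(kill[k].first, kill[k].second) = 0;
    }
  }
  // cleanup: Zhang-Suen can leave 2x2 blocks at staircase joints and
  // crossings; remove any pixel of such a block whose 8-neighbours stay in
  // one 8-connected component without it (a simple point)
  changed = true;
  while (changed) {
    changed = false;
    for (int r = 0; r + 1 < nr && !changed; ++r) {
      for (int c = 0; c + 1 < nc && !changed; ++c) {
        if (m(r, c) && m(r + 1, c) && m(r, c + 1) && m(r + 1, c + 1)) {
          int rr[4] = {r, r, r + 1, r + 1};
          int cc[4] = {c, c + 1, c, c + 1};
          for (int k = 0; k < 4; ++k) {
            neighbours(m, rr[k], cc[k], p);
            if (bsum(p) <= 1) continue;
            // coordinates of foreground neighbours, in ring order
            const int dro[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
            const int dco[8] = {0, 1, 1, 1, 0, -1, -1, -1};
            int nb_r[8], nb_c[8], nn = 0;
            for (int i = 0; i < 8; ++i) {
              if (p[i]) { nb_r[nn] = dro[i]; nb_c[nn] = dco[i]; ++nn; }
            }
            // single-linkage component count over Chebyshev adjacency
            int comp[8];
            for (int i = 0; i < nn; ++i) comp[i] = i;
            bool merged = true;
            while (merged) {
              merged = false;
              for (int i = 0; i < nn; ++i) {
                for (int j = i + 1; j < nn; ++j) {
                  if (comp[i] != comp[j] &&
                      std::abs(nb_r[i] - nb_r[j]) <= 1 &&
                      std::abs(nb_c[i] - nb_c[j]) <= 1) {
                    int from = comp[j], to = comp[i];
                    for (int q = 0; q < nn; ++q)
                      if (comp[q] == from) comp[q] = to;
                    merged = true;
                  }
                }
              }
            }
            int ncomp = 0;
            for (int i = 0; i < nn; ++i) {
              bool seen = false;
              for (int j = 0; j < i; ++j) seen = seen || (comp[j] == comp[i]);
              if (!seen) ++ncomp;
            }
            if (ncomp == 1) {
              m(rr[k], cc[k]) = 0;
              changed = true;
              break;
            }
          }
        }
      }
    }
  }
  return m;
}

// FNV-1a 32-bit hash, as 8 lowercase hex digits
// [[Rcpp::export(name = ".cpp_fnv1a")]]
std::string cpp_fnv1a(RawVector bytes) {
  uint32_t h = 2166136261u;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint32_t)bytes[i];
    h *= 16777619u;
  }
  char buf[9];
  snprintf(buf, sizeof(buf), "%08x", h);
  return std::string(buf);
}

// 8-connected component labelling (BFS); labels are 1..k in scan order
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > queue;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      queue.clear();
      queue.push_back(std::make_pair(r0, c0));
      lab(r0, c0) = next;
      while (!queue.empty()) {
        std::pair<int, int> p = queue.back();
        queue.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int r = p.first + dr, c = p.second + dc;
            if (r < 0 || c < 0 || r >= nr || c >= nc) continue;
            if (mask(r, c) && !lab(r, c)) {
              lab(r, c) = next;
              queue.push_back(std::make_pair(r, c));
            }
          }
        }
      }
    }
  }
  return lab;
}
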