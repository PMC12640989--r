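#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Reflect-101 index mapping (0-based): -1 -> 1, n -> n-2.
static inline int mirror(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// Sliding-window GLCM statistics.
//
// For every pixel, co-occurrences of quantised levels are collected over all
// horizontal neighbour pairs (offset 0 deg, distance 1) inside the centred
// window, symmetrised (each unordered pair counted in both directions) and
// normalised; the eight Haralick-style statistics are evaluated on that
// matrix. Edges use reflect-101 padding. Masked neighbours are excluded from
// the pair set; a window with no valid pair yields NA in all layers.
//
// levels: integer matrix (0..Ng-1), mask: logical matrix (true = valid).
// [[Rcpp::export]]
List glcm_stats_cpp(IntegerMatrix levels, LogicalMatrix mask, int window) {
  const int h = levels.nrow(), w = levels.ncol(), r = window / 2;
  NumericMatrix mea(h, w), var(h, w), hom(h, w), con(h, w),
      dis(h, w), ent(h, w), sem(h, w), cor(h, w);
  const int maxpairs = window * (window - 1);
  std::vector<int> codes(2 * maxpairs);

  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (!mask(i, j)) {
        mea(i, j) = var(i, j) = hom(i, j) = con(i, j) = dis(i, j) =
            ent(i, j) = sem(i, j) = cor(i, j) = NA_REAL;
        continue;
      }
      int np = 0; // ordered pairs
      double s_i = 0, s_ii = 0, s_ij = 0, s_con = 0, s_dis = 0, s_hom = 0;
      for (int di = -r; di <= r; ++di) {
        const int ri = mirror(i + di, h);
        for (int dj = -r; dj <= r - 1; ++dj) {
          const int c1 = mirror(j + dj, w), c2 = mirror(j + dj + 1, w);
          if (!mask(ri, c1) || !mask(ri, c2)) continue;
          const int a = levels(ri, c1), b = levels(ri, c2);
          codes[np]     = a * 4096 + b;
          codes[np + 1] = b * 4096 + a;
          np += 2;
          const double d = a - b;
          s_i   += a + b;
          s_ii  += (double)a * a + (double)b * b;
          s_ij  += 2.0 * a * b;
          s_con += 2.0 * d * d;
          s_dis += 2.0 * std::abs(d);
          s_hom += 2.0 / (1.0 + d * d);
        }
      }
      if (np == 0) {
        mea(i, j) = var(i, j) = hom(i, j) = con(i, j) = dis(i, j) =
            ent(i, j) = sem(i, j) = cor(i, j) = NA_REAL;
        continue;
      }
      const double n = np;
      const double mu = s_i / n;          // row-marginal mean (symmetric P)
      const double v = s_ii / n - mu * mu;
      mea(i, j) = mu;
      var(i, j) = v;
      hom(i, j) = s_hom / n;
      con(i, j) = s_con / n;
      dis(i, j) = s_dis / n;
      // entropy / second moment need the multiset of cell counts
      std::sort(codes.begin(), codes.begin() + np);
      double e = 0, se = 0;
      int k = 0;
      while (k < np) {
        int k2 = k;
        while (k2 < np && codes[k2] == codes[k]) ++k2;
        const double p = (double)(k2 - k) / n;
        se += p * p;
        e -= p * std::log(p);
        k = k2;
      }
      ent(i, j) = e;
      sem(i, j) = se;
      cor(i, j) = (v > 0) ? (s_ij / n - mu * mu) / v : 0.0;
    }
  }
  return List::create(_["MEA"] = mea, _["VAR"] = var, _["HOM"] = hom,
                      _["CON"] = con, _["DIS"] = dis, _["ENT"] = ent,
                      _["SEM"] = sem, _["COR"] = cor);
}
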