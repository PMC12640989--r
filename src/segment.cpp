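#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bottom-up multiresolution region merging (mutual-best-fit, scale^2 stop).
//
// Starting from single-pixel regions, adjacent regions merge while the
// heterogeneity increase
//   f = (1 - shape) * dh_color + shape * dh_shape
// stays below scale^2, where dh_color sums w_L * (n_m s_m - n_1 s_1 - n_2 s_2)
// over layers (s = within-region standard deviation) and dh_shape mixes the
// perimeter-based compactness (sqrt(n) * l) and smoothness (n * l / bbox
// perimeter) terms with the compactness weight. Each sweep scans live regions
// in ascending id; a pair merges only when each is the other's best-fitting
// neighbour. Deterministic given the pixel scan order.

struct Region {
  int n = 0;
  double perim = 0;
  int r1 = 0, r2 = 0, c1 = 0, c2 = 0;
  bool alive = false;
};

static std::vector<int> parent;
static int find_root(int x) {
  while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
  return x;
}

// [[Rcpp::export]]
IntegerVector segment_cpp(NumericMatrix X, LogicalVector mask, int h, int w,
                          NumericVector weights, double scale, double shape,
                          double compactness) {
  const int npix = h * w, L = X.ncol();
  const double thresh = scale * scale;
  std::vector<Region> reg(npix);
  std::vector<double> rsum((size_t)npix * L, 0.0), rsumsq((size_t)npix * L, 0.0);
  std::vector<std::unordered_map<int, double>> adj(npix);
  parent.assign(npix, 0);

  std::vector<int> ids;
  ids.reserve(npix);
  for (int p = 0; p < npix; ++p) {
    parent[p] = p;
    if (!mask[p]) continue;
    Region &r = reg[p];
    r.n = 1; r.perim = 4;
    r.r1 = r.r2 = p % h; r.c1 = r.c2 = p / h;
    r.alive = true;
    for (int l = 0; l < L; ++l) {
      const double v = X(p, l);
      rsum[(size_t)p * L + l] = v;
      rsumsq[(size_t)p * L + l] = v * v;
    }
    ids.push_back(p);
  }
  // 4-neighbour adjacency with shared boundary length 1
  for (int p = 0; p < npix; ++p) {
    if (!mask[p]) continue;
    const int row = p % h, col = p / h;
    if (row + 1 < h && mask[p + 1]) { adj[p][p + 1] = 1; adj[p + 1][p] = 1; }
    if (col + 1 < w && mask[p + h]) { adj[p][p + h] = 1; adj[p + h][p] = 1; }
  }

  auto sdev = [&](int r, int l) {
    const double n = reg[r].n;
    const double m = rsum[(size_t)r * L + l] / n;
    const double v = rsumsq[(size_t)r * L + l] / n - m * m;
    return v > 0 ? std::sqrt(v) : 0.0;
  };

  auto fuse_cost = [&](int a, int b, double shared) {
    const Region &ra = reg[a], &rb = reg[b];
    const double na = ra.n, nb = rb.n, nm = na + nb;
    double dcolor = 0;
    for (int l = 0; l < L; ++l) {
      const double sm = rsum[(size_t)a * L + l] + rsum[(size_t)b * L + l];
      const double sq = rsumsq[(size_t)a * L + l] + rsumsq[(size_t)b * L + l];
      const double mu = sm / nm;
      const double v = sq / nm - mu * mu;
      const double sdm = v > 0 ? std::sqrt(v) : 0.0;
      dcolor += weights[l] * (nm * sdm - na * sdev(a, l) - nb * sdev(b, l));
    }
    const double lm = ra.perim + rb.perim - 2.0 * shared;
    const double dcmpct = std::sqrt(nm) * lm -
        (std::sqrt(na) * ra.perim + std::sqrt(nb) * rb.perim);
    const int mr1 = std::min(ra.r1, rb.r1), mr2 = std::max(ra.r2, rb.r2);
    const int mc1 = std::min(ra.c1, rb.c1), mc2 = std::max(ra.c2, rb.c2);
    const double bm = 2.0 * ((mr2 - mr1 + 1) + (mc2 - mc1 + 1));
    const double ba = 2.0 * ((ra.r2 - ra.r1 + 1) + (ra.c2 - ra.c1 + 1));
    const double bb = 2.0 * ((rb.r2 - rb.r1 + 1) + (rb.c2 - rb.c1 + 1));
    const double dsmooth = nm * lm / bm - (na * ra.perim / ba + nb * rb.perim / bb);
    const double dshape = compactness * dcmpct + (1.0 - compactness) * dsmooth;
    return (1.0 - shape) * dcolor + shape * dshape;
  };

  auto best_neighbour = [&](int a, double &best_cost) {
    int best = -1;
    best_cost = R_PosInf;
    for (auto &kv : adj[a]) {
      const double c = fuse_cost(a, kv.first, kv.second);
      if (c < best_cost || (c == best_cost && kv.first < best)) {
        best_cost = c; best = kv.first;
      }
    }
    return best;
  };

  bool merged_any = true;
  while (merged_any) {
    merged_any = false;
    for (size_t k = 0; k < ids.size(); ++k) {
      const int a = ids[k];
      if (!reg[a].alive) continue;
      double ca, cb;
      const int b = best_neighbour(a, ca);
      if (b < 0 || !(ca < thresh)) continue;
      if (best_neighbour(b, cb) != a) continue;
      // merge b into a if a < b else a into b (keep the smaller id)
      const int keep = std::min(a, b), drop = std::max(a, b);
      Region &rk = reg[keep], &rd = reg[drop];
      const double shared = adj[keep][drop];
      rk.perim = rk.perim + rd.perim - 2.0 * shared;
      rk.r1 = std::min(rk.r1, rd.r1); rk.r2 = std::max(rk.r2, rd.r2);
      rk.c1 = std::min(rk.c1, rd.c1); rk.c2 = std::max(rk.c2, rd.c2);
      rk.n += rd.n;
      for (int l = 0; l < L; ++l) {
        rsum[(size_t)keep * L + l] += rsum[(size_t)drop * L + l];
        rsumsq[(size_t)keep * L + l] += rsumsq[(size_t)drop * L + l];
      }
      adj[keep].erase(drop);
      adj[drop].erase(keep);
      for (auto &kv : adj[drop]) {
        adj[kv.first].erase(drop);
        adj[keep][kv.first] += kv.second;
        adj[kv.first][keep] += kv.second;
      }
      adj[drop].clear();
      rd.alive = false;
      parent[drop] = keep;
      merged_any = true;
    }
  }

  // compact ids in order of first pixel (column-major scan)
  IntegerVector out(npix, 0);
  std::unordered_map<int, int> relabel;
  int next = 1;
  for (int p = 0; p < npix; ++p) {
    if (!mask[p]) continue;
    const int r = find_root(p);
    auto it = relabel.find(r);
    if (it == relabel.end()) { relabel[r] = next; out[p] = next; ++next; }
    else out[p] = it->second;
  }
  return out;
}

// 4-connected component labelling of a label raster (codes > 0); returns
// component ids (1..K, 0 for NoData), components split across class codes.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(IntegerVector labels, int h, int w) {
  const int npix = h * w;
  IntegerVector out(npix, 0);
  std::vector<int> stack;
  int next = 0;
  for (int p = 0; p < npix; ++p) {
    if (labels[p] <= 0 || out[p] != 0) continue;
    const int code = labels[p];
    ++next;
    stack.push_back(p);
    out[p] = next;
    while (!stack.empty()) {
      const int q = stack.back(); stack.pop_back();
      const int row = q % h, col = q / h;
      const int nb[4] = { row > 0 ? q - 1 : -1, row + 1 < h ? q + 1 : -1,
                          col > 0 ? q - h : -1, col + 1 < w ? q + h : -1 };
      for (int t = 0; t < 4; ++t) {
        const int u = nb[t];
        if (u >= 0 && out[u] == 0 && labels[u] == code) {
          out[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  return out;
}
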