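#include <Rcpp.h>
#include <map>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 8-connected component labeling by stack-based flood fill.
// Labels are assigned in column-major scan order, starting at 1.
// [[Rcpp::export]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int cur = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++cur;
      lab(i, j) = cur;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && !lab(qi, qj)) {
              lab(qi, qj) = cur;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Seed markers for the seeded watershed: local maxima of the distance
// transform (>= all 8 neighbours, out-of-mask treated as 0), thinned so that
// within each connected component accepted seeds are at least min_sep_px
// apart (greedy by decreasing distance value; ties broken by column-major
// position). The global maximum of every component is always accepted, so
// every component receives at least one seed.
// [[Rcpp::export]]
IntegerMatrix watershed_seeds(NumericMatrix dist, IntegerMatrix comp,
                              double min_sep_px) {
  const int nr = dist.nrow(), nc = dist.ncol();
  const double sep2 = min_sep_px * min_sep_px;
  std::vector<int> cand;
  cand.reserve(1024);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double d = dist(i, j);
      if (d <= 0) continue;
      bool ismax = true;
      for (int dj = -1; dj <= 1 && ismax; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          const int qi = i + di, qj = j + dj;
          double q = 0.0;
          if (qi >= 0 && qi < nr && qj >= 0 && qj < nc) q = dist(qi, qj);
          if (q > d) { ismax = false; break; }
        }
      }
      if (ismax) cand.push_back(i + j * nr);
    }
  }
  // sort candidates by decreasing distance, ties by column-major index
  std::stable_sort(cand.begin(), cand.end(), [&](int a, int b) {
    const double da = dist[a], db = dist[b];
    if (da != db) return da > db;
    return a < b;
  });
  IntegerMatrix seeds(nr, nc);
  // accepted seeds per component
  std::map< int, std::vector<int> > acc;
  int k = 0;
  for (size_t s = 0; s < cand.size(); ++s) {
    const int p = cand[s];
    const int pi = p % nr, pj = p / nr;
    const int cp = comp(pi, pj);
    std::vector<int> &v = acc[cp];
    bool ok = true;
    for (size_t t = 0; t < v.size(); ++t) {
      const int q = v[t];
      const double dr = (q % nr) - pi, dc = (q / nr) - pj;
      if (dr * dr + dc * dc < sep2) { ok = false; break; }
    }
    if (ok) {
      v.push_back(p);
      seeds(pi, pj) = ++k;
    }
  }
  return seeds;
}

struct FloodNode {
  double d;
  long ord;
  int idx;
  int lab;
};
struct FloodCmp {
  bool operator()(const FloodNode &a, const FloodNode &b) const {
    if (a.d != b.d) return a.d < b.d;   // max-heap on distance
    return a.ord > b.ord;               // FIFO on ties
  }
};

// Marker-controlled watershed of the negated distance transform, realised as
// an ordered flood: seeds grow outward, always expanding the front pixel with
// the highest distance value first. The union of labels equals the mask
// exactly; every masked pixel inherits the label of the seed whose flood
// reaches it first.
// [[Rcpp::export]]
IntegerMatrix watershed_flood(NumericMatrix dist, IntegerMatrix seeds,
                              LogicalMatrix mask) {
  const int nr = dist.nrow(), nc = dist.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<FloodNode, std::vector<FloodNode>, FloodCmp> pq;
  long ord = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (seeds(i, j) > 0) {
        lab(i, j) = seeds(i, j);
        pq.push(FloodNode{dist(i, j), ord++, i + j * nr, seeds(i, j)});
      }
    }
  }
  while (!pq.empty()) {
    const FloodNode nd = pq.top(); pq.pop();
    const int pi = nd.idx % nr, pj = nd.idx / nr;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        const int qi = pi + di, qj = pj + dj;
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        if (mask(qi, qj) && lab(qi, qj) == 0) {
          lab(qi, qj) = nd.lab;
          pq.push(FloodNode{dist(qi, qj), ord++, qi + qj * nr, nd.lab});
        }
      }
    }
  }
  return lab;
}

// Rasterized union of disks: TRUE where the pixel centre lies within
// radius_um of at least one reference point. Pixel (i, j) (1-based in R)
// has centre ((j - 0.5) * um_per_px, (i - 0.5) * um_per_px) in micrometres.
// [[Rcpp::export]]
LogicalMatrix mark_disks(int height_px, int width_px, double um_per_px,
                         NumericVector x_um, NumericVector y_um,
                         double radius_um) {
  LogicalMatrix out(height_px, width_px);
  const double r2 = radius_um * radius_um;
  for (int k = 0; k < x_um.size(); ++k) {
    const double x = x_um[k], y = y_um[k];
    int i0 = (int)std::floor((y - radius_um) / um_per_px + 0.5);
    int i1 = (int)std::ceil((y + radius_um) / um_per_px + 0.5);
    int j0 = (int)std::floor((x - radius_um) / um_per_px + 0.5);
    int j1 = (int)std::ceil((x + radius_um) / um_per_px + 0.5);
    if (i0 < 1) i0 = 1; if (i1 > height_px) i1 = height_px;
    if (j0 < 1) j0 = 1; if (j1 > width_px) j1 = width_px;
    for (int j = j0; j <= j1; ++j) {
      const double dx = (j - 0.5) * um_per_px - x;
      const double dx2 = dx * dx;
      if (dx2 > r2) continue;
      for (int i = i0; i <= i1; ++i) {
        const double dy = (i - 0.5) * um_per_px - y;
        if (dx2 + dy * dy <= r2) out(i - 1, j - 1) = true;
      }
    }
  }
  return out;
}

// Paint value disks onto a canvas, composing overlaps with max(): pixel
// centres within radius_um of point k take max(current, values[k]).
// [[Rcpp::export]]
NumericMatrix splat_disks(int height_px, int width_px, double um_per_px,
                          NumericVector x_um, NumericVector y_um,
                          double radius_um, NumericVector values) {
  NumericMatrix out(height_px, width_px);
  const double r2 = radius_um * radius_um;
  for (int k = 0; k < x_um.size(); ++k) {
    const double x = x_um[k], y = y_um[k], v = values[k];
    int i0 = (int)std::floor((y - radius_um) / um_per_px + 0.5);
    int i1 = (int)std::ceil((y + radius_um) / um_per_px + 0.5);
    int j0 = (int)std::floor((x - radius_um) / um_per_px + 0.5);
    int j1 = (int)std::ceil((x + radius_um) / um_per_px + 0.5);
    if (i0 < 1) i0 = 1; if (i1 > height_px) i1 = height_px;
    if (j0 < 1) j0 = 1; if (j1 > width_px) j1 = width_px;
    for (int j = j0; j <= j1; ++j) {
      const double dx = (j - 0.5) * um_per_px - x;
      const double dx2 = dx * dx;
      if (dx2 > r2) continue;
      for (int i = i0; i <= i1; ++i) {
        const double dy = (i - 0.5) * um_per_px - y;
        if (dx2 + dy * dy <= r2 && out(i - 1, j - 1) < v)
          out(i - 1, j - 1) = v;
      }
    }
  }
  return out;
}

// Minimum Euclidean distance from each query point to the reference set.
// self_ref[i] (1-based, 0 = none) names a reference to exclude for query i,
// so a reference cell can ask for its distance to the *other* references.
// [[Rcpp::export]]
NumericVector min_dist_to_refs(NumericVector qx, NumericVector qy,
                               NumericVector rx, NumericVector ry,
                               IntegerVector self_ref) {
  const int n = qx.size(), m = rx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const int skip = self_ref[i] - 1;
    for (int j = 0; j < m; ++j) {
      if (j == skip) continue;
      const double dx = qx[i] - rx[j], dy = qy[i] - ry[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
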