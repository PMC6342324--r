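#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Uniform grid over the bounding box of a point set, used for fast
// fixed-radius and k-nearest-neighbour queries on tissue-scale layouts.
struct PointGrid {
  int nx, ny;
  double x0, y0, cw, ch;
  std::vector< std::vector<int> > bins;

  PointGrid(const NumericVector& x, const NumericVector& y, int target_per_bin) {
    int n = x.size();
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    double side = std::sqrt((double)std::max(1, n) / std::max(1, target_per_bin));
    nx = std::max(1, (int)side);
    ny = nx;
    x0 = xmin; y0 = ymin;
    cw = (xmax - xmin) / nx; if (cw <= 0) cw = 1.0;
    ch = (ymax - ymin) / ny; if (ch <= 0) ch = 1.0;
    bins.assign((size_t)nx * ny, std::vector<int>());
    for (int i = 0; i < n; ++i) bins[bin_of(x[i], y[i])].push_back(i);
  }
  inline int clampi(int v, int lo, int hi) const {
    return v < lo ? lo : (v > hi ? hi : v);
  }
  inline size_t bin_of(double px, double py) const {
    int bx = clampi((int)((px - x0) / cw), 0, nx - 1);
    int by = clampi((int)((py - y0) / ch), 0, ny - 1);
    return (size_t)by * nx + bx;
  }
};

// Partition points into spatial clusters of a fixed size: walk `order`
// (a random permutation supplied by the caller); each still-unassigned
// point anchors a cluster and absorbs its (seed_size - 1) nearest
// still-unassigned neighbours. The trailing cluster may be smaller when
// n is not a multiple of seed_size.
// [[Rcpp::export]]
IntegerVector cpp_seed_clusters(NumericVector x, NumericVector y,
                                int seed_size, IntegerVector order) {
  int n = x.size();
  IntegerVector cluster(n, NA_INTEGER);
  if (seed_size <= 1) {
    for (int i = 0; i < n; ++i) cluster[i] = i + 1;
    return cluster;
  }
  PointGrid grid(x, y, 4);
  std::vector<char> assigned(n, 0);
  int next_cluster = 1;

  for (int oi = 0; oi < n; ++oi) {
    int anchor = order[oi] - 1;
    if (assigned[anchor]) continue;
    assigned[anchor] = 1;
    cluster[anchor] = next_cluster;
    int need = seed_size - 1;

    // expanding ring search for `need` nearest unassigned neighbours
    int abx = grid.clampi((int)((x[anchor] - grid.x0) / grid.cw), 0, grid.nx - 1);
    int aby = grid.clampi((int)((y[anchor] - grid.y0) / grid.ch), 0, grid.ny - 1);
    // max-heap of (dist2, idx) for current best `need`
    std::priority_queue< std::pair<double,int> > best;
    double cell_min = std::min(grid.cw, grid.ch);
    int max_ring = std::max(grid.nx, grid.ny);
    for (int ring = 0; ring <= max_ring; ++ring) {
      // prune: if we already hold `need` candidates all closer than the
      // nearest possible point in this ring, stop
      if ((int)best.size() == need && ring > 0) {
        double ring_min = (ring - 1) * cell_min;
        if (ring_min * ring_min > best.top().first) break;
      }
      bool any_cell = false;
      for (int by = aby - ring; by <= aby + ring; ++by) {
        if (by < 0 || by >= grid.ny) continue;
        for (int bx = abx - ring; bx <= abx + ring; ++bx) {
          if (bx < 0 || bx >= grid.nx) continue;
          // ring perimeter only
          if (ring > 0 && bx != abx - ring && bx != abx + ring &&
              by != aby - ring && by != aby + ring) continue;
          any_cell = true;
          const std::vector<int>& pts = grid.bins[(size_t)by * grid.nx + bx];
          for (size_t k = 0; k < pts.size(); ++k) {
            int j = pts[k];
            if (assigned[j]) continue;
            double dx = x[j] - x[anchor], dy = y[j] - y[anchor];
            double d2 = dx * dx + dy * dy;
            if ((int)best.size() < need) best.push(std::make_pair(d2, j));
            else if (d2 < best.top().first) { best.pop(); best.push(std::make_pair(d2, j)); }
          }
        }
      }
      if (!any_cell && ring > 0) break;  // ring fully outside the grid
    }
    while (!best.empty()) {
      int j = best.top().second; best.pop();
      assigned[j] = 1;
      cluster[j] = next_cluster;
    }
    ++next_cluster;
  }
  return cluster;
}

// All (query, target) pairs within `radius` (2D Euclidean). Returns 1-based
// indices and distances, sorted by query then distance.
// [[Rcpp::export]]
List cpp_radius_pairs(NumericVector qx, NumericVector qy,
                      NumericVector tx, NumericVector ty, double radius) {
  int nq = qx.size(), nt = tx.size();
  std::vector<int> qi, ti;
  std::vector<double> dist;
  if (nq > 0 && nt > 0) {
    PointGrid grid(tx, ty, 4);
    double r2 = radius * radius;
    int span_x = (int)std::ceil(radius / grid.cw);
    int span_y = (int)std::ceil(radius / grid.ch);
    for (int i = 0; i < nq; ++i) {
      int bx = grid.clampi((int)((qx[i] - grid.x0) / grid.cw), 0, grid.nx - 1);
      int by = grid.clampi((int)((qy[i] - grid.y0) / grid.ch), 0, grid.ny - 1);
      std::vector< std::pair<double,int> > hits;
      for (int cy = std::max(0, by - span_y); cy <= std::min(grid.ny - 1, by + span_y); ++cy) {
        for (int cx = std::max(0, bx - span_x); cx <= std::min(grid.nx - 1, bx + span_x); ++cx) {
          const std::vector<int>& pts = grid.bins[(size_t)cy * grid.nx + cx];
          for (size_t k = 0; k < pts.size(); ++k) {
            int j = pts[k];
            double dx = tx[j] - qx[i], dy = ty[j] - qy[i];
            double d2 = dx * dx + dy * dy;
            if (d2 <= r2) hits.push_back(std::make_pair(std::sqrt(d2), j));
          }
        }
      }
      std::sort(hits.begin(), hits.end());
      for (size_t k = 0; k < hits.size(); ++k) {
        qi.push_back(i + 1);
        ti.push_back(hits[k].second + 1);
        dist.push_back(hits[k].first);
      }
    }
  }
  return List::create(_["query"] = wrap(qi), _["target"] = wrap(ti),
                      _["dist"] = wrap(dist));
}
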