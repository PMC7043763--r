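// Object-level primitives: connected components, exact Euclidean distance
// transform, marker-controlled watershed, peak picking and circular Hough
// accumulation.
#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Connected component labeling (connectivity 4 or 8), labels 1..n.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int>> nbr;
  nbr.push_back({-1, 0}); nbr.push_back({1, 0});
  nbr.push_back({0, -1}); nbr.push_back({0, 1});
  if (connectivity == 8) {
    nbr.push_back({-1, -1}); nbr.push_back({-1, 1});
    nbr.push_back({1, -1}); nbr.push_back({1, 1});
  }
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      if (!mask(y, x) || lab(y, x)) continue;
      lab(y, x) = ++next;
      stack.clear();
      stack.push_back({y, x});
      while (!stack.empty()) {
        auto [cy, cx] = stack.back();
        stack.pop_back();
        for (auto& d : nbr) {
          int ny = cy + d.first, nx = cx + d.second;
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (mask(ny, nx) && !lab(ny, nx)) {
            lab(ny, nx) = next;
            stack.push_back({ny, nx});
          }
        }
      }
    }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -HUGE_VAL;
  z[1] = HUGE_VAL;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = HUGE_VAL;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance to the nearest false pixel.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix d(H, W);
  std::vector<double> f(std::max(H, W)), dd(std::max(H, W));
  // column pass
  for (int x = 0; x < W; ++x) {
    // large finite sentinel: infinities break the envelope intersections
    for (int y = 0; y < H; ++y) f[y] = mask(y, x) ? 1e12 : 0.0;
    dt1d(f, dd, H);
    for (int y = 0; y < H; ++y) d(y, x) = dd[y];
  }
  // row pass
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) f[x] = d(y, x);
    dt1d(f, dd, W);
    for (int x = 0; x < W; ++x) d(y, x) = std::sqrt(dd[x]);
  }
  return d;
}

// Marker-controlled watershed by priority flooding (4-connected); lower
// priority values flood first; FIFO order breaks ties deterministically.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix priority, IntegerMatrix markers,
                            LogicalMatrix mask) {
  const int H = priority.nrow(), W = priority.ncol();
  IntegerMatrix lab(H, W);
  struct Item { double p; long order; int y, x, l; };
  struct Cmp {
    bool operator()(const Item& a, const Item& b) const {
      if (a.p != b.p) return a.p > b.p;
      return a.order > b.order;
    }
  };
  std::priority_queue<Item, std::vector<Item>, Cmp> pq;
  long counter = 0;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      if (markers(y, x) > 0 && mask(y, x)) {
        lab(y, x) = markers(y, x);
        pq.push({priority(y, x), counter++, y, x, markers(y, x)});
      }
  const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    Item it = pq.top();
    pq.pop();
    for (int k = 0; k < 4; ++k) {
      int ny = it.y + dy[k], nx = it.x + dx[k];
      if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
      if (!mask(ny, nx) || lab(ny, nx)) continue;
      lab(ny, nx) = it.l;
      pq.push({priority(ny, nx), counter++, ny, nx, it.l});
    }
  }
  return lab;
}

// Greedy maxima: candidates (8-neighborhood local maxima with value >=
// threshold, inside mask) sorted by descending value (ties by row then
// column), accepted when no previously accepted peak lies within min_dist.
// Returns a k x 2 matrix of 0-based (row, col).
// [[Rcpp::export]]
IntegerMatrix cpp_peak_coords(NumericMatrix img, double min_dist,
                              double threshold, LogicalMatrix mask) {
  const int H = img.nrow(), W = img.ncol();
  struct Cand { double v; int y, x; };
  std::vector<Cand> cands;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      if (!mask(y, x) || img(y, x) < threshold) continue;
      bool ismax = true;
      for (int dy = -1; dy <= 1 && ismax; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dy == 0 && dx == 0) continue;
          int ny = y + dy, nx = x + dx;
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (img(ny, nx) > img(y, x)) { ismax = false; break; }
        }
      if (ismax) cands.push_back({img(y, x), y, x});
    }
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.v != b.v) return a.v > b.v;
    if (a.y != b.y) return a.y < b.y;
    return a.x < b.x;
  });
  std::vector<std::pair<int,int>> acc;
  const double md2 = min_dist * min_dist;
  for (auto& c : cands) {
    bool ok = true;
    for (auto& a : acc) {
      double ddy = c.y - a.first, ddx = c.x - a.second;
      if (ddy * ddy + ddx * ddx <= md2) { ok = false; break; }
    }
    if (ok) acc.push_back({c.y, c.x});
  }
  IntegerMatrix out(acc.size(), 2);
  for (size_t i = 0; i < acc.size(); ++i) {
    out(i, 0) = acc[i].first;
    out(i, 1) = acc[i].second;
  }
  return out;
}

// lattice points of a circle of radius r (midpoint-style, via rounding)
static std::vector<std::pair<int,int>> circle_points(int r) {
  std::vector<std::pair<int,int>> pts;
  int n = std::max(16, (int)std::ceil(4.0 * M_PI * r));
  for (int i = 0; i < n; ++i) {
    double a = 2.0 * M_PI * i / n;
    int dy = (int)std::lround(r * std::sin(a));
    int dx = (int)std::lround(r * std::cos(a));
    pts.push_back({dy, dx});
  }
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
  return pts;
}

// Circular Hough accumulation over edge pixels.  For each radius the
// accumulator is normalized by the circle perimeter length, so a complete
// ring scores ~1; the per-pixel maximum over radii is returned.
// [[Rcpp::export]]
NumericMatrix cpp_hough_circle(LogicalMatrix edges, IntegerVector radii) {
  const int H = edges.nrow(), W = edges.ncol();
  NumericMatrix best(H, W);
  std::vector<std::pair<int,int>> epx;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      if (edges(y, x)) epx.push_back({y, x});
  for (int ri = 0; ri < radii.size(); ++ri) {
    int r = radii[ri];
    if (r < 1) continue;
    auto pts = circle_points(r);
    NumericMatrix acc(H, W);
    double w = 1.0 / (double)pts.size();
    for (auto& e : epx)
      for (auto& p : pts) {
        int cy = e.first - p.first, cx = e.second - p.second;
        if (cy >= 0 && cy < H && cx >= 0 && cx < W) acc(cy, cx) += w;
      }
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x)
        if (acc(y, x) > best(y, x)) best(y, x) = acc(y, x);
  }
  return best;
}
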