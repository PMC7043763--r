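// Low-level image filtering primitives used by the filter bank and the
// nucleus segmentation stage.  All filters use symmetric (mirror) boundary
// padding so that every local window has a full complement of pixels.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// half-width of a disk of radius r at vertical offset dy
static std::vector<int> disk_spans(int r) {
  std::vector<int> xs(2 * r + 1);
  for (int dy = -r; dy <= r; ++dy)
    xs[dy + r] = (int)std::floor(std::sqrt((double)r * r - (double)dy * dy) + 1e-9);
  return xs;
}

enum RankType {
  RT_MAX, RT_MIN, RT_MEDIAN, RT_MEAN, RT_MODAL, RT_GRADIENT,
  RT_AUTO_LEVEL, RT_AUTO_LEVEL_PCT, RT_GRADIENT_PCT, RT_MEAN_PCT,
  RT_BILATERAL_MEAN, RT_LOCAL_HIST_EQ, RT_ENTROPY
};

static RankType rank_type_from_string(const std::string& s) {
  if (s == "maximum") return RT_MAX;
  if (s == "minimum") return RT_MIN;
  if (s == "median") return RT_MEDIAN;
  if (s == "mean") return RT_MEAN;
  if (s == "modal") return RT_MODAL;
  if (s == "gradient") return RT_GRADIENT;
  if (s == "auto_level") return RT_AUTO_LEVEL;
  if (s == "auto_level_percentile") return RT_AUTO_LEVEL_PCT;
  if (s == "gradient_percentile") return RT_GRADIENT_PCT;
  if (s == "mean_percentile") return RT_MEAN_PCT;
  if (s == "bilateral_mean") return RT_BILATERAL_MEAN;
  if (s == "local_hist_eq") return RT_LOCAL_HIST_EQ;
  if (s == "entropy") return RT_ENTROPY;
  stop("unknown rank filter type: %s", s.c_str());
}

struct Hist {
  int h[256];
  long n;
  Hist() : n(0) { std::fill(h, h + 256, 0); }
  inline void add(int v) { ++h[v]; ++n; }
  inline void rem(int v) { --h[v]; --n; }
  inline int minv() const { for (int b = 0; b < 256; ++b) if (h[b]) return b; return 0; }
  inline int maxv() const { for (int b = 255; b >= 0; --b) if (h[b]) return b; return 0; }
  // smallest bin with cdf >= max(1, ceil(p * n))
  inline int quantile(double p) const {
    long target = (long)std::ceil(p * (double)n - 1e-9);
    if (target < 1) target = 1;
    long c = 0;
    for (int b = 0; b < 256; ++b) { c += h[b]; if (c >= target) return b; }
    return 255;
  }
  inline long cdf_at(int v) const {
    long c = 0; for (int b = 0; b <= v; ++b) c += h[b]; return c;
  }
  inline double sum() const {
    double s = 0; for (int b = 0; b < 256; ++b) s += (double)b * h[b]; return s;
  }
  inline int mode() const {
    int best = 0, bc = h[0];
    for (int b = 1; b < 256; ++b) if (h[b] > bc) { bc = h[b]; best = b; }
    return best;
  }
};

// Rank-type filters over a disk footprint of the given radius, on an 8-bit
// quantized image (values 0..255).  Output intensities are returned on the
// [0,1] scale; entropy in bits (0..8); rank/equalization scores in [0,1].
// [[Rcpp::export]]
NumericMatrix cpp_rank_filter(IntegerMatrix img, int radius, std::string type,
                              double p_lo, double p_hi, int bilateral_halfwidth) {
  const int H = img.nrow(), W = img.ncol(), r = radius;
  if (r < 1) stop("radius must be >= 1");
  RankType ft = rank_type_from_string(type);
  NumericMatrix out(H, W);
  std::vector<int> xs = disk_spans(r);

  // disk size is constant under mirror padding -> precompute entropy table
  long nwin = 0;
  for (int dy = -r; dy <= r; ++dy) nwin += 2L * xs[dy + r] + 1L;
  std::vector<double> plogp(nwin + 1, 0.0);
  if (ft == RT_ENTROPY) {
    for (long c = 1; c <= nwin; ++c) {
      double p = (double)c / (double)nwin;
      plogp[c] = p * std::log2(p);
    }
  }

  for (int y = 0; y < H; ++y) {
    Hist hist;
    for (int dy = -r; dy <= r; ++dy) {
      int yy = reflect_idx(y + dy, H);
      int span = xs[dy + r];
      for (int dx = -span; dx <= span; ++dx)
        hist.add(img(yy, reflect_idx(dx, W)));
    }
    for (int x = 0; x < W; ++x) {
      const int v = img(y, x);
      double val = 0.0;
      switch (ft) {
      case RT_MAX: val = hist.maxv() / 255.0; break;
      case RT_MIN: val = hist.minv() / 255.0; break;
      case RT_MEDIAN: val = hist.quantile(0.5) / 255.0; break;
      case RT_MEAN: val = hist.sum() / (255.0 * hist.n); break;
      case RT_MODAL: val = hist.mode() / 255.0; break;
      case RT_GRADIENT: val = (hist.maxv() - hist.minv()) / 255.0; break;
      case RT_AUTO_LEVEL: {
        int lo = hist.minv(), hi = hist.maxv();
        val = (hi > lo) ? (double)(v - lo) / (hi - lo) : 0.0;
        if (val < 0) val = 0; if (val > 1) val = 1;
        break;
      }
      case RT_AUTO_LEVEL_PCT: {
        int lo = hist.quantile(p_lo), hi = hist.quantile(p_hi);
        val = (hi > lo) ? (double)(v - lo) / (hi - lo) : 0.0;
        if (val < 0) val = 0; if (val > 1) val = 1;
        break;
      }
      case RT_GRADIENT_PCT: {
        int lo = hist.quantile(p_lo), hi = hist.quantile(p_hi);
        val = (hi - lo) / 255.0; break;
      }
      case RT_MEAN_PCT: {
        int lo = hist.quantile(p_lo), hi = hist.quantile(p_hi);
        double s = 0; long c = 0;
        for (int b = lo; b <= hi; ++b) { s += (double)b * hist.h[b]; c += hist.h[b]; }
        val = c > 0 ? s / (255.0 * c) : v / 255.0;
        break;
      }
      case RT_BILATERAL_MEAN: {
        int lo = v - bilateral_halfwidth, hi = v + bilateral_halfwidth;
        if (lo < 0) lo = 0; if (hi > 255) hi = 255;
        double s = 0; long c = 0;
        for (int b = lo; b <= hi; ++b) { s += (double)b * hist.h[b]; c += hist.h[b]; }
        val = c > 0 ? s / (255.0 * c) : v / 255.0;
        break;
      }
      case RT_LOCAL_HIST_EQ:
        val = (double)hist.cdf_at(v) / (double)hist.n; break;
      case RT_ENTROPY: {
        double e = 0;
        for (int b = 0; b < 256; ++b) if (hist.h[b]) e -= plogp[hist.h[b]];
        val = e; break;
      }
      }
      out(y, x) = val;
      if (x + 1 < W) {
        for (int dy = -r; dy <= r; ++dy) {
          int yy = reflect_idx(y + dy, H);
          int span = xs[dy + r];
          hist.rem(img(yy, reflect_idx(x - span, W)));
          hist.add(img(yy, reflect_idx(x + 1 + span, W)));
        }
      }
    }
  }
  return out;
}

// Moving-sum mean of a real-valued image over a disk footprint.
// [[Rcpp::export]]
NumericMatrix cpp_disk_mean(NumericMatrix img, int radius) {
  const int H = img.nrow(), W = img.ncol(), r = radius;
  if (r < 1) stop("radius must be >= 1");
  NumericMatrix out(H, W);
  std::vector<int> xs = disk_spans(r);
  long nwin = 0;
  for (int dy = -r; dy <= r; ++dy) nwin += 2L * xs[dy + r] + 1L;
  for (int y = 0; y < H; ++y) {
    double s = 0.0;
    for (int dy = -r; dy <= r; ++dy) {
      int yy = reflect_idx(y + dy, H);
      int span = xs[dy + r];
      for (int dx = -span; dx <= span; ++dx)
        s += img(yy, reflect_idx(dx, W));
    }
    for (int x = 0; x < W; ++x) {
      out(y, x) = s / nwin;
      if (x + 1 < W) {
        for (int dy = -r; dy <= r; ++dy) {
          int yy = reflect_idx(y + dy, H);
          int span = xs[dy + r];
          s -= img(yy, reflect_idx(x - span, W));
          s += img(yy, reflect_idx(x + 1 + span, W));
        }
      }
    }
  }
  return out;
}

// Direct 2-D convolution with mirror padding; kernel anchored at its center.
// [[Rcpp::export]]
NumericMatrix cpp_convolve2(NumericMatrix img, NumericMatrix kern) {
  const int H = img.nrow(), W = img.ncol();
  const int kh = kern.nrow(), kw = kern.ncol();
  const int cy = kh / 2, cx = kw / 2;
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double s = 0;
      for (int i = 0; i < kh; ++i) {
        int yy = reflect_idx(y + i - cy, H);
        for (int j = 0; j < kw; ++j)
          s += kern(i, j) * img(yy, reflect_idx(x + j - cx, W));
      }
      out(y, x) = s;
    }
  return out;
}

// Separable convolution: 1-D kernel along rows (ky) then columns (kx).
// [[Rcpp::export]]
NumericMatrix cpp_sepconv(NumericMatrix img, NumericVector ky, NumericVector kx) {
  const int H = img.nrow(), W = img.ncol();
  const int ny = ky.size(), nx = kx.size();
  const int cy = ny / 2, cx = nx / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double s = 0;
      for (int i = 0; i < ny; ++i)
        s += ky[i] * img(reflect_idx(y + i - cy, H), x);
      tmp(y, x) = s;
    }
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double s = 0;
      for (int j = 0; j < nx; ++j)
        s += kx[j] * tmp(y, reflect_idx(x + j - cx, W));
      out(y, x) = s;
    }
  return out;
}

// Bilinear resampling to a new grid (pixel-center alignment).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int out_h, int out_w) {
  const int H = img.nrow(), W = img.ncol();
  if (out_h < 1 || out_w < 1) stop("output dimensions must be positive");
  NumericMatrix out(out_h, out_w);
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int y = 0; y < out_h; ++y) {
    double fy = (y + 0.5) * sy - 0.5;
    int y0 = (int)std::floor(fy);
    double wy = fy - y0;
    int y0c = std::min(std::max(y0, 0), H - 1);
    int y1c = std::min(std::max(y0 + 1, 0), H - 1);
    for (int x = 0; x < out_w; ++x) {
      double fx = (x + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(fx);
      double wx = fx - x0;
      int x0c = std::min(std::max(x0, 0), W - 1);
      int x1c = std::min(std::max(x0 + 1, 0), W - 1);
      out(y, x) = (1 - wy) * ((1 - wx) * img(y0c, x0c) + wx * img(y0c, x1c)) +
                  wy * ((1 - wx) * img(y1c, x0c) + wx * img(y1c, x1c));
    }
  }
  return out;
}

// Contrast-limited adaptive histogram equalization on a [0,1] image.
// Tile mappings are clipped at clip_frac of the tile pixel count (excess
// redistributed uniformly) and interpolated bilinearly between tile centers.
// [[Rcpp::export]]
NumericMatrix cpp_clahe(NumericMatrix img, int tile_px, double clip_frac) {
  const int H = img.nrow(), W = img.ncol(), nbins = 256;
  if (tile_px < 2) stop("tile size must be >= 2");
  const int nty = std::max(1, (H + tile_px - 1) / tile_px);
  const int ntx = std::max(1, (W + tile_px - 1) / tile_px);
  IntegerMatrix q(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double v = img(y, x);
      if (v < 0) v = 0; if (v > 1) v = 1;
      q(y, x) = (int)std::lround(v * (nbins - 1));
    }
  // per-tile clipped CDF mapping to [0,1]
  std::vector<std::vector<double>> map((size_t)nty * ntx,
                                       std::vector<double>(nbins, 0.0));
  for (int ty = 0; ty < nty; ++ty)
    for (int tx = 0; tx < ntx; ++tx) {
      int y0 = ty * H / nty, y1 = (ty + 1) * H / nty;
      int x0 = tx * W / ntx, x1 = (tx + 1) * W / ntx;
      std::vector<double> hist(nbins, 0.0);
      long n = 0;
      for (int y = y0; y < y1; ++y)
        for (int x = x0; x < x1; ++x) { ++hist[q(y, x)]; ++n; }
      if (n == 0) continue;
      double limit = std::max(1.0, clip_frac * (double)n);
      double excess = 0;
      for (int b = 0; b < nbins; ++b)
        if (hist[b] > limit) { excess += hist[b] - limit; hist[b] = limit; }
      double add = excess / nbins;
      double c = 0;
      std::vector<double>& m = map[(size_t)ty * ntx + tx];
      for (int b = 0; b < nbins; ++b) { c += hist[b] + add; m[b] = c / (double)n; }
    }
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y) {
    double gy = ((double)y + 0.5) * nty / H - 0.5;
    int t0 = (int)std::floor(gy);
    double wy = gy - t0;
    int t0c = std::min(std::max(t0, 0), nty - 1);
    int t1c = std::min(std::max(t0 + 1, 0), nty - 1);
    for (int x = 0; x < W; ++x) {
      double gx = ((double)x + 0.5) * ntx / W - 0.5;
      int s0 = (int)std::floor(gx);
      double wx = gx - s0;
      int s0c = std::min(std::max(s0, 0), ntx - 1);
      int s1c = std::min(std::max(s0 + 1, 0), ntx - 1);
      int b = q(y, x);
      double v00 = map[(size_t)t0c * ntx + s0c][b];
      double v01 = map[(size_t)t0c * ntx + s1c][b];
      double v10 = map[(size_t)t1c * ntx + s0c][b];
      double v11 = map[(size_t)t1c * ntx + s1c][b];
      out(y, x) = (1 - wy) * ((1 - wx) * v00 + wx * v01) +
                  wy * ((1 - wx) * v10 + wx * v11);
    }
  }
  return out;
}
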