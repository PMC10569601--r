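// Low-level image primitives shared by the segmentation and foci pipelines.
// All matrices are R column-major; (row, col) are 1-based at the R interface
// and 0-based here.  Edge policy: rank/morphology filters use the in-bounds
// part of the window (ImageJ-style); convolutions reflect at the border.

#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// rank filters
// ---------------------------------------------------------------------------

// Median over a kh x kw rectangular window anchored at the pixel (the pixel
// is the top-left element of the window), matching the anchoring of even
// footprints in common image libraries.  For even counts the upper-middle
// order statistic is used.
// [[Rcpp::export]]
NumericMatrix cpp_median_rect(const NumericMatrix& img, int kh, int kw) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)kh * kw);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = 0; dj < kw; ++dj) {
        int jj = j + dj;
        if (jj >= nc) continue;
        for (int di = 0; di < kh; ++di) {
          int ii = i + di;
          if (ii >= nr) continue;
          buf.push_back(img(ii, jj));
        }
      }
      size_t k = buf.size() / 2;  // upper middle for even sizes
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      out(i, j) = buf[k];
    }
  }
  return out;
}

// type: 0 = median, 1 = max, 2 = min, over a disk of the given radius
// (pixels whose centre distance is <= radius).
// [[Rcpp::export]]
NumericMatrix cpp_rank_disk(const NumericMatrix& img, int radius, int type) {
  const int nr = img.nrow(), nc = img.ncol();
  // precompute disk offsets
  std::vector<int> dr, dc;
  const double r2 = (double)radius * radius;
  for (int di = -radius; di <= radius; ++di)
    for (int dj = -radius; dj <= radius; ++dj)
      if ((double)di * di + (double)dj * dj <= r2) { dr.push_back(di); dc.push_back(dj); }
  const int nk = (int)dr.size();
  NumericMatrix out(nr, nc);
  // integral images over the bounding square let constant neighbourhoods
  // (most of a sparse fluorescence image) bypass the rank computation
  std::vector<double> S((size_t)(nr + 1) * (nc + 1), 0.0),
      S2((size_t)(nr + 1) * (nc + 1), 0.0);
  auto at = [&](std::vector<double>& tbl, int i, int j) -> double& {
    return tbl[(size_t)i * (nc + 1) + j];
  };
  for (int i = 1; i <= nr; ++i)
    for (int j = 1; j <= nc; ++j) {
      double v = img(i - 1, j - 1);
      at(S, i, j) = v + at(S, i - 1, j) + at(S, i, j - 1) - at(S, i - 1, j - 1);
      at(S2, i, j) = v * v + at(S2, i - 1, j) + at(S2, i, j - 1) - at(S2, i - 1, j - 1);
    }
  std::vector<double> buf;
  buf.reserve(nk);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      {
        int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
        int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
        double n = (double)(i1 - i0 + 1) * (j1 - j0 + 1);
        double s = at(S, i1 + 1, j1 + 1) - at(S, i0, j1 + 1) - at(S, i1 + 1, j0) + at(S, i0, j0);
        double s2 = at(S2, i1 + 1, j1 + 1) - at(S2, i0, j1 + 1) - at(S2, i1 + 1, j0) + at(S2, i0, j0);
        if (s2 - s * s / n <= 1e-9) { out(i, j) = img(i, j); continue; }
      }
      buf.clear();
      for (int k = 0; k < nk; ++k) {
        int ii = i + dr[k], jj = j + dc[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        buf.push_back(img(ii, jj));
      }
      if (type == 0) {
        size_t k = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + k, buf.end());
        out(i, j) = buf[k];
      } else if (type == 1) {
        out(i, j) = *std::max_element(buf.begin(), buf.end());
      } else {
        out(i, j) = *std::min_element(buf.begin(), buf.end());
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// separable convolution (reflect boundary) for 2-D and 3-D Gaussian blur
// ---------------------------------------------------------------------------

static inline int reflect_idx(int i, int n) {
  // reflect-101 style without repeating the edge twice for small overshoot
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Convolve a 3-D array (dims ny, nx, nz; column-major, y fastest) with a 1-D
// kernel along axis (1 = y, 2 = x, 3 = z).  Kernel length must be odd.
// [[Rcpp::export]]
NumericVector cpp_conv3d_axis(const NumericVector& arr, const IntegerVector& dim,
                              const NumericVector& kernel, int axis) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const int kn = kernel.size(), kr = kn / 2;
  NumericVector out(arr.size());
  const double* a = arr.begin();
  double* o = out.begin();
  auto idx = [&](int y, int x, int z) -> size_t {
    return (size_t)y + (size_t)ny * ((size_t)x + (size_t)nx * z);
  };
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        double s = 0.0;
        for (int k = 0; k < kn; ++k) {
          int off = k - kr;
          int yy = y, xx = x, zz = z;
          if (axis == 1) yy = reflect_idx(y + off, ny);
          else if (axis == 2) xx = reflect_idx(x + off, nx);
          else zz = reflect_idx(z + off, nz);
          s += kernel[k] * a[idx(yy, xx, zz)];
        }
        o[idx(y, x, z)] = s;
      }
  return out;
}

// ---------------------------------------------------------------------------
// flat rectangular erosion / dilation on a 3-D array (for the rolling-ball
// equivalent background opening at a large scale)
// ---------------------------------------------------------------------------

// type: 1 = max (dilate), 2 = min (erode); window half-widths per axis.
// [[Rcpp::export]]
NumericVector cpp_morph3d_rect(const NumericVector& arr, const IntegerVector& dim,
                               int ry, int rx, int rz, int type) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  auto idx = [&](int y, int x, int z) -> size_t {
    return (size_t)y + (size_t)ny * ((size_t)x + (size_t)nx * z);
  };
  // separable: three 1-D passes
  NumericVector cur = clone(arr);
  for (int axis = 1; axis <= 3; ++axis) {
    int r = axis == 1 ? ry : (axis == 2 ? rx : rz);
    if (r <= 0) continue;
    NumericVector nxt(arr.size());
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y) {
          double best = cur[idx(y, x, z)];
          for (int off = -r; off <= r; ++off) {
            int yy = y, xx = x, zz = z;
            if (axis == 1) yy = y + off;
            else if (axis == 2) xx = x + off;
            else zz = z + off;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
              continue;
            double v = cur[idx(yy, xx, zz)];
            if (type == 1) { if (v > best) best = v; }
            else { if (v < best) best = v; }
          }
          nxt[idx(y, x, z)] = best;
        }
    cur = nxt;
  }
  return cur;
}

// ---------------------------------------------------------------------------
// grayscale rolling-ball background (2-D): opening with a ball-height
// structuring element of the given radius
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_rolling_ball(const NumericMatrix& img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dr, dc;
  std::vector<double> h;
  const double r2 = (double)radius * radius;
  for (int di = -radius; di <= radius; ++di)
    for (int dj = -radius; dj <= radius; ++dj) {
      double d2 = (double)di * di + (double)dj * dj;
      if (d2 <= r2) {
        dr.push_back(di); dc.push_back(dj);
        h.push_back(std::sqrt(r2 - d2));
      }
    }
  const int nk = (int)dr.size();
  NumericMatrix ero(nr, nc), bg(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = R_PosInf;
      for (int k = 0; k < nk; ++k) {
        int ii = i + dr[k], jj = j + dc[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = img(ii, jj) - h[k];
        if (v < m) m = v;
      }
      ero(i, j) = m;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < nk; ++k) {
        int ii = i - dr[k], jj = j - dc[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = ero(ii, jj) + h[k];
        if (v > m) m = v;
      }
      bg(i, j) = m;
    }
  return bg;
}

// ---------------------------------------------------------------------------
// local outlier replacement (background modelling): replace a pixel by the
// local median when it deviates from that median by more than sd_factor
// times the local standard deviation within a (2r+1)^2 block
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_remove_outliers(const NumericMatrix& img, int radius,
                                  double sd_factor) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  // integral images for local mean / sd
  std::vector<double> S((nr + 1) * (nc + 1), 0.0), S2((nr + 1) * (nc + 1), 0.0);
  auto at = [&](std::vector<double>& t, int i, int j) -> double& {
    return t[(size_t)i * (nc + 1) + j];
  };
  for (int i = 1; i <= nr; ++i)
    for (int j = 1; j <= nc; ++j) {
      double v = img(i - 1, j - 1);
      at(S, i, j)  = v     + at(S, i - 1, j) + at(S, i, j - 1) - at(S, i - 1, j - 1);
      at(S2, i, j) = v * v + at(S2, i - 1, j) + at(S2, i, j - 1) - at(S2, i - 1, j - 1);
    }
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
      int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
      double n = (double)(i1 - i0 + 1) * (j1 - j0 + 1);
      double s  = at(S, i1 + 1, j1 + 1) - at(S, i0, j1 + 1) - at(S, i1 + 1, j0) + at(S, i0, j0);
      double s2 = at(S2, i1 + 1, j1 + 1) - at(S2, i0, j1 + 1) - at(S2, i1 + 1, j0) + at(S2, i0, j0);
      double var = (s2 - s * s / n) / std::max(1.0, n - 1.0);
      double sd = var > 0 ? std::sqrt(var) : 0.0;
      if (sd <= 1e-9) { out(i, j) = img(i, j); continue; }  // constant block
      buf.clear();
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii) buf.push_back(img(ii, jj));
      size_t k = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      double med = buf[k];
      double v = img(i, j);
      out(i, j) = (std::fabs(v - med) > sd_factor * sd) ? med : v;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// connected-component labelling
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label2d(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int, int>> nb;
  nb = {{-1, 0}, {1, 0}, {0, -1}, {0, 1}};
  if (connectivity == 8) {
    nb.push_back({-1, -1}); nb.push_back({-1, 1});
    nb.push_back({1, -1});  nb.push_back({1, 1});
  }
  std::queue<std::pair<int, int>> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push({i, j});
      while (!q.empty()) {
        auto [ci, cj] = q.front(); q.pop();
        for (auto& d : nb) {
          int ii = ci + d.first, jj = cj + d.second;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && !lab(ii, jj)) { lab(ii, jj) = next; q.push({ii, jj}); }
        }
      }
    }
  return lab;
}

// 3-D labelling, 26-connectivity (or 6).  mask is a logical/integer vector
// with dims (ny, nx, nz), column-major.
// [[Rcpp::export]]
IntegerVector cpp_label3d(const IntegerVector& mask, const IntegerVector& dim,
                          int connectivity) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  auto idx = [&](int y, int x, int z) -> size_t {
    return (size_t)y + (size_t)ny * ((size_t)x + (size_t)nx * z);
  };
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<std::array<int, 3>> q;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        size_t p = idx(y, x, z);
        if (!mask[p] || lab[p]) continue;
        lab[p] = ++next;
        q.push({y, x, z});
        while (!q.empty()) {
          auto c = q.front(); q.pop();
          for (int dz = -1; dz <= 1; ++dz)
            for (int dx = -1; dx <= 1; ++dx)
              for (int dy = -1; dy <= 1; ++dy) {
                if (!dy && !dx && !dz) continue;
                int ad = std::abs(dy) + std::abs(dx) + std::abs(dz);
                if (connectivity == 6 && ad != 1) continue;
                int yy = c[0] + dy, xx = c[1] + dx, zz = c[2] + dz;
                if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
                  continue;
                size_t pp = idx(yy, xx, zz);
                if (mask[pp] && !lab[pp]) { lab[pp] = next; q.push({yy, xx, zz}); }
              }
        }
      }
  lab.attr("dim") = dim;
  lab.attr("n_labels") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Moore-neighbour boundary tracing of a single connected object
// ---------------------------------------------------------------------------

// Returns an ordered closed boundary as a k x 2 matrix of 1-based (row, col),
// oriented counter-clockwise in standard (x = col, y = -row) orientation.
// Moore-neighbour tracing with Jacob's stopping criterion.
// [[Rcpp::export]]
IntegerMatrix cpp_trace_boundary(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  // clockwise neighbour order in image coords (row down)
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  auto fg = [&](int i, int j) -> bool {
    return i >= 0 && i < nr && j >= 0 && j < nc && mask(i, j) != 0;
  };
  // start: topmost-leftmost foreground pixel
  int si = -1, sj = -1;
  for (int i = 0; i < nr && si < 0; ++i)
    for (int j = 0; j < nc; ++j)
      if (mask(i, j)) { si = i; sj = j; break; }
  if (si < 0) stop("empty mask");
  std::vector<int> ri, cj;
  int ci = si, cjj = sj;          // current boundary pixel
  int bi = si, bj = sj - 1;       // backtrack (background) cell, W of start
  const int b0i = bi, b0j = bj;
  ri.push_back(ci); cj.push_back(cjj);
  const size_t cap = (size_t)nr * nc * 4 + 16;
  bool moved = false;
  while (true) {
    // direction index from current pixel toward the backtrack cell
    int d0 = -1;
    for (int d = 0; d < 8; ++d)
      if (ci + dr[d] == bi && cjj + dc[d] == bj) { d0 = d; break; }
    if (d0 < 0) stop("internal error in boundary tracing");
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (d0 + k) % 8;  // clockwise sweep starting just after backtrack
      if (fg(ci + dr[d], cjj + dc[d])) { found = d; break; }
      bi = ci + dr[d]; bj = cjj + dc[d];  // last background cell checked
    }
    if (found < 0) break;  // isolated single pixel
    ci += dr[found]; cjj += dc[found];
    if (ci == si && cjj == sj && bi == b0i && bj == b0j && moved) break;
    if (ci == si && cjj == sj && !moved) {
      // immediate return for 2-pixel objects still counts as a move
    }
    moved = true;
    if (!(ci == si && cjj == sj)) { ri.push_back(ci); cj.push_back(cjj); }
    else if (!(bi == b0i && bj == b0j)) { ri.push_back(ci); cj.push_back(cjj); }
    if ((size_t)ri.size() > cap) stop("boundary tracing failed to terminate");
  }
  // remove consecutive duplicates (start may have been re-appended)
  std::vector<int> ri2, cj2;
  for (size_t k = 0; k < ri.size(); ++k) {
    size_t nxt = (k + 1) % ri.size();
    if (ri[k] == ri[nxt] && cj[k] == cj[nxt] && ri.size() > 1) continue;
    ri2.push_back(ri[k]); cj2.push_back(cj[k]);
  }
  ri.swap(ri2); cj.swap(cj2);
  int n = (int)ri.size();
  // orientation: make counter-clockwise with y pointing up (= -row)
  double area2 = 0.0;
  for (int k = 0; k < n; ++k) {
    int k2 = (k + 1) % n;
    double x1 = cj[k], y1 = -ri[k], x2 = cj[k2], y2 = -ri[k2];
    area2 += x1 * y2 - x2 * y1;
  }
  IntegerMatrix out(n, 2);
  if (area2 >= 0) {
    for (int k = 0; k < n; ++k) { out(k, 0) = ri[k] + 1; out(k, 1) = cj[k] + 1; }
  } else {
    for (int k = 0; k < n; ++k) {
      out(k, 0) = ri[n - 1 - k] + 1; out(k, 1) = cj[n - 1 - k] + 1;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// minimum pairwise anisotropic distance between two voxel coordinate sets
// ---------------------------------------------------------------------------

// A, B: n x 3 matrices of (z, y, x) voxel indices; w: physical spacing per
// axis in the same order.  Returns the minimum Euclidean distance in
// physical units.
// [[Rcpp::export]]
double cpp_min_pair_dist(const NumericMatrix& A, const NumericMatrix& B,
                         const NumericVector& w) {
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i) {
    for (int j = 0; j < B.nrow(); ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = (A(i, k) - B(j, k)) * w[k];
        s += d * d;
      }
      if (s < best) {
        best = s;
        if (best == 0.0) return 0.0;
      }
    }
  }
  return std::sqrt(best);
}
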