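// Low-level voxel kernels for 3D shell volumes.
// All arrays are column-major (R layout): idx = i + nx*(j + ny*k), 0-based.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
#include <limits>
#include <functional>
#include <algorithm>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
// Large finite stand-in for "no source on this line yet"; squared voxel
// distances never exceed ~3 * nmax^2, far below this.
static const double BIG = 1e15;

// Neighbor offsets for 6/18/26 connectivity.
static void neighbor_offsets(int connectivity,
                             std::vector<int>& di, std::vector<int>& dj,
                             std::vector<int>& dk) {
  di.clear(); dj.clear(); dk.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) { parent[find(a)] = find(b); }
};

// Connected components of a boolean mask. Labels are assigned in raster-scan
// order of first discovery, so results are deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<int> di, dj, dk;
  neighbor_offsets(connectivity, di, dj, dk);
  int nb = (int)di.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int k = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v % ((R_xlen_t)nx * ny));
      int j = rem / nx, i = rem % nx;
      for (int t = 0; t < nb; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] && labels[w] == 0) { labels[w] = next; stack.push_back(w); }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// 1D squared distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher). f values are finite (BIG where unseeded).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  auto inter = [&](int q, int p) {
    return ((f[q] + q * (double)q) - (f[p] + p * (double)p)) / (2.0 * (q - p));
  };
  for (int q = 1; q < n; ++q) {
    double s = inter(q, v[k]);
    while (s <= z[k]) { --k; s = inter(q, v[k]); }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = (q - p) * (double)(q - p) + f[p];
  }
}

// Exact Euclidean distance transform: distance (in voxel units x spacing)
// from each TRUE voxel to the nearest FALSE voxel; 0 on FALSE voxels.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector fg, IntegerVector dim, double spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t s = 0; s < n; ++s) g[s] = fg[s] ? BIG : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, nx);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        f[j] = g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, ny);
      for (int j = 0; j < ny; ++j)
        g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k)
        f[k] = g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, nz);
      for (int k = 0; k < nz; ++k)
        g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
    }
  NumericVector out(n);
  for (R_xlen_t s = 0; s < n; ++s)
    out[s] = (g[s] >= BIG / 2) ? R_PosInf : spacing * std::sqrt(g[s]);
  out.attr("dim") = dim;
  return out;
}

// Hierarchical watershed on a distance map. Voxels with dist > 0 are
// foreground. Voxels are processed in decreasing distance order (ties by
// linear index); a basin is born at each unclaimed local maximum. When two
// basins meet at a saddle of height h, they merge if
// min(peak_a, peak_b) - h < persistence; otherwise the meeting voxel joins
// the surviving basin with the smaller label id. Labels are finally
// renumbered 1..K in order of basin birth.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector dist, IntegerVector dim,
                            double persistence, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<R_xlen_t> order;
  order.reserve(n / 4);
  for (R_xlen_t s = 0; s < n; ++s)
    if (dist[s] > 0) order.push_back(s);
  std::stable_sort(order.begin(), order.end(),
                   [&](R_xlen_t a, R_xlen_t b) {
                     if (dist[a] != dist[b]) return dist[a] > dist[b];
                     return a < b;
                   });
  std::vector<int> di, dj, dk;
  neighbor_offsets(connectivity, di, dj, dk);
  int nb = (int)di.size();

  std::vector<int> basin(n, 0);          // basin id per voxel (1-based)
  std::vector<double> peak;              // peak height per basin (index id-1)
  std::vector<int> parent;               // union-find over basin ids (id-1)
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  std::vector<int> roots;
  for (R_xlen_t t = 0; t < (R_xlen_t)order.size(); ++t) {
    R_xlen_t v = order[t];
    double h = dist[v];
    int k = (int)(v / ((R_xlen_t)nx * ny));
    int rem = (int)(v % ((R_xlen_t)nx * ny));
    int j = rem / nx, i = rem % nx;
    roots.clear();
    for (int q = 0; q < nb; ++q) {
      int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (basin[w] > 0) {
        int r = find(basin[w] - 1);
        bool seen = false;
        for (int rr : roots) if (rr == r) { seen = true; break; }
        if (!seen) roots.push_back(r);
      }
    }
    if (roots.empty()) {
      peak.push_back(h);
      parent.push_back((int)parent.size());
      basin[v] = (int)parent.size();
      continue;
    }
    // Merge all pairs (against the strongest root) with shallow saddles.
    std::sort(roots.begin(), roots.end(), [&](int a, int b) {
      if (peak[a] != peak[b]) return peak[a] > peak[b];
      return a < b;
    });
    int keep = roots[0];
    std::vector<int> survivors;
    survivors.push_back(keep);
    for (size_t q = 1; q < roots.size(); ++q) {
      int r = roots[q];
      if (std::min(peak[keep], peak[r]) - h < persistence) {
        // merge r into keep
        parent[r] = keep;
        if (peak[r] > peak[keep]) peak[keep] = peak[r];
      } else {
        survivors.push_back(r);
      }
    }
    int assign = survivors[0];
    for (int r : survivors) if (r < assign) assign = r;
    basin[v] = assign + 1;
  }
  // Renumber surviving roots compactly in id (birth) order.
  std::vector<int> newid(parent.size(), 0);
  int next = 0;
  for (size_t b = 0; b < parent.size(); ++b)
    if (find((int)b) == (int)b) newid[b] = ++next;
  IntegerVector out(n, 0);
  for (R_xlen_t s = 0; s < n; ++s)
    if (basin[s] > 0) out[s] = newid[find(basin[s] - 1)];
  out.attr("dim") = dim;
  return out;
}

// Marker-based watershed restricted to `region`: grows labels from marker
// voxels in decreasing distance order (priority flood).
// [[Rcpp::export]]
IntegerVector cpp_marker_watershed(NumericVector dist, IntegerVector dim,
                                   IntegerVector markers, LogicalVector region,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  std::vector<int> di, dj, dk;
  neighbor_offsets(connectivity, di, dj, dk);
  int nb = (int)di.size();
  struct Item { double h; long long seq; R_xlen_t v; int lab; };
  struct Cmp {
    bool operator()(const Item& a, const Item& b) const {
      if (a.h != b.h) return a.h < b.h;       // max-heap on height
      return a.seq > b.seq;                   // FIFO on ties
    }
  };
  std::priority_queue<Item, std::vector<Item>, Cmp> pq;
  long long seq = 0;
  for (R_xlen_t s = 0; s < n; ++s)
    if (markers[s] > 0 && region[s]) pq.push({dist[s], seq++, s, markers[s]});
  while (!pq.empty()) {
    Item it = pq.top(); pq.pop();
    if (out[it.v] != 0) continue;
    out[it.v] = it.lab;
    int k = (int)(it.v / ((R_xlen_t)nx * ny));
    int rem = (int)(it.v % ((R_xlen_t)nx * ny));
    int j = rem / nx, i = rem % nx;
    for (int q = 0; q < nb; ++q) {
      int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (region[w] && out[w] == 0) pq.push({dist[w], seq++, w, it.lab});
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Counts of face-adjacent (6-connectivity) voxel pairs between distinct
// positive labels. Returns a 3-column matrix (a, b, count) with a < b.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_counts(IntegerVector labels, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::map<std::pair<int,int>, int> counts;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        int a = labels[v];
        if (a <= 0) continue;
        const int off[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
        for (int t = 0; t < 3; ++t) {
          int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
          if (ii >= nx || jj >= ny || kk >= nz) continue;
          R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          int b = labels[w];
          if (b <= 0 || b == a) continue;
          std::pair<int,int> key(std::min(a,b), std::max(a,b));
          counts[key] += 1;
        }
      }
  IntegerMatrix out((int)counts.size(), 3);
  int r = 0;
  for (auto& kv : counts) {
    out(r,0) = kv.first.first; out(r,1) = kv.first.second; out(r,2) = kv.second;
    ++r;
  }
  colnames(out) = CharacterVector::create("a", "b", "count");
  return out;
}

// Synchronous face-dilation of labels: unlabeled voxels take the smallest
// positive label among their 6-neighbors; `rounds` iterations.
// [[Rcpp::export]]
IntegerVector cpp_dilate_labels(IntegerVector labels, IntegerVector dim,
                                int rounds) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> cur(labels.begin(), labels.end()), nxt(n);
  for (int r = 0; r < rounds; ++r) {
    for (R_xlen_t s = 0; s < n; ++s) nxt[s] = cur[s];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          if (cur[v] != 0) continue;
          int best = 0;
          const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
          for (int t = 0; t < 6; ++t) {
            int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            int b = cur[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
            if (b > 0 && (best == 0 || b < best)) best = b;
          }
          if (best > 0) nxt[v] = best;
        }
    std::swap(cur, nxt);
  }
  IntegerVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = cur[s];
  out.attr("dim") = dim;
  return out;
}

// Separable Gaussian blur with truncated, renormalized kernels at borders.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector img, IntegerVector dim,
                                double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(clone(img));
  if (sigma <= 0) { out.attr("dim") = dim; return out; }
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  for (int t = -rad; t <= rad; ++t)
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  std::vector<double> res(buf.size());
  auto pass = [&](int axis) {
    int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
    R_xlen_t stride = axis == 0 ? 1 :
      (axis == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
    int n1 = axis == 0 ? ny : nx;
    int n2 = axis == 2 ? ny : nz;
    for (int b = 0; b < n2; ++b)
      for (int a = 0; a < n1; ++a) {
        R_xlen_t base;
        if (axis == 0) base = (R_xlen_t)nx * (a + (R_xlen_t)ny * b);
        else if (axis == 1) base = a + (R_xlen_t)nx * ny * b;
        else base = a + (R_xlen_t)nx * b;
        for (int t = 0; t < len; ++t) buf[t] = out[base + stride * t];
        for (int t = 0; t < len; ++t) {
          double s = 0, wsum = 0;
          int lo = std::max(0, t - rad), hi = std::min(len - 1, t + rad);
          for (int u = lo; u <= hi; ++u) {
            double w = ker[u - t + rad];
            s += w * buf[u]; wsum += w;
          }
          res[t] = s / wsum;
        }
        for (int t = 0; t < len; ++t) out[base + stride * t] = res[t];
      }
  };
  pass(0); pass(1); pass(2);
  out.attr("dim") = dim;
  return out;
}

// Per-label summaries in one pass: voxel count, centroid sums and bounding
// box (0-based index extremes) for labels 1..max.
// [[Rcpp::export]]
NumericMatrix cpp_label_stats(IntegerVector labels, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxlab = 0;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t s = 0; s < n; ++s) if (labels[s] > maxlab) maxlab = labels[s];
  NumericMatrix out(maxlab, 10);
  for (int r = 0; r < maxlab; ++r) {
    out(r,0) = 0; out(r,1) = out(r,2) = out(r,3) = 0;
    out(r,4) = out(r,6) = out(r,8) = R_PosInf;
    out(r,5) = out(r,7) = out(r,9) = R_NegInf;
  }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int lab = labels[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        if (lab <= 0) continue;
        int r = lab - 1;
        out(r,0) += 1;
        out(r,1) += i; out(r,2) += j; out(r,3) += k;
        if (i < out(r,4)) out(r,4) = i;
        if (i > out(r,5)) out(r,5) = i;
        if (j < out(r,6)) out(r,6) = j;
        if (j > out(r,7)) out(r,7) = j;
        if (k < out(r,8)) out(r,8) = k;
        if (k > out(r,9)) out(r,9) = k;
      }
  colnames(out) = CharacterVector::create(
    "count", "sum_i", "sum_j", "sum_k",
    "min_i", "max_i", "min_j", "max_j", "min_k", "max_k");
  return out;
}
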