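// 3D voxel kernels shared by the segmentation and phenotyping stages.
// Volumes are R arrays with dim = c(nz, ny, nx); the first index varies
// fastest (column-major), so linear index = z + nz * (y + ny * x).
// Border handling for the sliding-window filters is half-sample symmetric
// reflection (edge voxel repeated), applied independently per axis.

#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <set>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    else i = 2 * n - 1 - i;
  }
  return i;
}

static inline size_t lin(int i0, int i1, int i2, int n0, int n1) {
  return (size_t)i0 + (size_t)n0 * ((size_t)i1 + (size_t)n1 * (size_t)i2);
}

// [[Rcpp::export]]
NumericVector cpp_median_filter3d(NumericVector vol, IntegerVector dim, int r) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  NumericVector out(vol.size());
  const int w = 2 * r + 1;
  std::vector<double> buf((size_t)w * w * w);
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i0 = 0; i0 < n0; ++i0) {
        size_t k = 0;
        for (int d2 = -r; d2 <= r; ++d2) {
          const int j2 = reflect_idx(i2 + d2, n2);
          for (int d1 = -r; d1 <= r; ++d1) {
            const int j1 = reflect_idx(i1 + d1, n1);
            for (int d0 = -r; d0 <= r; ++d0) {
              const int j0 = reflect_idx(i0 + d0, n0);
              buf[k++] = vol[lin(j0, j1, j2, n0, n1)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
        out[lin(i0, i1, i2, n0, n1)] = buf[k / 2];
      }
  return out;
}

// Population variance of the (2r+1)^3 neighbourhood.
// [[Rcpp::export]]
NumericVector cpp_variance_filter3d(NumericVector vol, IntegerVector dim, int r) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  NumericVector out(vol.size());
  const int w = 2 * r + 1;
  const double m = (double)w * w * w;
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i0 = 0; i0 < n0; ++i0) {
        double s = 0.0, s2 = 0.0;
        for (int d2 = -r; d2 <= r; ++d2) {
          const int j2 = reflect_idx(i2 + d2, n2);
          for (int d1 = -r; d1 <= r; ++d1) {
            const int j1 = reflect_idx(i1 + d1, n1);
            for (int d0 = -r; d0 <= r; ++d0) {
              const int j0 = reflect_idx(i0 + d0, n0);
              const double v = vol[lin(j0, j1, j2, n0, n1)];
              s += v;
              s2 += v * v;
            }
          }
        }
        const double mu = s / m;
        double var = s2 / m - mu * mu;
        if (var < 0) var = 0;  // guard against round-off
        out[lin(i0, i1, i2, n0, n1)] = var;
      }
  return out;
}

// Separable Gaussian blur, truncated at 3 sigma, reflect padding.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector vol, IntegerVector dim, double sigma) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  if (sigma <= 0) return clone(vol);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double ksum = 0.0;
  for (int d = -r; d <= r; ++d) {
    ker[d + r] = std::exp(-0.5 * d * d / (sigma * sigma));
    ksum += ker[d + r];
  }
  for (double &k : ker) k /= ksum;

  std::vector<double> a(vol.begin(), vol.end()), b(vol.size());
  const int n[3] = {n0, n1, n2};
  for (int axis = 0; axis < 3; ++axis) {
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1)
        for (int i0 = 0; i0 < n0; ++i0) {
          double s = 0.0;
          int c[3] = {i0, i1, i2};
          for (int d = -r; d <= r; ++d) {
            int j[3] = {c[0], c[1], c[2]};
            j[axis] = reflect_idx(c[axis] + d, n[axis]);
            s += ker[d + r] * a[lin(j[0], j[1], j[2], n0, n1)];
          }
          b[lin(i0, i1, i2, n0, n1)] = s;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  return out;
}

// Grey min/max filter over an explicit offset set (structuring element).
// Out-of-bounds neighbours contribute `padval`.
// [[Rcpp::export]]
NumericVector cpp_minmax_filter3d(NumericVector vol, IntegerVector dim,
                                  IntegerMatrix offsets, bool take_max,
                                  double padval) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  NumericVector out(vol.size());
  const int K = offsets.nrow();
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i0 = 0; i0 < n0; ++i0) {
        double best = take_max ? -INFINITY : INFINITY;
        for (int k = 0; k < K; ++k) {
          const int j0 = i0 + offsets(k, 0);
          const int j1 = i1 + offsets(k, 1);
          const int j2 = i2 + offsets(k, 2);
          double v;
          if (j0 < 0 || j0 >= n0 || j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2)
            v = padval;
          else
            v = vol[lin(j0, j1, j2, n0, n1)];
          if (take_max ? (v > best) : (v < best)) best = v;
        }
        out[lin(i0, i1, i2, n0, n1)] = best;
      }
  return out;
}

// Binary majority filter over the 3x3x3 neighbourhood with reflect
// padding: equivalent to the radius-1 binary median (foreground iff >= 14
// of 27 are foreground) but computed with separable box sums in O(N).
// [[Rcpp::export]]
IntegerVector cpp_majority3d(IntegerVector mask, IntegerVector dim) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const size_t N = (size_t)n0 * n1 * n2;
  std::vector<int> a(mask.begin(), mask.end()), b(N);
  const int n[3] = {n0, n1, n2};
  for (int axis = 0; axis < 3; ++axis) {
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1)
        for (int i0 = 0; i0 < n0; ++i0) {
          int c[3] = {i0, i1, i2};
          int s = 0;
          for (int d = -1; d <= 1; ++d) {
            int j[3] = {c[0], c[1], c[2]};
            j[axis] = reflect_idx(c[axis] + d, n[axis]);
            s += a[lin(j[0], j[1], j[2], n0, n1)];
          }
          b[lin(i0, i1, i2, n0, n1)] = s;
        }
    std::swap(a, b);
  }
  IntegerVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = a[i] >= 14 ? 1 : 0;
  return out;
}

// 26-connected component labelling of a binary mask; labels assigned in
// scan order (z fastest), hence deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const size_t N = (size_t)n0 * n1 * n2;
  IntegerVector lab(mask.size());
  std::vector<size_t> stack;
  int next = 0;
  for (size_t i = 0; i < N; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int c0 = (int)(cur % n0);
      const int c1 = (int)((cur / n0) % n1);
      const int c2 = (int)(cur / ((size_t)n0 * n1));
      for (int d2 = -1; d2 <= 1; ++d2)
        for (int d1 = -1; d1 <= 1; ++d1)
          for (int d0 = -1; d0 <= 1; ++d0) {
            if (d0 == 0 && d1 == 0 && d2 == 0) continue;
            const int j0 = c0 + d0, j1 = c1 + d1, j2 = c2 + d2;
            if (j0 < 0 || j0 >= n0 || j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2)
              continue;
            const size_t j = lin(j0, j1, j2, n0, n1);
            if (mask[j] != 0 && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}

// Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// distance of each foreground voxel to the nearest background voxel.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
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
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector mask, IntegerVector dim) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const size_t N = (size_t)n0 * n1 * n2;
  const double INF = 1e18;
  std::vector<double> g(N);
  for (size_t i = 0; i < N; ++i) g[i] = mask[i] != 0 ? INF : 0.0;

  std::vector<double> f, d;
  // axis 0
  f.resize(n0); d.resize(n0);
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      for (int i0 = 0; i0 < n0; ++i0) f[i0] = g[lin(i0, i1, i2, n0, n1)];
      dt1d(f, d, n0);
      for (int i0 = 0; i0 < n0; ++i0) g[lin(i0, i1, i2, n0, n1)] = d[i0];
    }
  // axis 1
  f.resize(n1); d.resize(n1);
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i0 = 0; i0 < n0; ++i0) {
      for (int i1 = 0; i1 < n1; ++i1) f[i1] = g[lin(i0, i1, i2, n0, n1)];
      dt1d(f, d, n1);
      for (int i1 = 0; i1 < n1; ++i1) g[lin(i0, i1, i2, n0, n1)] = d[i1];
    }
  // axis 2
  f.resize(n2); d.resize(n2);
  for (int i1 = 0; i1 < n1; ++i1)
    for (int i0 = 0; i0 < n0; ++i0) {
      for (int i2 = 0; i2 < n2; ++i2) f[i2] = g[lin(i0, i1, i2, n0, n1)];
      dt1d(f, d, n2);
      for (int i2 = 0; i2 < n2; ++i2) g[lin(i0, i1, i2, n0, n1)] = d[i2];
    }
  NumericVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Local maxima of `vol` restricted to vol > 0: voxel >= all in-bounds
// 26-neighbours. Plateaus yield multiple maxima; the caller thins them.
// [[Rcpp::export]]
LogicalVector cpp_local_maxima3d(NumericVector vol, IntegerVector dim) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  LogicalVector out(vol.size());
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i0 = 0; i0 < n0; ++i0) {
        const size_t i = lin(i0, i1, i2, n0, n1);
        const double v = vol[i];
        if (v <= 0) { out[i] = false; continue; }
        bool ok = true;
        for (int d2 = -1; d2 <= 1 && ok; ++d2)
          for (int d1 = -1; d1 <= 1 && ok; ++d1)
            for (int d0 = -1; d0 <= 1 && ok; ++d0) {
              if (d0 == 0 && d1 == 0 && d2 == 0) continue;
              const int j0 = i0 + d0, j1 = i1 + d1, j2 = i2 + d2;
              if (j0 < 0 || j0 >= n0 || j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2)
                continue;
              if (vol[lin(j0, j1, j2, n0, n1)] > v) ok = false;
            }
        out[i] = ok;
      }
  return out;
}

// Seeded watershed by priority flooding: grow seed labels into the mask in
// order of decreasing priority (the distance map). Ties are broken by the
// smaller linear index, making the result deterministic.
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector priority, IntegerVector seeds,
                              IntegerVector mask, IntegerVector dim) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const size_t N = (size_t)n0 * n1 * n2;
  IntegerVector lab(seeds.size());
  struct Node {
    double p;
    size_t idx;
    int label;
  };
  struct Cmp {
    bool operator()(const Node &a, const Node &b) const {
      if (a.p != b.p) return a.p < b.p;  // max-heap on priority
      return a.idx > b.idx;              // then smallest index first
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  for (size_t i = 0; i < N; ++i) {
    lab[i] = seeds[i];
    if (seeds[i] > 0) pq.push({priority[i], i, seeds[i]});
  }
  while (!pq.empty()) {
    const Node nd = pq.top();
    pq.pop();
    const int c0 = (int)(nd.idx % n0);
    const int c1 = (int)((nd.idx / n0) % n1);
    const int c2 = (int)(nd.idx / ((size_t)n0 * n1));
    for (int d2 = -1; d2 <= 1; ++d2)
      for (int d1 = -1; d1 <= 1; ++d1)
        for (int d0 = -1; d0 <= 1; ++d0) {
          if (d0 == 0 && d1 == 0 && d2 == 0) continue;
          const int j0 = c0 + d0, j1 = c1 + d1, j2 = c2 + d2;
          if (j0 < 0 || j0 >= n0 || j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2)
            continue;
          const size_t j = lin(j0, j1, j2, n0, n1);
          if (mask[j] != 0 && lab[j] == 0) {
            lab[j] = nd.label;
            pq.push({priority[j], j, nd.label});
          }
        }
  }
  return lab;
}

// Per-label voxel count, centroid sums (1-based coordinates) and per-channel
// intensity sums. `channels` is a matrix with one column per channel.
// [[Rcpp::export]]
List cpp_region_stats(IntegerVector labels, IntegerVector dim,
                      NumericMatrix channels, int nlab) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const size_t N = (size_t)n0 * n1 * n2;
  const int C = channels.ncol();
  NumericVector count(nlab);
  NumericMatrix cent(nlab, 3);  // sums of (z, y, x), 1-based
  NumericMatrix sums(nlab, C);
  for (size_t i = 0; i < N; ++i) {
    const int l = labels[i];
    if (l <= 0 || l > nlab) continue;
    const int c0 = (int)(i % n0);
    const int c1 = (int)((i / n0) % n1);
    const int c2 = (int)(i / ((size_t)n0 * n1));
    count[l - 1] += 1;
    cent(l - 1, 0) += c0 + 1;
    cent(l - 1, 1) += c1 + 1;
    cent(l - 1, 2) += c2 + 1;
    for (int c = 0; c < C; ++c) sums(l - 1, c) += channels(i, c);
  }
  return List::create(_["count"] = count, _["centroid_sum"] = cent,
                      _["intensity_sum"] = sums);
}

// Unordered pairs of distinct labels whose regions come within Chebyshev
// distance `reach` of each other (reach = 1: touching under 26-connectivity;
// reach = 2: at most one background voxel between them).
// [[Rcpp::export]]
IntegerMatrix cpp_label_pairs(IntegerVector labels, IntegerVector dim, int reach) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const size_t N = (size_t)n0 * n1 * n2;
  std::set<std::pair<int, int> > pairs;
  for (size_t i = 0; i < N; ++i) {
    const int a = labels[i];
    if (a <= 0) continue;
    const int c0 = (int)(i % n0);
    const int c1 = (int)((i / n0) % n1);
    const int c2 = (int)(i / ((size_t)n0 * n1));
    for (int d2 = -reach; d2 <= reach; ++d2)
      for (int d1 = -reach; d1 <= reach; ++d1)
        for (int d0 = -reach; d0 <= reach; ++d0) {
          // scan each unordered voxel pair once (lexicographically forward)
          if (d2 < 0 || (d2 == 0 && (d1 < 0 || (d1 == 0 && d0 <= 0)))) continue;
          const int j0 = c0 + d0, j1 = c1 + d1, j2 = c2 + d2;
          if (j0 < 0 || j0 >= n0 || j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2)
            continue;
          const int b = labels[lin(j0, j1, j2, n0, n1)];
          if (b > 0 && b != a)
            pairs.insert(std::make_pair(std::min(a, b), std::max(a, b)));
        }
  }
  IntegerMatrix out((int)pairs.size(), 2);
  int r = 0;
  for (std::set<std::pair<int, int> >::const_iterator it = pairs.begin();
       it != pairs.end(); ++it, ++r) {
    out(r, 0) = it->first;
    out(r, 1) = it->second;
  }
  return out;
}
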