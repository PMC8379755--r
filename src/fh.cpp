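// Graph-based image segmentation (Felzenszwalb-Huttenlocher).
//
// Pixels form an 8-connected grid graph with edge weights equal to the
// Euclidean RGB distance between (Gaussian-smoothed) pixel colors. Edges are
// processed in nondecreasing weight order; two components C1, C2 joined by an
// edge of weight w merge iff w <= min(Int(C1) + k/|C1|, Int(C2) + k/|C2|),
// where Int(C) is the largest edge weight so far accepted inside C. A final
// pass over the same sorted edge list merges any component smaller than
// min_size into its most similar neighbor (the neighbor reachable through
// the cheapest remaining edge, since edges arrive by weight).
//
// Determinism: ties in edge weight are broken by edge construction order
// (column-major pixel order; neighbor order down, right, down-right,
// up-right), via a stable sort.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct DisjointSet {
  std::vector<int> parent;
  std::vector<int> rank_;
  std::vector<int> size;
  std::vector<double> thresh;  // Int(C) + k/|C|

  DisjointSet(int n, double k)
      : parent(n), rank_(n, 0), size(n, 1), thresh(n, k) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  // returns the new root
  int join(int a, int b) {
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
    if (rank_[a] == rank_[b]) ++rank_[a];
    return a;
  }
};

// separable Gaussian blur with reflected boundaries, in place on a copy
std::vector<double> gaussian_blur(const double* src, int H, int W, double sigma) {
  std::vector<double> out(src, src + (size_t)H * W);
  if (sigma <= 0) return out;
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; ++i) {
    kern[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + radius];
  }
  for (double& v : kern) v /= s;

  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - i - 1;
    }
    return i;
  };

  std::vector<double> tmp((size_t)H * W);
  // vertical pass (column-major storage: column c starts at c*H)
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0;
      for (int i = -radius; i <= radius; ++i)
        acc += kern[i + radius] * out[(size_t)c * H + reflect(r + i, H)];
      tmp[(size_t)c * H + r] = acc;
    }
  // horizontal pass
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0;
      for (int i = -radius; i <= radius; ++i)
        acc += kern[i + radius] * tmp[(size_t)reflect(c + i, W) * H + r];
      out[(size_t)c * H + r] = acc;
    }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".fh_segment_cpp")]]
IntegerMatrix fh_segment_cpp(NumericMatrix red, NumericMatrix green,
                             NumericMatrix blue, double k, double sigma,
                             int min_size) {
  const int H = red.nrow(), W = red.ncol();
  const size_t n = (size_t)H * W;

  std::vector<double> r = gaussian_blur(red.begin(), H, W, sigma);
  std::vector<double> g = gaussian_blur(green.begin(), H, W, sigma);
  std::vector<double> b = gaussian_blur(blue.begin(), H, W, sigma);

  // build edges in deterministic construction order
  const int dr[4] = {1, 0, 1, -1};
  const int dc[4] = {0, 1, 1, 1};
  std::vector<int> eu, ev;
  std::vector<double> ew;
  eu.reserve(4 * n); ev.reserve(4 * n); ew.reserve(4 * n);
  for (int c = 0; c < W; ++c)
    for (int rr = 0; rr < H; ++rr) {
      int u = c * H + rr;
      for (int d = 0; d < 4; ++d) {
        int r2 = rr + dr[d], c2 = c + dc[d];
        if (r2 < 0 || r2 >= H || c2 >= W) continue;
        int v = c2 * H + r2;
        double dR = r[u] - r[v], dG = g[u] - g[v], dB = b[u] - b[v];
        eu.push_back(u);
        ev.push_back(v);
        ew.push_back(std::sqrt(dR * dR + dG * dG + dB * dB));
      }
    }

  std::vector<int> order(ew.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b2) { return ew[a] < ew[b2]; });

  DisjointSet ds((int)n, k);
  for (int ei : order) {
    int a = ds.find(eu[ei]), b2 = ds.find(ev[ei]);
    if (a == b2) continue;
    double w = ew[ei];
    if (w <= ds.thresh[a] && w <= ds.thresh[b2]) {
      int root = ds.join(a, b2);
      ds.thresh[root] = w + k / ds.size[root];
    }
  }

  // absorb components below min_size
  if (min_size > 1) {
    for (int ei : order) {
      int a = ds.find(eu[ei]), b2 = ds.find(ev[ei]);
      if (a == b2) continue;
      if (ds.size[a] < min_size || ds.size[b2] < min_size) ds.join(a, b2);
    }
  }

  // contiguous labels from 0 in column-major scan order
  IntegerMatrix labels(H, W);
  std::vector<int> remap(n, -1);
  int next = 0;
  for (size_t i = 0; i < n; ++i) {
    int root = ds.find((int)i);
    if (remap[root] < 0) remap[root] = next++;
    labels[i] = remap[root];
  }
  labels.attr("n_segments") = next;
  return labels;
}
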