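// Coordinate->label decision forest used to encode a labeled atlas.
//
// Each tree is grown on a bootstrap resample of the training voxels; at
// every node exactly one of the three coordinate axes is drawn uniformly
// at random as the split candidate and the split threshold maximising the
// information gain (entropy impurity) is taken, ties resolved toward the
// lowest threshold.  If the drawn axis is constant within the node the
// remaining axes are tried in random order; a node with all coordinates
// identical becomes a leaf.  Growth stops at a depth cap.  Leaves store
// the class distribution of the training samples they received.
//
// Randomness comes from a private splitmix64 stream seeded as
// (master seed + tree index), so a forest is reproducible independently
// of R's RNG state and trees can be rebuilt in any order.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &state) {
  state += 0x9E3779B97F4A7C15ULL;
  uint64_t z = state;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double unif01(uint64_t &state) {
  return (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0); // 2^53
}

static inline int unif_int(uint64_t &state, int n) {
  int k = (int)(unif01(state) * n);
  return k >= n ? n - 1 : k;
}

static double entropy_from_counts(const std::vector<int> &counts, int total) {
  if (total <= 0) return 0.0;
  double h = 0.0;
  for (size_t c = 0; c < counts.size(); ++c) {
    if (counts[c] > 0) {
      double p = (double)counts[c] / total;
      h -= p * std::log(p);
    }
  }
  return h;
}

struct TreeBuilder {
  const IntegerMatrix &X;   // n x 3 integer voxel coordinates
  const IntegerVector &y;   // 0-based class indices
  int n_classes;
  int max_depth;
  uint64_t rng;

  std::vector<int> node_dim;      // split axis, -1 for leaf
  std::vector<double> node_thr;
  std::vector<int> node_left, node_right;
  std::vector< std::vector<double> > node_dist;

  TreeBuilder(const IntegerMatrix &X_, const IntegerVector &y_,
              int n_classes_, int max_depth_, uint64_t seed)
    : X(X_), y(y_), n_classes(n_classes_), max_depth(max_depth_), rng(seed) {}

  int new_node() {
    node_dim.push_back(-1);
    node_thr.push_back(0.0);
    node_left.push_back(-1);
    node_right.push_back(-1);
    node_dist.push_back(std::vector<double>(n_classes, 0.0));
    return (int)node_dim.size() - 1;
  }

  void make_leaf(int node, const std::vector<int> &counts, int total) {
    for (int c = 0; c < n_classes; ++c)
      node_dist[node][c] = (double)counts[c] / total;
  }

  // Best split on one axis: returns true if >= 2 distinct values; fills
  // thr/gain with the gain-maximising midpoint (lowest wins ties).
  bool best_split_on_axis(const std::vector<int> &samples, int axis,
                          double parent_h, double &thr, double &gain) {
    size_t n = samples.size();
    std::vector< std::pair<int,int> > vals(n); // (coordinate, class)
    for (size_t i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(samples[i], axis), y[samples[i]]);
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) return false;

    std::vector<int> left_counts(n_classes, 0), total_counts(n_classes, 0);
    for (size_t i = 0; i < n; ++i) total_counts[vals[i].second]++;

    bool found = false;
    double best_gain = -1.0, best_thr = 0.0;
    size_t i = 0;
    int n_left = 0;
    while (i < n) {
      int v = vals[i].first;
      while (i < n && vals[i].first == v) {
        left_counts[vals[i].second]++;
        n_left++;
        ++i;
      }
      if (i >= n) break; // no boundary after the last distinct value
      double mid = 0.5 * (v + vals[i].first);
      int n_right = (int)n - n_left;
      std::vector<int> right_counts(n_classes);
      for (int c = 0; c < n_classes; ++c)
        right_counts[c] = total_counts[c] - left_counts[c];
      double g = parent_h
        - ((double)n_left / n) * entropy_from_counts(left_counts, n_left)
        - ((double)n_right / n) * entropy_from_counts(right_counts, n_right);
      if (!found || g > best_gain + 1e-12) { // strict: keep lowest threshold on ties
        best_gain = g;
        best_thr = mid;
        found = true;
      }
    }
    if (!found) return false;
    thr = best_thr;
    gain = best_gain;
    return true;
  }

  int build(std::vector<int> &samples, int depth) {
    int node = new_node();
    int n = (int)samples.size();
    std::vector<int> counts(n_classes, 0);
    for (int i = 0; i < n; ++i) counts[y[samples[i]]]++;
    int n_present = 0;
    for (int c = 0; c < n_classes; ++c) if (counts[c] > 0) n_present++;

    if (depth >= max_depth || n_present <= 1) {
      make_leaf(node, counts, n);
      return node;
    }

    // one random axis; fall back to the remaining axes in random order
    int axes[3];
    axes[0] = unif_int(rng, 3);
    int other1 = (axes[0] + 1) % 3, other2 = (axes[0] + 2) % 3;
    if (unif01(rng) < 0.5) { axes[1] = other1; axes[2] = other2; }
    else                   { axes[1] = other2; axes[2] = other1; }

    double thr = 0.0, gain = 0.0;
    int axis = -1;
    for (int a = 0; a < 3; ++a) {
      if (best_split_on_axis(samples, axes[a], entropy_from_counts(counts, n),
                             thr, gain)) {
        axis = axes[a];
        break;
      }
    }
    if (axis < 0) { // all coordinates identical: impure leaf
      make_leaf(node, counts, n);
      return node;
    }

    std::vector<int> left, right;
    left.reserve(n); right.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(samples[i], axis) < thr) left.push_back(samples[i]);
      else right.push_back(samples[i]);
    }
    node_dim[node] = axis;
    node_thr[node] = thr;
    {
      // free the parent's sample list before recursing
      std::vector<int>().swap(samples);
    }
    int l = build(left, depth + 1);
    int r = build(right, depth + 1);
    node_left[node] = l;
    node_right[node] = r;
    return node;
  }

  List as_list() const {
    int m = (int)node_dim.size();
    IntegerVector dim(m), left(m), right(m);
    NumericVector thr(m);
    NumericMatrix dist(m, n_classes);
    for (int i = 0; i < m; ++i) {
      dim[i] = node_dim[i];
      thr[i] = node_thr[i];
      left[i] = node_left[i];
      right[i] = node_right[i];
      for (int c = 0; c < n_classes; ++c) dist(i, c) = node_dist[i][c];
    }
    return List::create(_["dim"] = dim, _["threshold"] = thr,
                        _["left"] = left, _["right"] = right,
                        _["dist"] = dist);
  }
};

// [[Rcpp::export(name = ".df_train")]]
List df_train(IntegerMatrix X, IntegerVector y, int n_classes,
              int n_trees, int max_depth, double seed) {
  int n = X.nrow();
  if (n < 1) stop("no training samples");
  if (X.ncol() != 3) stop("coordinate matrix must have 3 columns");
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    uint64_t s = (uint64_t)((int64_t)seed) + (uint64_t)t;
    TreeBuilder tb(X, y, n_classes, max_depth, s);
    // bootstrap resample, same size as the training set
    std::vector<int> samples(n);
    for (int i = 0; i < n; ++i) samples[i] = unif_int(tb.rng, n);
    tb.build(samples, 0);
    trees[t] = tb.as_list();
  }
  return trees;
}

// [[Rcpp::export(name = ".df_predict")]]
NumericMatrix df_predict(List trees, IntegerMatrix X, int n_classes,
                         bool hard_vote) {
  int n = X.nrow(), T = trees.size();
  if (X.ncol() != 3) stop("coordinate matrix must have 3 columns");
  NumericMatrix out(n, n_classes);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector dim = tr["dim"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["threshold"];
    NumericMatrix dist = tr["dist"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (dim[node] >= 0)
        node = (X(i, dim[node]) < thr[node]) ? left[node] : right[node];
      if (hard_vote) {
        int best = 0;
        for (int c = 1; c < n_classes; ++c)
          if (dist(node, c) > dist(node, best)) best = c;
        out(i, best) += 1.0;
      } else {
        for (int c = 0; c < n_classes; ++c) out(i, c) += dist(node, c);
      }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < n_classes; ++c) out(i, c) /= T;
  return out;
}
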