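// Minimal random forest classifier (CART, gini impurity, bootstrap +
// per-node feature subsampling). Kept in-package because no random-forest
// library ships with the target environment; the model is a plain R list of
// flat trees, so it serializes with saveRDS/dput like any other object.
#include <Rcpp.h>
#include <algorithm>
#include <limits>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;      // -1 => leaf
  double threshold = 0;  // go left when x <= threshold
  int left = -1, right = -1;
  int pred = -1;         // majority class at this node
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int n_class, mtry, min_node, max_depth;
  std::mt19937& rng;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int n_class_,
              int mtry_, int min_node_, int max_depth_, std::mt19937& rng_)
      : X(X_), y(y_), n_class(n_class_), mtry(mtry_), min_node(min_node_),
        max_depth(max_depth_), rng(rng_) {}

  static double gini(const std::vector<int>& counts, int total) {
    if (total == 0) return 0.0;
    double g = 1.0;
    for (int c : counts) {
      double p = static_cast<double>(c) / total;
      g -= p * p;
    }
    return g;
  }

  int majority(const std::vector<int>& idx) {
    std::vector<int> counts(n_class, 0);
    for (int i : idx) counts[y[i]]++;
    return static_cast<int>(std::max_element(counts.begin(), counts.end()) -
                            counts.begin());
  }

  int build(std::vector<int>& idx, int depth) {
    Node node;
    node.pred = majority(idx);
    int id = static_cast<int>(nodes.size());
    nodes.push_back(node);

    bool pure = true;
    for (size_t i = 1; i < idx.size(); ++i) {
      if (y[idx[i]] != y[idx[0]]) { pure = false; break; }
    }
    if (pure || static_cast<int>(idx.size()) < min_node || depth >= max_depth)
      return id;

    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    std::shuffle(feats.begin(), feats.end(), rng);

    double best_score = -std::numeric_limits<double>::infinity();
    int best_feat = -1;
    double best_thr = 0.0;
    int tried = 0;
    std::vector<std::pair<double, int>> vals;
    for (int f : feats) {
      if (tried >= mtry) break;
      vals.clear();
      for (int i : idx) vals.push_back({X(i, f), y[i]});
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;  // constant
      ++tried;
      std::vector<int> left_counts(n_class, 0), right_counts(n_class, 0);
      for (auto& v : vals) right_counts[v.second]++;
      int n = static_cast<int>(vals.size());
      int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        left_counts[vals[i].second]++;
        right_counts[vals[i].second]--;
        ++nl;
        if (vals[i].first == vals[i + 1].first) continue;
        double score = -(nl * gini(left_counts, nl) +
                         (n - nl) * gini(right_counts, n - nl));
        if (score > best_score) {
          best_score = score;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return id;

    std::vector<int> left_idx, right_idx;
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) left_idx.push_back(i);
      else right_idx.push_back(i);
    }
    if (left_idx.empty() || right_idx.empty()) return id;

    nodes[id].feature = best_feat;
    nodes[id].threshold = best_thr;
    nodes[id].left = build(left_idx, depth + 1);
    nodes[id].right = build(right_idx, depth + 1);
    return id;
  }
};

int predict_tree(const List& tree, const NumericMatrix& X, int row) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"], pred = tree["pred"];
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  }
  return pred[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_class, int ntree,
                  int mtry, int min_node, int max_depth, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  int n = X.nrow();
  List forest(ntree);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    TreeBuilder tb(X, y, n_class, mtry, min_node, max_depth, rng);
    tb.build(idx, 0);
    int m = static_cast<int>(tb.nodes.size());
    IntegerVector feature(m), left(m), right(m), pred(m);
    NumericVector threshold(m);
    for (int i = 0; i < m; ++i) {
      feature[i] = tb.nodes[i].feature;
      threshold[i] = tb.nodes[i].threshold;
      left[i] = tb.nodes[i].left;
      right[i] = tb.nodes[i].right;
      pred[i] = tb.nodes[i].pred;
    }
    forest[t] = List::create(Named("feature") = feature,
                             Named("threshold") = threshold,
                             Named("left") = left, Named("right") = right,
                             Named("pred") = pred);
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
IntegerVector rf_predict_cpp(List forest, NumericMatrix X, int n_class) {
  int n = X.nrow(), T = forest.size();
  IntegerVector out(n);
  std::vector<int> votes(n_class);
  for (int i = 0; i < n; ++i) {
    std::fill(votes.begin(), votes.end(), 0);
    for (int t = 0; t < T; ++t) {
      List tree = forest[t];
      votes[predict_tree(tree, X, i)]++;
    }
    out[i] = static_cast<int>(std::max_element(votes.begin(), votes.end()) -
                              votes.begin());
  }
  return out;
}
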