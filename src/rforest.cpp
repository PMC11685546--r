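// CART random forest: Gini splits, bootstrap bagging, per-node feature
// subsampling, mean-decrease-in-impurity importance. Written here because the
// environment ships no R random-forest package; kept deliberately small.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;            // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<std::vector<double>> prob;  // per-node class proportions
};

double gini(const std::vector<int>& counts, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int c : counts) {
    double p = static_cast<double>(c) / n;
    g -= p * p;
  }
  return g;
}

class Builder {
public:
  Builder(const NumericMatrix& X, const IntegerVector& y, int nclass, int mtry,
          int min_split, int max_depth, std::mt19937& rng, std::vector<double>& imp,
          double n_total)
    : X_(X), y_(y), nclass_(nclass), mtry_(mtry), min_split_(min_split),
      max_depth_(max_depth), rng_(rng), imp_(imp), n_total_(n_total) {}

  Tree tree;

  int build(std::vector<int>& idx, int depth) {
    int n = idx.size();
    std::vector<int> counts(nclass_, 0);
    for (int i : idx) counts[y_[i]]++;
    int node = new_node(counts, n);
    double g_node = gini(counts, n);
    bool pure = false;
    for (int c : counts) if (c == n) pure = true;
    if (pure || n < min_split_ || depth >= max_depth_) return node;

    int p = X_.ncol();
    // partial Fisher-Yates draw of mtry distinct features
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry_, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feats[j], feats[d(rng_)]);
    }

    int best_f = -1;
    double best_thr = 0.0, best_score = g_node - 1e-12;
    double best_gl = 0, best_gr = 0;
    int best_nl = 0;
    std::vector<std::pair<double, int>> vals(n);
    std::vector<int> lc(nclass_);
    for (int j = 0; j < m; ++j) {
      int f = feats[j];
      for (int i = 0; i < n; ++i) vals[i] = {X_(idx[i], f), y_[idx[i]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::fill(lc.begin(), lc.end(), 0);
      std::vector<int> rc = counts;
      for (int i = 0; i < n - 1; ++i) {
        lc[vals[i].second]++;
        rc[vals[i].second]--;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        double gl = gini(lc, nl), gr = gini(rc, nr);
        double score = (nl * gl + nr * gr) / n;
        if (score < best_score) {
          best_score = score;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          best_gl = gl; best_gr = gr; best_nl = nl;
        }
      }
    }
    if (best_f < 0) return node;

    // weighted impurity decrease, relative to the bootstrap sample size
    imp_[best_f] += (n * g_node - best_nl * best_gl - (n - best_nl) * best_gr) / n_total_;

    std::vector<int> li, ri;
    li.reserve(best_nl);
    ri.reserve(n - best_nl);
    for (int i : idx) {
      if (X_(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    tree.feature[node] = best_f;
    tree.thr[node] = best_thr;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }

private:
  int new_node(const std::vector<int>& counts, int n) {
    tree.feature.push_back(-1);
    tree.thr.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    std::vector<double> pr(nclass_, 0.0);
    for (int c = 0; c < nclass_; ++c) pr[c] = n > 0 ? static_cast<double>(counts[c]) / n : 0.0;
    tree.prob.push_back(pr);
    return static_cast<int>(tree.feature.size()) - 1;
  }

  const NumericMatrix& X_;
  const IntegerVector& y_;
  int nclass_, mtry_, min_split_, max_depth_;
  std::mt19937& rng_;
  std::vector<double>& imp_;
  double n_total_;
};

List tree_to_list(const Tree& t, int nclass) {
  int nn = t.feature.size();
  NumericMatrix prob(nn, nclass);
  for (int i = 0; i < nn; ++i) {
    for (int c = 0; c < nclass; ++c) prob(i, c) = t.prob[i][c];
  }
  return List::create(_["feature"] = wrap(t.feature), _["thr"] = wrap(t.thr),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["prob"] = prob);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_grow_forest")]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                     int mtry, int min_split, int max_depth, IntegerVector seeds) {
  int n = X.nrow(), p = X.ncol();
  List trees(ntree);
  std::vector<double> importance(p, 0.0);
  for (int t = 0; t < ntree; ++t) {
    std::mt19937 rng(static_cast<unsigned int>(seeds[t]));
    std::uniform_int_distribution<int> pick(0, n - 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    std::vector<double> imp_t(p, 0.0);
    Builder b(X, y, nclass, mtry, min_split, max_depth, rng, imp_t,
              static_cast<double>(n));
    b.build(idx, 0);
    trees[t] = tree_to_list(b.tree, nclass);
    for (int j = 0; j < p; ++j) importance[j] += imp_t[j] / ntree;
  }
  return List::create(_["trees"] = trees, _["importance"] = wrap(importance));
}

// [[Rcpp::export(name = ".cpp_predict_forest")]]
NumericMatrix cpp_predict_forest(List trees, NumericMatrix X, int nclass) {
  int n = X.nrow(), ntree = trees.size();
  NumericMatrix out(n, nclass);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"];
    NumericMatrix prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = X(i, feature[node]) <= thr[node] ? left[node] : right[node];
      }
      for (int c = 0; c < nclass; ++c) out(i, c) += prob(node, c) / ntree;
    }
  }
  return out;
}
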