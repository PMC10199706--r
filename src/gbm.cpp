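// Least-squares gradient boosting over categorical design factors.
//
// Trees split on single factor levels (x[var] == level sent right), grown
// greedily to a depth limit; each boosting round fits a tree to the current
// residuals on a subsample and updates predictions by a shrunken leaf mean.
// Variable importance is the classical relative-influence definition: the
// squared-error reduction of every split, summed per underlying factor.

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

namespace {

struct Node {
  int var;    // factor index of the split, -1 for leaf
  int level;  // level code sent right
  int left;
  int right;
  double value;  // leaf prediction (unshrunken residual mean)
};

struct Tree {
  std::vector<Node> nodes;
};

struct SplitChoice {
  int var = -1;
  int level = -1;
  double gain = 0.0;
};

// Best single-level split for the rows in `idx`. Gain is the SSE reduction
// S_L^2/n_L + S_R^2/n_R - S^2/n of residuals r. Ties keep the first
// (lowest var, lowest level) candidate.
SplitChoice best_split(const IntegerMatrix& X, const std::vector<double>& r,
                       const std::vector<int>& idx,
                       const IntegerVector& nlev, int min_node) {
  const int p = X.ncol();
  const int n = static_cast<int>(idx.size());
  double sum = 0.0;
  for (int i : idx) sum += r[i];

  SplitChoice best;
  for (int v = 0; v < p; ++v) {
    const int L = nlev[v];
    if (L < 2) continue;
    std::vector<double> lsum(L, 0.0);
    std::vector<int> lcnt(L, 0);
    for (int i : idx) {
      const int code = X(i, v);
      lsum[code] += r[i];
      lcnt[code] += 1;
    }
    for (int lev = 0; lev < L; ++lev) {
      const int nr = lcnt[lev];
      const int nl = n - nr;
      if (nr < min_node || nl < min_node) continue;
      const double sr = lsum[lev];
      const double sl = sum - sr;
      const double gain = sl * sl / nl + sr * sr / nr - sum * sum / n;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.var = v;
        best.level = lev;
      }
    }
  }
  return best;
}

int grow(Tree& tree, const IntegerMatrix& X, const std::vector<double>& r,
         const std::vector<int>& idx, const IntegerVector& nlev, int depth,
         int min_node, std::vector<double>& vim, double& total_gain) {
  double sum = 0.0;
  for (int i : idx) sum += r[i];
  const double mean = idx.empty() ? 0.0 : sum / idx.size();

  Node node{-1, -1, -1, -1, mean};
  const int id = static_cast<int>(tree.nodes.size());
  tree.nodes.push_back(node);

  if (depth <= 0 || static_cast<int>(idx.size()) < 2 * min_node) return id;
  SplitChoice sp = best_split(X, r, idx, nlev, min_node);
  if (sp.var < 0 || sp.gain <= 0.0) return id;

  std::vector<int> left_idx, right_idx;
  left_idx.reserve(idx.size());
  right_idx.reserve(idx.size());
  for (int i : idx) {
    if (X(i, sp.var) == sp.level) right_idx.push_back(i);
    else left_idx.push_back(i);
  }

  vim[sp.var] += sp.gain;
  total_gain += sp.gain;

  tree.nodes[id].var = sp.var;
  tree.nodes[id].level = sp.level;
  tree.nodes[id].left =
      grow(tree, X, r, left_idx, nlev, depth - 1, min_node, vim, total_gain);
  tree.nodes[id].right =
      grow(tree, X, r, right_idx, nlev, depth - 1, min_node, vim, total_gain);
  return id;
}

double predict_row(const Tree& tree, const IntegerMatrix& X, int row) {
  int id = 0;
  while (tree.nodes[id].var >= 0) {
    id = (X(row, tree.nodes[id].var) == tree.nodes[id].level)
             ? tree.nodes[id].right
             : tree.nodes[id].left;
  }
  return tree.nodes[id].value;
}

// One full boosting fit; fills vim (per factor) and optionally the forest.
void boost(const std::vector<double>& y, const IntegerMatrix& X,
           const IntegerVector& nlev, int n_trees, int depth,
           double learning_rate, double subsample, int min_node,
           std::mt19937& rng, std::vector<double>& vim, double& total_gain,
           double& init, std::vector<Tree>* forest) {
  const int n = static_cast<int>(y.size());
  init = 0.0;
  for (double v : y) init += v;
  init /= n;

  std::vector<double> pred(n, init);
  std::vector<double> resid(n);
  std::vector<int> all(n), bag;
  for (int i = 0; i < n; ++i) all[i] = i;
  const int n_bag = std::max(2, static_cast<int>(std::floor(subsample * n)));

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - pred[i];
    bag = all;
    if (n_bag < n) {
      // partial Fisher-Yates: first n_bag entries are the subsample
      for (int i = 0; i < n_bag; ++i) {
        std::uniform_int_distribution<int> pick(i, n - 1);
        std::swap(bag[i], bag[pick(rng)]);
      }
      bag.resize(n_bag);
    }
    Tree tree;
    grow(tree, X, resid, bag, nlev, depth, min_node, vim, total_gain);
    for (int i = 0; i < n; ++i) {
      pred[i] += learning_rate * predict_row(tree, X, i);
    }
    if (forest) forest->push_back(std::move(tree));
  }
}

List forest_to_list(const std::vector<Tree>& forest) {
  List out(forest.size());
  for (size_t t = 0; t < forest.size(); ++t) {
    const std::vector<Node>& nd = forest[t].nodes;
    const int m = static_cast<int>(nd.size());
    IntegerVector var(m), level(m), left(m), right(m);
    NumericVector value(m);
    for (int i = 0; i < m; ++i) {
      var[i] = nd[i].var;
      level[i] = nd[i].level;
      left[i] = nd[i].left;
      right[i] = nd[i].right;
      value[i] = nd[i].value;
    }
    out[t] = List::create(_["var"] = var, _["level"] = level,
                          _["left"] = left, _["right"] = right,
                          _["value"] = value);
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".gbm_fit_cpp")]]
List gbm_fit_cpp(NumericVector y, IntegerMatrix X, IntegerVector nlev,
                 int n_trees, int depth, double learning_rate,
                 double subsample, int min_node, int seed,
                 bool keep_trees) {
  const int p = X.ncol();
  std::vector<double> yy(y.begin(), y.end());
  std::vector<double> vim(p, 0.0);
  double total_gain = 0.0, init = 0.0;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<Tree> forest;
  boost(yy, X, nlev, n_trees, depth, learning_rate, subsample, min_node, rng,
        vim, total_gain, init, keep_trees ? &forest : nullptr);
  List out = List::create(
      _["vim"] = NumericVector(vim.begin(), vim.end()),
      _["total_gain"] = total_gain, _["init"] = init);
  if (keep_trees) out["trees"] = forest_to_list(forest);
  return out;
}

// [[Rcpp::export(name = ".gbm_vim_matrix_cpp")]]
NumericMatrix gbm_vim_matrix_cpp(NumericMatrix Y, IntegerMatrix X,
                                 IntegerVector nlev, int n_trees, int depth,
                                 double learning_rate, double subsample,
                                 int min_node, int seed) {
  const int n_genes = Y.nrow();
  const int p = X.ncol();
  NumericMatrix out(n_genes, p);
  for (int g = 0; g < n_genes; ++g) {
    std::vector<double> yy(Y.ncol());
    double mean = 0.0;
    for (int j = 0; j < Y.ncol(); ++j) {
      yy[j] = Y(g, j);
      mean += yy[j];
    }
    mean /= Y.ncol();
    double ss = 0.0;
    for (double v : yy) ss += (v - mean) * (v - mean);
    if (ss <= 0.0) continue;  // constant gene: all VIMs stay 0
    std::vector<double> vim(p, 0.0);
    double total_gain = 0.0, init = 0.0;
    std::mt19937 rng(static_cast<uint32_t>(seed + g));
    boost(yy, X, nlev, n_trees, depth, learning_rate, subsample, min_node,
          rng, vim, total_gain, init, nullptr);
    for (int v = 0; v < p; ++v) out(g, v) = vim[v];
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".gbm_predict_cpp")]]
NumericVector gbm_predict_cpp(List trees, double init, double learning_rate,
                              IntegerMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, init);
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector var = tr["var"], level = tr["level"], left = tr["left"],
                  right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int id = 0;
      while (var[id] >= 0) {
        id = (X(i, var[id]) == level[id]) ? right[id] : left[id];
      }
      out[i] += learning_rate * value[id];
    }
  }
  return out;
}
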