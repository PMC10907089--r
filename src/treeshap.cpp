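// Exact Shapley attribution for tree ensembles (the polynomial-time
// path-dependent algorithm), accumulated in double precision. Feature
// values and thresholds arrive pre-rounded to float32 so routing matches
// the single-precision learner exactly.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(std::vector<PathElement> &path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[unique_depth].feature_index = feature_index;
  path[unique_depth].zero_fraction = zero_fraction;
  path[unique_depth].one_fraction = one_fraction;
  path[unique_depth].pweight = unique_depth == 0 ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1) /
                           static_cast<double>(unique_depth + 1);
    path[i].pweight = zero_fraction * path[i].pweight * (unique_depth - i) /
                      static_cast<double>(unique_depth + 1);
  }
}

static void unwind_path(std::vector<PathElement> &path, int unique_depth,
                        int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (unique_depth + 1) /
                        static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
                                   (unique_depth - i) /
                                   static_cast<double>(unique_depth + 1);
    } else {
      path[i].pweight = (path[i].pweight * (unique_depth + 1)) /
                        (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const std::vector<PathElement> &path,
                               int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1) /
                         static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight -
                         tmp * zero_fraction *
                             ((unique_depth - i) /
                              static_cast<double>(unique_depth + 1));
    } else {
      total += (path[i].pweight / zero_fraction) /
               ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    }
  }
  return total;
}

struct Tree {
  const int *left;
  const int *right;
  const int *missing;
  const int *feature;  // -1 for leaves
  const double *threshold;
  const double *value;  // leaf values
  const double *cover;
};

static void tree_shap_recursive(const Tree &tree, const double *x, double *phi,
                                int node, std::vector<PathElement> path,
                                int unique_depth, double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);
  const int split_feature = tree.feature[node];
  if (split_feature < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      const PathElement &el = path[i];
      phi[el.feature_index] +=
          w * (el.one_fraction - el.zero_fraction) * tree.value[node];
    }
    return;
  }
  const double xv = x[split_feature];
  int hot, cold;
  if (ISNAN(xv)) {
    hot = tree.missing[node];
    cold = hot == tree.left[node] ? tree.right[node] : tree.left[node];
  } else if (xv < tree.threshold[node]) {
    hot = tree.left[node];
    cold = tree.right[node];
  } else {
    hot = tree.right[node];
    cold = tree.left[node];
  }
  const double w = tree.cover[node];
  const double hot_zero_fraction = tree.cover[hot] / w;
  const double cold_zero_fraction = tree.cover[cold] / w;
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  // if this feature was already split on upstream, undo that path entry
  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (path[path_index].feature_index == split_feature) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = path[path_index].zero_fraction;
    incoming_one_fraction = path[path_index].one_fraction;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tree, x, phi, hot, path, unique_depth + 1,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_feature);
  tree_shap_recursive(tree, x, phi, cold, path, unique_depth + 1,
                      cold_zero_fraction * incoming_zero_fraction, 0,
                      split_feature);
}

// walk one row down one tree (for the double-precision margin)
static double tree_predict(const Tree &tree, const double *x) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    const double xv = x[tree.feature[node]];
    if (ISNAN(xv)) {
      node = tree.missing[node];
    } else if (xv < tree.threshold[node]) {
      node = tree.left[node];
    } else {
      node = tree.right[node];
    }
  }
  return tree.value[node];
}

// cover-weighted expected leaf value of one tree
static double tree_expected(const Tree &tree, int n_nodes) {
  double total = 0, cover = 0;
  for (int j = 0; j < n_nodes; ++j) {
    if (tree.feature[j] < 0) {
      total += tree.cover[j] * tree.value[j];
      cover += tree.cover[j];
    }
  }
  return cover > 0 ? total / cover : 0.0;
}

// [[Rcpp::export]]
List treeshap_ensemble(NumericMatrix X, List trees, double base_margin) {
  const int n = X.nrow();
  const int p = X.ncol();
  NumericMatrix contrib(n, p);
  NumericVector margin(n);
  NumericVector base(n);

  std::vector<Tree> parsed;
  std::vector<int> sizes;
  std::vector<double> expected;
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    Tree tree;
    IntegerVector left = tr["left"], right = tr["right"],
                  missing = tr["missing"], feature = tr["feature"];
    NumericVector threshold = tr["threshold"], value = tr["value"],
                  cover = tr["cover"];
    tree.left = INTEGER(left);
    tree.right = INTEGER(right);
    tree.missing = INTEGER(missing);
    tree.feature = INTEGER(feature);
    tree.threshold = REAL(threshold);
    tree.value = REAL(value);
    tree.cover = REAL(cover);
    parsed.push_back(tree);
    sizes.push_back(left.size());
    expected.push_back(tree_expected(tree, left.size()));
  }
  double base_total = base_margin;
  for (size_t t = 0; t < parsed.size(); ++t) base_total += expected[t];

  std::vector<double> xrow(p);
  const int max_depth_guess = 64;
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < p; ++j) xrow[j] = X(r, j);
    double m = base_margin;
    for (size_t t = 0; t < parsed.size(); ++t) {
      const Tree &tree = parsed[t];
      m += tree_predict(tree, xrow.data());
      if (tree.feature[0] < 0) continue;  // stump-less tree: no attribution
      std::vector<PathElement> path(max_depth_guess);
      std::vector<double> phi(p, 0.0);
      tree_shap_recursive(tree, xrow.data(), phi.data(), 0, path, 0, 1.0, 1.0,
                          -1);
      for (int j = 0; j < p; ++j) contrib(r, j) += phi[j];
    }
    margin[r] = m;
    base[r] = base_total;
  }
  return List::create(_["contrib"] = contrib, _["margin"] = margin,
                      _["base"] = base);
}
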