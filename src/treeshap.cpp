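// Path-dependent TreeSHAP for binary-probability forests, plus helpers to
// route samples through trees (node covers, forest prediction).
//
// Trees are passed as flat arrays over all trees: for node i, left[i] /
// right[i] are 0-based child indices into the same arrays (-1 for a leaf),
// feature[i] the 0-based split feature, threshold[i] the split value
// (x <= threshold goes left), value[i] the leaf's positive-class
// probability, cover[i] the number of background samples reaching the
// node. tree_start gives each tree's first node index, with a final
// element equal to the total node count.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *unique_path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; i--) {
    unique_path[i + 1].pweight +=
        one_fraction * unique_path[i].pweight * (i + 1) /
        static_cast<double>(unique_depth + 1);
    unique_path[i].pweight =
        zero_fraction * unique_path[i].pweight * (unique_depth - i) /
        static_cast<double>(unique_depth + 1);
  }
}

static void unwind_path(PathElement *unique_path, int unique_depth,
                        int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1) /
                               static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
                                   (unique_depth - i) /
                                   static_cast<double>(unique_depth + 1);
    } else {
      unique_path[i].pweight =
          (unique_path[i].pweight * (unique_depth + 1)) /
          static_cast<double>(zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *unique_path,
                               int unique_depth, int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1) /
                         static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight -
                         tmp * zero_fraction * (unique_depth - i) /
                             static_cast<double>(unique_depth + 1);
    } else {
      total += (unique_path[i].pweight / zero_fraction) /
               ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    }
  }
  return total;
}

static void tree_shap_recursive(const int *left, const int *right,
                                const int *feature, const double *threshold,
                                const double *value, const double *cover,
                                const double *x, double *phi, int node,
                                int unique_depth,
                                PathElement *parent_unique_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  PathElement *unique_path = parent_unique_path + unique_depth + 1;
  std::copy(parent_unique_path, parent_unique_path + unique_depth + 1,
            unique_path);
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  if (left[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      phi[el.feature_index] +=
          w * (el.one_fraction - el.zero_fraction) * value[node];
    }
    return;
  }

  int hot_index, cold_index;
  if (x[feature[node]] <= threshold[node]) {
    hot_index = left[node];
    cold_index = right[node];
  } else {
    hot_index = right[node];
    cold_index = left[node];
  }
  const double w = cover[node];
  const double hot_zero_fraction = (w > 0) ? cover[hot_index] / w : 0.0;
  const double cold_zero_fraction = (w > 0) ? cover[cold_index] / w : 0.0;
  double incoming_zero_fraction = 1;
  double incoming_one_fraction = 1;

  // have we already split on this feature on the path?
  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (unique_path[path_index].feature_index == feature[node]) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(left, right, feature, threshold, value, cover, x, phi,
                      hot_index, unique_depth + 1, unique_path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, feature[node]);
  tree_shap_recursive(left, right, feature, threshold, value, cover, x, phi,
                      cold_index, unique_depth + 1, unique_path,
                      cold_zero_fraction * incoming_zero_fraction, 0,
                      feature[node]);
}

static int tree_max_depth(const int *left, const int *right, int node) {
  if (left[node] < 0) return 0;
  int dl = tree_max_depth(left, right, left[node]);
  int dr = tree_max_depth(left, right, right[node]);
  return 1 + (dl > dr ? dl : dr);
}

// [[Rcpp::export]]
NumericVector forest_covers_cpp(IntegerVector left, IntegerVector right,
                                IntegerVector feature,
                                NumericVector threshold,
                                IntegerVector tree_start, NumericMatrix bg) {
  const int n_nodes = left.size();
  const int n_trees = tree_start.size() - 1;
  NumericVector cover(n_nodes);
  const int n = bg.nrow();
  for (int t = 0; t < n_trees; ++t) {
    const int root = tree_start[t];
    for (int i = 0; i < n; ++i) {
      int node = root;
      for (;;) {
        cover[node] += 1;
        if (left[node] < 0) break;
        node = (bg(i, feature[node]) <= threshold[node]) ? left[node]
                                                         : right[node];
      }
    }
  }
  return cover;
}

// [[Rcpp::export]]
NumericVector forest_predict_cpp(IntegerVector left, IntegerVector right,
                                 IntegerVector feature,
                                 NumericVector threshold, NumericVector value,
                                 IntegerVector tree_start, NumericMatrix X) {
  const int n_trees = tree_start.size() - 1;
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0;
    for (int t = 0; t < n_trees; ++t) {
      int node = tree_start[t];
      while (left[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      acc += value[node];
    }
    out[i] = acc / n_trees;
  }
  return out;
}

// [[Rcpp::export]]
List treeshap_forest_cpp(IntegerVector left, IntegerVector right,
                         IntegerVector feature, NumericVector threshold,
                         NumericVector value, NumericVector cover,
                         IntegerVector tree_start, int n_features,
                         NumericMatrix X) {
  const int n_trees = tree_start.size() - 1;
  const int n = X.nrow();
  NumericMatrix phi(n, n_features);
  double base = 0;

  std::vector<double> xrow(n_features);
  for (int t = 0; t < n_trees; ++t) {
    const int root = tree_start[t];
    // expected value of this tree under the cover distribution
    double e = 0, ctot = 0;
    for (int j = tree_start[t]; j < tree_start[t + 1]; ++j) {
      if (left[j] < 0) {
        e += cover[j] * value[j];
        ctot += cover[j];
      }
    }
    if (ctot > 0) base += e / ctot;

    const int depth = tree_max_depth(left.begin(), right.begin(), root);
    std::vector<PathElement> path((depth + 2) * (depth + 3));
    std::vector<double> phirow(n_features);
    for (int i = 0; i < n; ++i) {
      for (int f = 0; f < n_features; ++f) {
        xrow[f] = X(i, f);
        phirow[f] = 0;
      }
      tree_shap_recursive(left.begin(), right.begin(), feature.begin(),
                          threshold.begin(), value.begin(), cover.begin(),
                          xrow.data(), phirow.data(), root, 0, path.data(),
                          1, 1, -1);
      for (int f = 0; f < n_features; ++f) phi(i, f) += phirow[f];
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int f = 0; f < n_features; ++f) phi(i, f) /= n_trees;
  }
  base /= n_trees;
  return List::create(_["phi"] = phi, _["base"] = base);
}
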