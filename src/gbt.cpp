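// Histogram-based gradient-boosted decision trees (leaf-wise growth).
//
// A small, deterministic Newton-boosting learner in the LightGBM mould:
// features are pre-binned into <= max_bin quantile bins, trees are grown
// best-first until num_leaves leaves, split gain is the usual
// G^2/(H + lambda) reduction, and leaf values are damped Newton steps.
// Supports squared-error regression and weighted binary logistic loss,
// which is all the pipeline needs (conditional models for chained-equation
// imputation and the shock classifier).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct Split {
  double gain = -1.0;
  int feature = -1;
  int bin = -1;  // go left if binned value <= bin
};

struct Leaf {
  std::vector<int> rows;
  double sum_g = 0.0, sum_h = 0.0;
  Split best;
  int node_id = -1;  // index in the output node arrays
};

struct TreeNodes {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;
  int add_leaf(double v) {
    feature.push_back(-1); threshold.push_back(0.0);
    left.push_back(-1); right.push_back(-1); value.push_back(v);
    return (int)feature.size() - 1;
  }
};

inline double leaf_objective(double g, double h, double l2) {
  return g * g / (h + l2);
}

void find_best_split(const Leaf& leaf, const std::vector<int>& B,
                     const std::vector<int>& nbins, int n, int p,
                     const std::vector<double>& g,
                     const std::vector<double>& h,
                     int min_data, double l2, Split* out) {
  Split best;
  const double parent = leaf_objective(leaf.sum_g, leaf.sum_h, l2);
  std::vector<double> hg, hh;
  std::vector<int> hc;
  for (int j = 0; j < p; ++j) {
    const int nb = nbins[j];
    if (nb < 2) continue;
    hg.assign(nb, 0.0); hh.assign(nb, 0.0); hc.assign(nb, 0);
    const int* col = B.data() + (size_t)j * n;
    for (int r : leaf.rows) {
      const int b = col[r];
      hg[b] += g[r]; hh[b] += h[r]; ++hc[b];
    }
    double gl = 0.0, hl = 0.0; int cl = 0;
    const int ctot = (int)leaf.rows.size();
    for (int b = 0; b < nb - 1; ++b) {
      gl += hg[b]; hl += hh[b]; cl += hc[b];
      const int cr = ctot - cl;
      if (cl < min_data) continue;
      if (cr < min_data) break;
      const double gr = leaf.sum_g - gl, hr = leaf.sum_h - hl;
      const double gain = leaf_objective(gl, hl, l2) +
                          leaf_objective(gr, hr, l2) - parent;
      if (gain > best.gain + 1e-12) {
        best.gain = gain; best.feature = j; best.bin = b;
      }
    }
  }
  *out = best;
}

}  // namespace

// [[Rcpp::export(name = ".gbt_bin")]]
List gbt_bin(NumericMatrix X, int max_bin) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> B((size_t)n * p);
  List edges_out(p);
  std::vector<double> col(n), uniq;
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) {
      double v = X(i, j);
      col[i] = R_finite(v) ? v : -std::numeric_limits<double>::infinity();
    }
    std::vector<double> sorted(col);
    std::sort(sorted.begin(), sorted.end());
    uniq.clear();
    for (double v : sorted)
      if (uniq.empty() || v > uniq.back()) uniq.push_back(v);
    std::vector<double> edges;  // bin b: value <= edges[b]; last bin open
    if ((int)uniq.size() <= max_bin) {
      for (size_t k = 0; k + 1 < uniq.size(); ++k)
        edges.push_back((uniq[k] + uniq[k + 1]) / 2.0);
    } else {
      for (int b = 1; b < max_bin; ++b) {
        size_t idx = (size_t)((double)b / max_bin * (n - 1));
        double e = sorted[idx];
        if (edges.empty() || e > edges.back()) edges.push_back(e);
      }
    }
    int* bj = B.data() + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      bj[i] = (int)(std::upper_bound(edges.begin(), edges.end(), col[i]) -
                    edges.begin());
    }
    edges_out[j] = NumericVector(edges.begin(), edges.end());
  }
  IntegerVector Bv(B.begin(), B.end());
  Bv.attr("dim") = IntegerVector::create(n, p);
  return List::create(_["bins"] = Bv, _["edges"] = edges_out);
}

// [[Rcpp::export(name = ".gbt_train")]]
List gbt_train(NumericMatrix X, NumericVector y, std::string objective,
               NumericVector w, int n_estimators, int num_leaves,
               double learning_rate, int min_data_in_leaf, double lambda_l2,
               int max_bin) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 1) stop("empty training matrix");
  List binned = gbt_bin(X, max_bin);
  IntegerVector Bv = binned["bins"];
  List edges = binned["edges"];
  std::vector<int> B(Bv.begin(), Bv.end());
  std::vector<int> nbins(p);
  std::vector<std::vector<double>> edge_vals(p);
  for (int j = 0; j < p; ++j) {
    NumericVector e = edges[j];
    edge_vals[j].assign(e.begin(), e.end());
    nbins[j] = (int)e.size() + 1;
  }

  const bool binary = (objective == "binary");
  double f0;
  double sw = 0.0, swy = 0.0;
  for (int i = 0; i < n; ++i) { sw += w[i]; swy += w[i] * y[i]; }
  if (binary) {
    double pbar = std::min(std::max(swy / sw, 1e-6), 1.0 - 1e-6);
    f0 = std::log(pbar / (1.0 - pbar));
  } else {
    f0 = swy / sw;
  }

  std::vector<double> F(n, f0), g(n), h(n);
  List trees(n_estimators);
  int used = 0;

  for (int t = 0; t < n_estimators; ++t) {
    if (binary) {
      for (int i = 0; i < n; ++i) {
        double pr = 1.0 / (1.0 + std::exp(-F[i]));
        g[i] = w[i] * (pr - y[i]);
        h[i] = std::max(w[i] * pr * (1.0 - pr), 1e-12);
      }
    } else {
      for (int i = 0; i < n; ++i) { g[i] = w[i] * (F[i] - y[i]); h[i] = w[i]; }
    }

    std::vector<Leaf> leaves;
    Leaf root;
    root.rows.resize(n);
    for (int i = 0; i < n; ++i) root.rows[i] = i;
    for (int i = 0; i < n; ++i) { root.sum_g += g[i]; root.sum_h += h[i]; }
    find_best_split(root, B, nbins, n, p, g, h, min_data_in_leaf, lambda_l2,
                    &root.best);

    TreeNodes nodes;
    root.node_id = nodes.add_leaf(0.0);
    leaves.push_back(std::move(root));

    while ((int)leaves.size() < num_leaves) {
      int best_i = -1; double best_gain = 1e-12;
      for (size_t i = 0; i < leaves.size(); ++i)
        if (leaves[i].best.gain > best_gain) {
          best_gain = leaves[i].best.gain; best_i = (int)i;
        }
      if (best_i < 0) break;

      Leaf& L = leaves[best_i];
      const int j = L.best.feature, bsplit = L.best.bin;
      Leaf lc, rc;
      const int* col = B.data() + (size_t)j * n;
      for (int r : L.rows) {
        if (col[r] <= bsplit) { lc.rows.push_back(r); lc.sum_g += g[r]; lc.sum_h += h[r]; }
        else rc.rows.push_back(r);
      }
      rc.sum_g = L.sum_g - lc.sum_g; rc.sum_h = L.sum_h - lc.sum_h;

      const int nid = L.node_id;
      nodes.feature[nid] = j;
      nodes.threshold[nid] = edge_vals[j][bsplit];
      lc.node_id = nodes.add_leaf(0.0);
      rc.node_id = nodes.add_leaf(0.0);
      nodes.left[nid] = lc.node_id;
      nodes.right[nid] = rc.node_id;

      find_best_split(lc, B, nbins, n, p, g, h, min_data_in_leaf, lambda_l2,
                      &lc.best);
      find_best_split(rc, B, nbins, n, p, g, h, min_data_in_leaf, lambda_l2,
                      &rc.best);
      leaves[best_i] = std::move(lc);
      leaves.push_back(std::move(rc));
    }

    for (const Leaf& L : leaves) {
      const double v = -L.sum_g / (L.sum_h + lambda_l2) * learning_rate;
      nodes.value[L.node_id] = v;
      for (int r : L.rows) F[r] += v;
    }

    trees[t] = List::create(
        _["feature"] = IntegerVector(nodes.feature.begin(), nodes.feature.end()),
        _["threshold"] = NumericVector(nodes.threshold.begin(), nodes.threshold.end()),
        _["left"] = IntegerVector(nodes.left.begin(), nodes.left.end()),
        _["right"] = IntegerVector(nodes.right.begin(), nodes.right.end()),
        _["value"] = NumericVector(nodes.value.begin(), nodes.value.end()));
    used = t + 1;
  }

  return List::create(_["f0"] = f0, _["trees"] = trees,
                      _["n_trees"] = used, _["objective"] = objective);
}

// [[Rcpp::export(name = ".gbt_predict_raw")]]
NumericVector gbt_predict_raw(List model, NumericMatrix X) {
  const int n = X.nrow();
  const double f0 = as<double>(model["f0"]);
  List trees = model["trees"];
  const int nt = as<int>(model["n_trees"]);
  NumericVector out(n, f0);
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        double v = X(i, feature[node]);
        if (!R_finite(v)) v = -std::numeric_limits<double>::infinity();
        node = (v <= threshold[node]) ? left[node] : right[node];
      }
      out[i] += value[node];
    }
  }
  return out;
}
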