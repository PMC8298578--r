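// Decision-tree base learners for the ensemble classifier.
//
// Two growers:
//  - a second-order (Newton) gradient-boosting grower with log-loss,
//    level-wise over presorted feature orders, recording per-feature
//    split gains (the "gain" importance metric);
//  - a Breiman-style random-forest grower (bootstrap + per-node feature
//    subsampling, Gini criterion) recording impurity-decrease
//    importance.
//
// Randomness (bootstrap, feature subsampling) flows through R's RNG, so
// set.seed() on the R side makes fits reproducible. Trees serialize as
// plain numeric matrices (feat, thr, left, right, value), one row per
// node, feat = -1 marking a leaf.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feat, left, right;
  std::vector<double> thr, value;
  int add_node() {
    feat.push_back(-1); left.push_back(-1); right.push_back(-1);
    thr.push_back(0.0); value.push_back(0.0);
    return (int)feat.size() - 1;
  }
  NumericMatrix as_matrix() const {
    int m = (int)feat.size();
    NumericMatrix out(m, 5);
    for (int i = 0; i < m; ++i) {
      out(i, 0) = feat[i]; out(i, 1) = thr[i];
      out(i, 2) = left[i]; out(i, 3) = right[i];
      out(i, 4) = value[i];
    }
    return out;
  }
};

double tree_predict_one(const NumericMatrix& tree, const NumericMatrix& X, int i) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(i, f) <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

}  // namespace

// ---------------------------------------------------------------- GBDT

// Histogram-based growing (64 bins per feature, quantile cuts), the
// standard device of modern boosting implementations: per level the
// cost is one cheap bin-accumulation pass over the samples plus 64
// gain evaluations per node-feature.

// [[Rcpp::export]]
List cpp_gbdt_fit(NumericMatrix X, IntegerVector y, int n_trees,
                  int max_depth, double eta, double lambda,
                  double min_child_weight) {
  const int n = X.nrow(), p = X.ncol();
  const int B = 64;  // histogram bins per feature

  // quantile binning: bin index per (sample, feature) + the upper edge
  // value of each bin (split "bin <= b" == "x <= edge[b]")
  std::vector<unsigned char> binX((size_t)n * p);
  std::vector<std::vector<double>> edges(p);
  {
    std::vector<double> vals(n);
    std::vector<int> ord(n);
    for (int j = 0; j < p; ++j) {
      const double* col = &X(0, j);
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::stable_sort(ord.begin(), ord.end(),
                       [col](int a, int b) { return col[a] < col[b]; });
      // distinct values
      std::vector<double> uniq;
      uniq.reserve(n);
      for (int k = 0; k < n; ++k) {
        double v = col[ord[k]];
        if (uniq.empty() || v > uniq.back()) uniq.push_back(v);
      }
      int nu = (int)uniq.size();
      std::vector<double>& ed = edges[j];
      if (nu <= B) {
        ed = uniq;
      } else {
        ed.resize(B);
        for (int b = 0; b < B; ++b) {
          int q = (int)((double)(b + 1) * nu / B) - 1;
          if (q < 0) q = 0;
          if (q >= nu) q = nu - 1;
          ed[b] = uniq[q];
        }
        ed.erase(std::unique(ed.begin(), ed.end()), ed.end());
      }
      unsigned char* bj = &binX[(size_t)j * n];
      for (int i = 0; i < n; ++i) {
        double v = col[i];
        int b = (int)(std::lower_bound(ed.begin(), ed.end(), v) - ed.begin());
        if (b >= (int)ed.size()) b = (int)ed.size() - 1;
        bj[i] = (unsigned char)b;
      }
    }
  }

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  const double base = std::log(ybar / (1.0 - ybar));

  std::vector<double> margin(n, base), g(n), h(n);
  NumericVector importance(p);
  List trees(n_trees);
  std::vector<int> node(n);

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = pr - y[i];
      h[i] = pr * (1.0 - pr);
    }
    TreeNodes tree;
    int root = tree.add_node();
    std::fill(node.begin(), node.end(), root);
    std::vector<int> level_nodes(1, root);
    std::vector<double> nodeG(1, 0.0), nodeH(1, 0.0);
    for (int i = 0; i < n; ++i) { nodeG[0] += g[i]; nodeH[0] += h[i]; }

    for (int depth = 0; ; ++depth) {
      int ns = (int)level_nodes.size();
      if (ns == 0) break;
      bool last_level = (depth >= max_depth);
      std::vector<int> slot(tree.feat.size(), -1);
      for (int s = 0; s < ns; ++s) slot[level_nodes[s]] = s;

      std::vector<double> bestGain(ns, 0.0), bestThr(ns, 0.0);
      std::vector<int> bestFeat(ns, -1);

      if (!last_level) {
        std::vector<double> parent_term(ns);
        for (int s = 0; s < ns; ++s) {
          parent_term[s] = nodeG[s] * nodeG[s] / (nodeH[s] + lambda);
        }
        // sample -> slot map (flattened; -1 for finished samples)
        std::vector<int> sslot(n, -1);
        for (int i = 0; i < n; ++i) {
          int nid = node[i];
          if (nid >= 0) sslot[i] = slot[nid];
        }
        std::vector<double> Gb(ns * B), Hb(ns * B);
        for (int j = 0; j < p; ++j) {
          int nb = (int)edges[j].size();
          if (nb < 2) continue;
          std::fill(Gb.begin(), Gb.begin() + ns * nb, 0.0);
          std::fill(Hb.begin(), Hb.begin() + ns * nb, 0.0);
          const unsigned char* bj = &binX[(size_t)j * n];
          for (int i = 0; i < n; ++i) {
            int s = sslot[i];
            if (s < 0) continue;
            int idx = s * nb + bj[i];
            Gb[idx] += g[i];
            Hb[idx] += h[i];
          }
          for (int s = 0; s < ns; ++s) {
            double GL = 0.0, HL = 0.0;
            const double* Gs = &Gb[s * nb];
            const double* Hs = &Hb[s * nb];
            for (int b = 0; b < nb - 1; ++b) {
              GL += Gs[b]; HL += Hs[b];
              double HR = nodeH[s] - HL;
              if (HL < min_child_weight || HR < min_child_weight) continue;
              double GR = nodeG[s] - GL;
              double gain = GL * GL / (HL + lambda) + GR * GR / (HR + lambda) -
                            parent_term[s];
              if (gain > bestGain[s] + 1e-12) {
                bestGain[s] = gain;
                bestFeat[s] = j;
                bestThr[s] = edges[j][b];
              }
            }
          }
        }
      }

      // finalize splits/leaves for this level
      std::vector<int> next_nodes;
      std::vector<double> nextG, nextH;
      std::vector<int> child_slot_base(ns, -1);
      for (int s = 0; s < ns; ++s) {
        int nid = level_nodes[s];
        if (bestFeat[s] >= 0) {
          int l = tree.add_node();
          int r = tree.add_node();
          tree.feat[nid] = bestFeat[s];
          tree.thr[nid] = bestThr[s];
          tree.left[nid] = l;
          tree.right[nid] = r;
          importance[bestFeat[s]] += bestGain[s];
          child_slot_base[s] = (int)next_nodes.size();
          next_nodes.push_back(l); nextG.push_back(0.0); nextH.push_back(0.0);
          next_nodes.push_back(r); nextG.push_back(0.0); nextH.push_back(0.0);
        } else {
          tree.value[nid] = -eta * nodeG[s] / (nodeH[s] + lambda);
        }
      }
      // partition samples into children (or drop into finished leaves)
      for (int i = 0; i < n; ++i) {
        int nid = node[i];
        if (nid < 0) continue;
        int s = slot[nid];
        if (s < 0) continue;
        if (bestFeat[s] < 0) {
          node[i] = -1;
        } else {
          bool goleft = X(i, bestFeat[s]) <= bestThr[s];
          int cs = child_slot_base[s] + (goleft ? 0 : 1);
          node[i] = next_nodes[cs];
          nextG[cs] += g[i];
          nextH[cs] += h[i];
        }
      }
      level_nodes.swap(next_nodes);
      nodeG.swap(nextG);
      nodeH.swap(nextH);
      if (last_level) break;
    }

    NumericMatrix tm = tree.as_matrix();
    trees[t] = tm;
    for (int i = 0; i < n; ++i) margin[i] += tree_predict_one(tm, X, i);
  }
  return List::create(_["trees"] = trees, _["base"] = base,
                      _["importance"] = importance);
}

// ---------------------------------------------------------------- RF

namespace {

struct RFGrower {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, max_depth, min_node, p;
  TreeNodes tree;
  std::vector<double>& importance;
  std::vector<int> feat_pool;

  RFGrower(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
           int max_depth_, int min_node_, std::vector<double>& imp)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_), min_node(min_node_),
        p(X_.ncol()), importance(imp), feat_pool(X_.ncol()) {
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
  }

  int grow(std::vector<int>& idx, int depth) {
    int nid = tree.add_node();
    int n = (int)idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    double pr = (double)n1 / n;
    tree.value[nid] = pr;
    if (depth >= max_depth || n < 2 * min_node || n1 == 0 || n1 == n) {
      return nid;
    }
    double gini_parent = 2.0 * pr * (1.0 - pr);

    // sample mtry features without replacement (partial Fisher-Yates);
    // candidates are evaluated in sampled (random) order so exact ties
    // resolve randomly rather than by column index.
    for (int k = 0; k < mtry; ++k) {
      int r = k + (int)(unif_rand() * (p - k));
      if (r >= p) r = p - 1;
      std::swap(feat_pool[k], feat_pool[r]);
    }

    double bestDec = 0.0, bestThr = 0.0;
    int bestFeat = -1;
    std::vector<std::pair<double, int>> vals(n);
    for (int k = 0; k < mtry; ++k) {
      int j = feat_pool[k];
      for (int a = 0; a < n; ++a) vals[a] = {X(idx[a], j), y[idx[a]]};
      std::sort(vals.begin(), vals.end());
      int nL = 0, n1L = 0;
      for (int a = 0; a < n - 1; ++a) {
        ++nL; n1L += vals[a].second;
        if (vals[a + 1].first <= vals[a].first) continue;
        int nR = n - nL, n1R = n1 - n1L;
        if (nL < min_node || nR < min_node) continue;
        double pL = (double)n1L / nL, pR = (double)n1R / nR;
        double child = (nL * 2.0 * pL * (1.0 - pL) +
                        nR * 2.0 * pR * (1.0 - pR)) / n;
        double dec = gini_parent - child;
        if (dec > bestDec + 1e-12) {
          bestDec = dec;
          bestFeat = j;
          bestThr = 0.5 * (vals[a].first + vals[a + 1].first);
        }
      }
    }
    if (bestFeat < 0) return nid;
    importance[bestFeat] += n * bestDec;
    std::vector<int> lidx, ridx;
    for (int i : idx) {
      if (X(i, bestFeat) <= bestThr) lidx.push_back(i); else ridx.push_back(i);
    }
    tree.feat[nid] = bestFeat;
    tree.thr[nid] = bestThr;
    int l = grow(lidx, depth + 1);
    int r = grow(ridx, depth + 1);
    tree.left[nid] = l;
    tree.right[nid] = r;
    return nid;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int max_depth, int min_node) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::vector<double> imp(p, 0.0);
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      idx[i] = r;
    }
    RFGrower grower(X, y, mtry, max_depth, min_node, imp);
    std::vector<int> root_idx = idx;
    grower.grow(root_idx, 0);
    trees[t] = grower.tree.as_matrix();
  }
  NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = imp[j] / n_trees;
  return List::create(_["trees"] = trees, _["importance"] = importance);
}

// ------------------------------------------------------------- predict

// Sum (GBDT: add base, apply sigmoid) or average (RF) leaf values.

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X, double base,
                                 bool average, bool sigmoid) {
  const int n = X.nrow();
  const int T = trees.size();
  NumericVector out(n, base);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) out[i] += tree_predict_one(tm, X, i);
  }
  if (average && T > 0) {
    for (int i = 0; i < n; ++i) out[i] /= T;
  }
  if (sigmoid) {
    for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  }
  return out;
}
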