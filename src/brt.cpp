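// Weighted boosted regression trees for a Bernoulli (presence/background)
// response: stagewise fitting of small least-squares regression trees to
// the deviance gradient, with shrinkage, weighted bagging and Newton leaf
// steps. Feature orders are presorted once per fit and split search is a
// single pass over each feature's sorted order, as in the classic GBM
// implementations. Uses R's RNG throughout so set.seed() governs
// reproducibility.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double LEAF_DEN_FLOOR = 1e-12;

struct Split {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
};

struct Leaf {
  int node = -1;     // index into the tree node arrays
  double W = 0.0;    // total bag weight
  double S = 0.0;    // total weighted residual
  int cnt = 0;       // bag observation count
  Split best;
};

struct TreeNodes {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value, gain, weight;
  int add(double w) {
    feature.push_back(-1);
    left.push_back(-1);
    right.push_back(-1);
    threshold.push_back(0.0);
    value.push_back(0.0);
    gain.push_back(0.0);
    weight.push_back(w);
    return (int)feature.size() - 1;
  }
};

class Fitter {
 public:
  Fitter(const NumericMatrix& X, const NumericVector& y,
         const NumericVector& w, int max_leaves, int min_obs)
      : n_(X.nrow()), p_(X.ncol()), y_(y), w_(w),
        max_leaves_(max_leaves), min_obs_(min_obs) {
    r_.resize(n_);
    h_.resize(n_);
    Xv_.resize((size_t)n_ * p_);
    order_.resize((size_t)n_ * p_);
    leaf_of_.assign(n_, -1);
    for (int j = 0; j < p_; ++j)
      for (int i = 0; i < n_; ++i) Xv_[(size_t)j * n_ + i] = X(i, j);
    std::vector<int> idx(n_);
    for (int j = 0; j < p_; ++j) {
      for (int i = 0; i < n_; ++i) idx[i] = i;
      const double* col = &Xv_[(size_t)j * n_];
      std::stable_sort(idx.begin(), idx.end(),
                       [col](int a, int b) { return col[a] < col[b]; });
      std::copy(idx.begin(), idx.end(), order_.begin() + (size_t)j * n_);
    }
  }

  double x(int i, int j) const { return Xv_[(size_t)j * n_ + i]; }
  std::vector<double> r_, h_;  // per-observation residual and hessian

  // Best split for each leaf in `update` (indices into leaves). One pass
  // per feature over the presorted order; features ascending and
  // thresholds ascending with strict improvement, so ties resolve to the
  // lowest feature index, then the lowest threshold.
  void best_splits(std::vector<Leaf>& leaves,
                   const std::vector<int>& update,
                   const std::vector<int>& leaf_slot) {
    const int L = (int)leaves.size();
    std::vector<double> WL(L), SL(L), prev(L);
    std::vector<int> cntL(L);
    std::vector<char> active(L, 0);
    for (int u : update) {
      leaves[u].best = Split();
      active[u] = 1;
    }
    for (int j = 0; j < p_; ++j) {
      for (int u : update) {
        WL[u] = SL[u] = 0.0;
        cntL[u] = 0;
      }
      const int* ord = &order_[(size_t)j * n_];
      const double* col = &Xv_[(size_t)j * n_];
      for (int k = 0; k < n_; ++k) {
        const int i = ord[k];
        const int slot = leaf_of_[i] < 0 ? -1 : leaf_slot[leaf_of_[i]];
        if (slot < 0 || !active[slot]) continue;
        const double xv = col[i];
        Leaf& lf = leaves[slot];
        if (cntL[slot] > 0 && xv > prev[slot]) {
          const int nR = lf.cnt - cntL[slot];
          if (cntL[slot] >= min_obs_ && nR >= min_obs_) {
            const double WR = lf.W - WL[slot];
            if (WL[slot] > 0.0 && WR > 0.0) {
              const double SR = lf.S - SL[slot];
              const double gain = SL[slot] * SL[slot] / WL[slot] +
                                  SR * SR / WR - lf.S * lf.S / lf.W;
              if (gain > lf.best.gain) {
                lf.best.gain = gain;
                lf.best.feature = j;
                lf.best.threshold = 0.5 * (prev[slot] + xv);
              }
            }
          }
        }
        WL[slot] += w_[i];
        SL[slot] += w_[i] * r_[i];
        ++cntL[slot];
        prev[slot] = xv;
      }
    }
  }

  // Grow one tree on the bag (leaf_of_ must mark bag members as 0) and
  // return its packed node matrix.
  NumericMatrix grow(const std::vector<int>& bag) {
    TreeNodes tree;
    std::vector<Leaf> leaves(1);
    std::vector<int> leaf_slot;  // leaf id (value in leaf_of_) -> slot
    double W0 = 0.0, S0 = 0.0;
    for (int i : bag) {
      W0 += w_[i];
      S0 += w_[i] * r_[i];
    }
    leaves[0].node = tree.add(W0);
    leaves[0].W = W0;
    leaves[0].S = S0;
    leaves[0].cnt = (int)bag.size();
    leaf_slot.assign(1, 0);
    std::vector<int> update(1, 0);
    best_splits(leaves, update, leaf_slot);

    while ((int)leaves.size() < max_leaves_) {
      int pick = -1;
      double pick_gain = 0.0;
      for (int q = 0; q < (int)leaves.size(); ++q)
        if (leaves[q].best.feature >= 0 && leaves[q].best.gain > pick_gain) {
          pick = q;
          pick_gain = leaves[q].best.gain;
        }
      if (pick < 0) break;
      const int j = leaves[pick].best.feature;
      const double thr = leaves[pick].best.threshold;
      const double pick_split_gain = leaves[pick].best.gain;
      const int pnode = leaves[pick].node;
      const int parent_leaf_id = pick;  // leaf ids equal their slot here
      // partition: left keeps the parent's leaf id slot replaced below
      Leaf lc, rc;
      const int lid = (int)leaves.size();
      const int rid = lid + 1;
      for (int i : bag) {
        if (leaf_of_[i] != parent_leaf_id) continue;
        if (x(i, j) <= thr) {
          leaf_of_[i] = lid;
          lc.W += w_[i];
          lc.S += w_[i] * r_[i];
          ++lc.cnt;
        } else {
          leaf_of_[i] = rid;
          rc.W += w_[i];
          rc.S += w_[i] * r_[i];
          ++rc.cnt;
        }
      }
      tree.feature[pnode] = j;
      tree.threshold[pnode] = thr;
      tree.gain[pnode] = pick_split_gain;
      lc.node = tree.add(lc.W);
      rc.node = tree.add(rc.W);
      tree.left[pnode] = lc.node;
      tree.right[pnode] = rc.node;
      leaves[pick].best = Split();  // parent is interior now
      leaves[pick].cnt = 0;
      leaves.push_back(lc);
      leaves.push_back(rc);
      leaf_slot.resize(leaves.size());
      leaf_slot[lid] = lid;
      leaf_slot[rid] = rid;
      update.assign(1, lid);
      update.push_back(rid);
      best_splits(leaves, update, leaf_slot);
    }

    // Newton leaf values on the Bernoulli loss
    std::vector<double> num(leaves.size(), 0.0), den(leaves.size(), 0.0);
    for (int i : bag) {
      const int q = leaf_of_[i];
      num[q] += w_[i] * r_[i];
      den[q] += w_[i] * h_[i];
    }
    for (int q = 0; q < (int)leaves.size(); ++q) {
      if (tree.feature[leaves[q].node] >= 0) continue;
      tree.value[leaves[q].node] =
          num[q] / std::max(den[q], LEAF_DEN_FLOOR);
    }

    const int nn = (int)tree.feature.size();
    NumericMatrix out(nn, 7);
    for (int q = 0; q < nn; ++q) {
      out(q, 0) = tree.feature[q];
      out(q, 1) = tree.threshold[q];
      out(q, 2) = tree.left[q];
      out(q, 3) = tree.right[q];
      out(q, 4) = tree.value[q];
      out(q, 5) = tree.gain[q];
      out(q, 6) = tree.weight[q];
    }
    colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                            "right", "value", "gain",
                                            "weight");
    return out;
  }

  // predict one observation of the training matrix through a packed tree
  double predict_row(const NumericMatrix& tree, int i) const {
    int node = 0;
    while ((int)tree(node, 0) >= 0)
      node = (x(i, (int)tree(node, 0)) <= tree(node, 1))
                 ? (int)tree(node, 2)
                 : (int)tree(node, 3);
    return tree(node, 4);
  }

  void reset_leaf_of() { std::fill(leaf_of_.begin(), leaf_of_.end(), -1); }
  void mark_bag(const std::vector<int>& bag) {
    for (int i : bag) leaf_of_[i] = 0;
  }

  const int n_, p_;
  const NumericVector y_, w_;
  const int max_leaves_, min_obs_;

 private:
  std::vector<double> Xv_;
  std::vector<int> order_;
  std::vector<int> leaf_of_;
};

// Weighted sampling without replacement (Efraimidis-Spirakis keys
// u^(1/w)); invariant to rescaling the weights.
std::vector<int> weighted_bag(const std::vector<int>& pool,
                              const NumericVector& w, int k) {
  const int n = (int)pool.size();
  std::vector<std::pair<double, int> > keys(n);
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    keys[i] = std::make_pair(std::pow(u, 1.0 / w[pool[i]]), pool[i]);
  }
  std::partial_sort(keys.begin(), keys.begin() + k, keys.end(),
                    std::greater<std::pair<double, int> >());
  std::vector<int> out(k);
  for (int i = 0; i < k; ++i) out[i] = keys[i].second;
  return out;
}

double weighted_deviance(const std::vector<double>& F,
                         const NumericVector& y, const NumericVector& w,
                         const std::vector<int>& idx) {
  double dev = 0.0, W = 0.0;
  for (int i : idx) {
    double p = 1.0 / (1.0 + std::exp(-F[i]));
    p = std::min(1.0 - 1e-12, std::max(1e-12, p));
    dev += w[i] * (y[i] * std::log(p) + (1.0 - y[i]) * std::log(1.0 - p));
    W += w[i];
  }
  return -2.0 * dev / W;
}

}  // namespace

// [[Rcpp::export(name = ".brt_fit_cpp")]]
List brt_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                 int n_trees, double shrinkage, int max_leaves,
                 double bag_fraction, int min_obs, bool early_stop,
                 double holdout_fraction, int patience) {
  RNGScope scope;
  const int n = X.nrow();

  // optional internal holdout for tree-count selection
  std::vector<int> train, holdout;
  if (early_stop) {
    std::vector<int> perm(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(perm[i], perm[j]);
    }
    int nh = std::max(1, (int)std::floor(holdout_fraction * n + 0.5));
    nh = std::min(nh, n - 2);
    holdout.assign(perm.begin(), perm.begin() + nh);
    train.assign(perm.begin() + nh, perm.end());
    std::sort(train.begin(), train.end());
    std::sort(holdout.begin(), holdout.end());
  } else {
    train.resize(n);
    for (int i = 0; i < n; ++i) train[i] = i;
  }

  double Wy = 0.0, W = 0.0;
  for (int i : train) {
    Wy += w[i] * y[i];
    W += w[i];
  }
  double pbar = std::min(1.0 - 1e-12, std::max(1e-12, Wy / W));
  const double F0 = std::log(pbar / (1.0 - pbar));

  Fitter fitter(X, y, w, max_leaves, min_obs);
  std::vector<double> F(n, F0);
  List trees(n_trees);
  std::vector<double> train_dev, hold_dev;
  int best_stage = -1;
  double best_hold = R_PosInf;
  int built = 0;

  const int n_train = (int)train.size();
  const bool do_bag = bag_fraction < 1.0;
  const int bag_size =
      do_bag ? std::max(2, (int)std::floor(bag_fraction * n_train + 0.5))
             : n_train;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      const double p = 1.0 / (1.0 + std::exp(-F[i]));
      fitter.r_[i] = y[i] - p;
      fitter.h_[i] = p * (1.0 - p);
    }
    std::vector<int> bag = do_bag ? weighted_bag(train, w, bag_size) : train;
    fitter.reset_leaf_of();
    fitter.mark_bag(bag);
    NumericMatrix tree = fitter.grow(bag);
    for (int i = 0; i < n; ++i)
      F[i] += shrinkage * fitter.predict_row(tree, i);
    trees[built++] = tree;
    train_dev.push_back(weighted_deviance(F, y, w, train));
    if (early_stop) {
      const double hd = weighted_deviance(F, y, w, holdout);
      hold_dev.push_back(hd);
      if (hd < best_hold - 1e-12) {
        best_hold = hd;
        best_stage = t;
      } else if (t - best_stage >= patience) {
        break;
      }
    }
  }

  int keep = built;
  if (early_stop && best_stage >= 0) keep = best_stage + 1;
  List kept_trees(keep);
  for (int t = 0; t < keep; ++t) kept_trees[t] = trees[t];
  return List::create(
      _["intercept"] = F0, _["trees"] = kept_trees,
      _["train_deviance"] =
          NumericVector(train_dev.begin(), train_dev.begin() + keep),
      _["holdout_deviance"] =
          early_stop ? NumericVector(hold_dev.begin(),
                                     hold_dev.begin() + keep)
                     : NumericVector(0),
      _["n_trees"] = keep);
}

// [[Rcpp::export(name = ".brt_predict_cpp")]]
NumericVector brt_predict_cpp(List trees, double intercept,
                              double shrinkage, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, intercept);
  const double* xp = REAL(X);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    const double* tp = REAL(tree);
    const int nn = tree.nrow();
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while ((int)tp[node] >= 0) {
        const int f = (int)tp[node];
        node = (xp[(size_t)f * n + i] <= tp[nn + node])
                   ? (int)tp[2 * nn + node]
                   : (int)tp[3 * nn + node];
      }
      out[i] += shrinkage * tp[4 * nn + node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}
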