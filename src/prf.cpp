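// Probabilistic tree growth, split search and propagation.
//
// Conventions shared with the R layer:
//  * sample indices and feature indices are 0-based inside C++; the R
//    wrappers translate to/from 1-based,
//  * a sample crosses a split (x, dx, t) to the right with probability
//    P(N(x, dx^2) > t); dx == 0 degenerates to the step function x > t,
//  * node class distributions are probability-weighted, class-weighted
//    fractions: p_c = w_c * sum_i m_i pmf_ic / normalizer,
//  * split cost is the child-mass-weighted mean of the children's modified
//    Gini impurities; a split is accepted only if cost < parent impurity
//    minus IMP_EPS,
//  * a sample's path into a child is dropped during training when its
//    arrival mass at that child is below keep_prob (or exactly zero).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <utility>
#include <vector>

using namespace Rcpp;

static const double IMP_EPS = 1e-12;

static inline double right_prob(double x, double dx, double t) {
  if (dx == 0.0) return x > t ? 1.0 : 0.0;
  return R::pnorm(t, x, dx, /*lower_tail=*/0, /*log_p=*/0);
}

// [[Rcpp::export]]
double prf_right_prob_cpp(double x, double dx, double t) {
  if (dx < 0) stop("dx must be non-negative");
  return right_prob(x, dx, t);
}

struct BestSplit {
  int feature = -1;  // 0-based
  double threshold = 0.0;
  double cost = R_PosInf;
  bool valid = false;
};

// Weighted class distribution of a node; also returns total (unweighted)
// effective mass.  s_c = sum_i m_i pmf_ic, p_c = w_c s_c / sum_c w_c s_c.
static void node_dist(const NumericMatrix& PMF, const NumericVector& w,
                      const std::vector<int>& idx,
                      const std::vector<double>& mass,
                      std::vector<double>& dist, double& total_mass) {
  const int K = PMF.ncol();
  std::vector<double> s(K, 0.0);
  total_mass = 0.0;
  for (int c = 0; c < K; ++c) {
    const double* pc = &PMF(0, c);
    for (size_t a = 0; a < idx.size(); ++a) s[c] += mass[a] * pc[idx[a]];
  }
  for (size_t a = 0; a < idx.size(); ++a) total_mass += mass[a];
  double z = 0.0;
  dist.assign(K, 0.0);
  for (int c = 0; c < K; ++c) {
    dist[c] = w[c] * s[c];
    z += dist[c];
  }
  if (z <= 0.0) stop("degenerate node: zero total class mass");
  for (int c = 0; c < K; ++c) dist[c] /= z;
}

static inline double gini_of(const std::vector<double>& p) {
  double g = 1.0;
  for (double v : p) g -= v * v;
  return g;
}

// Exhaustive candidate-threshold search over a feature subset.
// Candidate thresholds are midpoints between consecutive distinct sorted
// feature values among samples with arrival mass >= keep_prob; costs are
// computed over *all* samples at the node (no pruning during search).
// Ties are resolved by iteration order: features ascending, thresholds
// ascending, first strict minimum wins.
static BestSplit best_split(const NumericMatrix& X, const NumericMatrix& DX,
                            const NumericMatrix& PMF, const NumericVector& w,
                            const std::vector<int>& idx,
                            const std::vector<double>& mass,
                            const std::vector<int>& subset, double min_leaf,
                            double keep_prob) {
  const int K = PMF.ncol();
  const size_t n = idx.size();
  BestSplit best;

  std::vector<const double*> pmfcol(K);
  for (int c = 0; c < K; ++c) pmfcol[c] = &PMF(0, c);

  std::vector<double> stot(K, 0.0);
  double mtot = 0.0;
  for (size_t a = 0; a < n; ++a) {
    mtot += mass[a];
    for (int c = 0; c < K; ++c) stot[c] += mass[a] * pmfcol[c][idx[a]];
  }
  if (mtot <= 0.0) return best;

  std::vector<double> qL(K), qR(K);

  for (int f : subset) {
    const double* xcol = &X(0, f);
    const double* dxcol = &DX(0, f);
    std::vector<double> vals;
    vals.reserve(n);
    for (size_t a = 0; a < n; ++a)
      if (mass[a] >= keep_prob) vals.push_back(xcol[idx[a]]);
    std::sort(vals.begin(), vals.end());
    vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
    if (vals.size() < 2) continue;

    bool zero_dx = true;
    for (size_t a = 0; a < n && zero_dx; ++a)
      if (dxcol[idx[a]] != 0.0) zero_dx = false;

    if (zero_dx) {
      // deterministic routing: single sorted sweep with running sums
      std::vector<size_t> ord(n);
      for (size_t a = 0; a < n; ++a) ord[a] = a;
      std::stable_sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
        return xcol[idx[a]] < xcol[idx[b]];
      });
      std::vector<double> sL(K, 0.0);
      double mL = 0.0;
      size_t pos = 0;
      for (size_t j = 0; j + 1 < vals.size(); ++j) {
        const double t = (vals[j] + vals[j + 1]) / 2.0;
        while (pos < n && xcol[idx[ord[pos]]] <= t) {
          const size_t a = ord[pos];
          mL += mass[a];
          for (int c = 0; c < K; ++c) sL[c] += mass[a] * pmfcol[c][idx[a]];
          ++pos;
        }
        const double mR = mtot - mL;
        if (mL < min_leaf || mR < min_leaf || mL <= 0.0 || mR <= 0.0)
          continue;
        double zL = 0.0, zR = 0.0;
        for (int c = 0; c < K; ++c) {
          qL[c] = w[c] * sL[c];
          zL += qL[c];
          qR[c] = w[c] * (stot[c] - sL[c]);
          zR += qR[c];
        }
        if (zL <= 0.0 || zR <= 0.0) continue;
        double gL = 1.0, gR = 1.0;
        for (int c = 0; c < K; ++c) {
          const double pl = qL[c] / zL, pr = qR[c] / zR;
          gL -= pl * pl;
          gR -= pr * pr;
        }
        const double cost = (mL * gL + mR * gR) / mtot;
        if (cost < best.cost) {
          best.cost = cost;
          best.feature = f;
          best.threshold = t;
          best.valid = true;
        }
      }
    } else {
      // probabilistic routing: per-candidate Gaussian tail masses
      for (size_t j = 0; j + 1 < vals.size(); ++j) {
        const double t = (vals[j] + vals[j + 1]) / 2.0;
        std::vector<double> sL(K, 0.0), sR(K, 0.0);
        double mL = 0.0, mR = 0.0;
        for (size_t a = 0; a < n; ++a) {
          const double pR = right_prob(xcol[idx[a]], dxcol[idx[a]], t);
          const double mr = mass[a] * pR;
          const double ml = mass[a] - mr;
          mL += ml;
          mR += mr;
          for (int c = 0; c < K; ++c) {
            const double pc = pmfcol[c][idx[a]];
            sL[c] += ml * pc;
            sR[c] += mr * pc;
          }
        }
        if (mL < min_leaf || mR < min_leaf || mL <= 0.0 || mR <= 0.0)
          continue;
        double zL = 0.0, zR = 0.0;
        for (int c = 0; c < K; ++c) {
          qL[c] = w[c] * sL[c];
          zL += qL[c];
          qR[c] = w[c] * sR[c];
          zR += qR[c];
        }
        if (zL <= 0.0 || zR <= 0.0) continue;
        double gL = 1.0, gR = 1.0;
        for (int c = 0; c < K; ++c) {
          const double pl = qL[c] / zL, pr = qR[c] / zR;
          gL -= pl * pl;
          gR -= pr * pr;
        }
        const double cost = (mL * gL + mR * gR) / (mL + mR);
        if (cost < best.cost) {
          best.cost = cost;
          best.feature = f;
          best.threshold = t;
          best.valid = true;
        }
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List prf_best_split_cpp(NumericMatrix X, NumericMatrix DX, NumericMatrix PMF,
                        NumericVector w, IntegerVector idx, NumericVector mass,
                        IntegerVector subset, double min_leaf,
                        double keep_prob) {
  std::vector<int> id(idx.size());
  std::vector<double> ms(mass.size());
  for (int i = 0; i < idx.size(); ++i) {
    id[i] = idx[i] - 1;
    ms[i] = mass[i];
  }
  std::vector<int> sub(subset.size());
  for (int i = 0; i < subset.size(); ++i) sub[i] = subset[i] - 1;
  std::sort(sub.begin(), sub.end());

  std::vector<double> dist;
  double mtot;
  node_dist(PMF, w, id, ms, dist, mtot);
  const double parent = gini_of(dist);

  BestSplit b = best_split(X, DX, PMF, w, id, ms, sub, min_leaf, keep_prob);
  return List::create(
      _["feature"] = b.valid ? b.feature + 1 : NA_INTEGER,
      _["threshold"] = b.valid ? b.threshold : NA_REAL,
      _["cost"] = b.valid ? b.cost : NA_REAL,
      _["improving"] = b.valid && b.cost < parent - IMP_EPS,
      _["parent_impurity"] = parent);
}

struct Grower {
  const NumericMatrix &X, &DX, &PMF;
  const NumericVector& w;
  int d, mtry, max_depth;
  double min_split, min_leaf, keep_prob;
  bool has_stream;
  List stream;
  int stream_pos = 0;

  std::vector<int> feature_, left_, right_;
  std::vector<double> thr_, mass_, decrease_;
  std::vector<std::vector<double>> dist_;
  std::vector<std::vector<int>> subsets_;  // 1-based, split-attempt order

  Grower(const NumericMatrix& X_, const NumericMatrix& DX_,
         const NumericMatrix& PMF_, const NumericVector& w_, int mtry_,
         double min_split_, double min_leaf_, double keep_prob_,
         int max_depth_, bool has_stream_, List stream_)
      : X(X_), DX(DX_), PMF(PMF_), w(w_), d(X_.ncol()), mtry(mtry_),
        max_depth(max_depth_), min_split(min_split_), min_leaf(min_leaf_),
        keep_prob(keep_prob_), has_stream(has_stream_), stream(stream_) {}

  std::vector<int> draw_subset() {
    std::vector<int> out;
    if (has_stream) {
      if (stream_pos >= stream.size())
        stop("feature-subset stream exhausted");
      IntegerVector s = stream[stream_pos++];
      out.resize(s.size());
      for (int i = 0; i < s.size(); ++i) out[i] = s[i] - 1;
    } else {
      std::vector<int> pool(d);
      for (int i = 0; i < d; ++i) pool[i] = i;
      for (int i = 0; i < mtry; ++i) {
        int j = i + (int)std::floor(unif_rand() * (d - i));
        if (j >= d) j = d - 1;
        std::swap(pool[i], pool[j]);
      }
      out.assign(pool.begin(), pool.begin() + mtry);
    }
    std::sort(out.begin(), out.end());
    return out;
  }

  int grow(const std::vector<int>& idx, const std::vector<double>& mass,
           int depth) {
    const int id = (int)feature_.size();
    feature_.push_back(-1);
    thr_.push_back(NA_REAL);
    left_.push_back(-1);
    right_.push_back(-1);
    decrease_.push_back(0.0);
    std::vector<double> dist;
    double mtot;
    node_dist(PMF, w, idx, mass, dist, mtot);
    dist_.push_back(dist);
    mass_.push_back(mtot);
    const double g = gini_of(dist);

    const bool can_split =
        mtot >= min_split && depth < max_depth && g > IMP_EPS;
    if (!can_split) return id;

    std::vector<int> sub = draw_subset();
    {
      std::vector<int> sub1(sub.size());
      for (size_t i = 0; i < sub.size(); ++i) sub1[i] = sub[i] + 1;
      subsets_.push_back(sub1);
    }
    BestSplit b =
        best_split(X, DX, PMF, w, idx, mass, sub, min_leaf, keep_prob);
    if (!b.valid || !(b.cost < g - IMP_EPS)) return id;

    std::vector<int> li, ri;
    std::vector<double> lm, rm;
    li.reserve(idx.size());
    ri.reserve(idx.size());
    for (size_t a = 0; a < idx.size(); ++a) {
      const double pR =
          right_prob(X(idx[a], b.feature), DX(idx[a], b.feature), b.threshold);
      const double mr = mass[a] * pR;
      const double ml = mass[a] - mr;
      if (ml > 0.0 && ml >= keep_prob) {
        li.push_back(idx[a]);
        lm.push_back(ml);
      }
      if (mr > 0.0 && mr >= keep_prob) {
        ri.push_back(idx[a]);
        rm.push_back(mr);
      }
    }
    if (li.empty() || ri.empty()) return id;  // pruning emptied a child

    feature_[id] = b.feature;
    thr_[id] = b.threshold;
    decrease_[id] = mtot * (g - b.cost);
    const int L = grow(li, lm, depth + 1);
    left_[id] = L;
    const int R = grow(ri, rm, depth + 1);
    right_[id] = R;
    return id;
  }
};

// [[Rcpp::export]]
List prf_grow_tree_cpp(NumericMatrix X, NumericMatrix DX, NumericMatrix PMF,
                       NumericVector w, IntegerVector boot, int mtry,
                       double min_split, double min_leaf, double keep_prob,
                       int max_depth, Nullable<List> subset_stream) {
  if (boot.size() == 0) stop("empty bootstrap");
  const bool has_stream = subset_stream.isNotNull();
  List stream = has_stream ? List(subset_stream) : List();
  Grower gr(X, DX, PMF, w, mtry, min_split, min_leaf, keep_prob,
            max_depth, has_stream, stream);
  std::vector<int> idx(boot.size());
  std::vector<double> mass(boot.size(), 1.0);
  for (int i = 0; i < boot.size(); ++i) idx[i] = boot[i] - 1;
  gr.grow(idx, mass, 0);

  const int nn = (int)gr.feature_.size();
  const int K = PMF.ncol();
  IntegerVector feature(nn), left(nn), right(nn);
  NumericVector thr(nn), mass_out(nn), decrease(nn);
  NumericMatrix dist(nn, K);
  for (int i = 0; i < nn; ++i) {
    feature[i] = gr.feature_[i] >= 0 ? gr.feature_[i] + 1 : NA_INTEGER;
    left[i] = gr.left_[i] >= 0 ? gr.left_[i] + 1 : NA_INTEGER;
    right[i] = gr.right_[i] >= 0 ? gr.right_[i] + 1 : NA_INTEGER;
    thr[i] = gr.thr_[i];
    mass_out[i] = gr.mass_[i];
    decrease[i] = gr.decrease_[i];
    for (int c = 0; c < K; ++c) dist(i, c) = gr.dist_[i][c];
  }
  List subsets(gr.subsets_.size());
  for (size_t i = 0; i < gr.subsets_.size(); ++i)
    subsets[i] = wrap(gr.subsets_[i]);
  return List::create(_["feature"] = feature, _["threshold"] = thr,
                      _["left"] = left, _["right"] = right, _["dist"] = dist,
                      _["mass"] = mass_out, _["decrease"] = decrease,
                      _["subsets"] = subsets);
}

// Per-sample class probabilities from one tree.  With prune = FALSE the
// leaf arrival masses sum to 1 (up to roundoff) and no renormalization is
// applied; with prune = TRUE sub-threshold paths are dropped and the
// output is renormalized by the surviving mass.
// [[Rcpp::export]]
NumericMatrix prf_predict_tree_cpp(List tree, NumericMatrix X,
                                   NumericMatrix DX, bool prune,
                                   double keep_prob) {
  IntegerVector feature = tree["feature"];
  NumericVector thr = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericMatrix dist = tree["dist"];
  const int K = dist.ncol(), n = X.nrow();
  NumericMatrix out(n, K);
  std::vector<std::pair<int, double>> stack;
  for (int i = 0; i < n; ++i) {
    stack.clear();
    stack.push_back({0, 1.0});
    double tot = 0.0;
    while (!stack.empty()) {
      const int nd = stack.back().first;
      const double m = stack.back().second;
      stack.pop_back();
      if (m <= 0.0) continue;
      if (prune && m < keep_prob) continue;
      if (feature[nd] == NA_INTEGER) {
        for (int c = 0; c < K; ++c) out(i, c) += m * dist(nd, c);
        tot += m;
      } else {
        const int f = feature[nd] - 1;
        const double pR = right_prob(X(i, f), DX(i, f), thr[nd]);
        stack.push_back({right[nd] - 1, m * pR});
        stack.push_back({left[nd] - 1, m * (1.0 - pR)});
      }
    }
    if (prune && tot > 0.0)
      for (int c = 0; c < K; ++c) out(i, c) /= tot;
  }
  return out;
}

// Leaf arrival masses of a single test point (nodes that are not leaves
// get 0); used by conservation tests and by the methods documentation.
// [[Rcpp::export]]
NumericVector prf_leaf_arrivals_cpp(List tree, NumericVector x,
                                    NumericVector dx, bool prune,
                                    double keep_prob) {
  IntegerVector feature = tree["feature"];
  NumericVector thr = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  const int nn = feature.size();
  NumericVector arr(nn);
  std::vector<std::pair<int, double>> stack;
  stack.push_back({0, 1.0});
  while (!stack.empty()) {
    const int nd = stack.back().first;
    const double m = stack.back().second;
    stack.pop_back();
    if (m <= 0.0) continue;
    if (prune && m < keep_prob) continue;
    if (feature[nd] == NA_INTEGER) {
      arr[nd] += m;
    } else {
      const int f = feature[nd] - 1;
      const double pR = right_prob(x[f], dx[f], thr[nd]);
      stack.push_back({right[nd] - 1, m * pR});
      stack.push_back({left[nd] - 1, m * (1.0 - pR)});
    }
  }
  return arr;
}
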