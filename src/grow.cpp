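#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exhaustive reward-maximizing split search for sum-of-squares node costs.
//
// All quadratic node deviances (scalar SSD, region-wise SSD, Mahalanobis
// with a fixed covariance, PCA-score and basis-coefficient deviances)
// reduce to the plain multivariate SSD of a suitably transformed response
// matrix.  For such costs the reward of a threshold split can be scanned in
// O(n * d) per feature via prefix sums, because the squared-observation
// term cancels:
//   C = D(P) - D(L) - D(R)
//     = sum_j S_Lj^2/n_L + sum_j S_Rj^2/n_R - sum_j S_Pj^2/n_P
// where S are per-column member sums.  Ties are broken toward the lowest
// feature index and lowest threshold; zero-reward splits are rejected.
//
// Responses are stored transposed (d x n, one contiguous block per sample)
// so the prefix-sum scan is cache-friendly.

struct SplitResult {
  int feature;      // 0-based column of X, -1 if none
  double threshold;
  double reward;
  std::vector<int> left_rows;   // positions into the node member vector
  std::vector<int> right_rows;
};

// draw `m` of 1..M without replacement with R's RNG (partial Fisher-Yates)
static void draw_subset(int M, int m, std::vector<int>& pool,
                        std::vector<int>& out) {
  for (int i = 0; i < M; ++i) pool[i] = i;
  out.resize(m);
  for (int i = 0; i < m; ++i) {
    int j = i + (int) (unif_rand() * (M - i));
    if (j >= M) j = M - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

// Yt: d x n transposed responses (column-major NumericMatrix => sample
// blocks contiguous). members hold bootstrap positions; boot maps them to
// training rows (0-based).
static SplitResult best_split_scan(const double* Xp, int n_train, int M,
                                   const double* Yt, int d,
                                   const std::vector<int>& boot0,
                                   const std::vector<int>& members,
                                   const std::vector<int>& feats_sorted) {
  SplitResult best;
  best.feature = -1;
  best.threshold = NA_REAL;
  best.reward = 0.0;

  const int n = (int) members.size();
  std::vector<double> Sp(d, 0.0), SL(d);
  double Q = 0.0;
  for (int k = 0; k < n; ++k) {
    const double* y = Yt + (size_t) d * boot0[members[k]];
    for (int j = 0; j < d; ++j) { Sp[j] += y[j]; Q += y[j] * y[j]; }
  }
  double parent_sq = 0.0;
  for (int j = 0; j < d; ++j) parent_sq += Sp[j] * Sp[j] / n;
  const double D_parent = Q - parent_sq;
  if (D_parent <= 0.0) return best;
  const double tol = D_parent * 1e-12;

  std::vector<std::pair<double,int>> xv(n);

  for (size_t fi = 0; fi < feats_sorted.size(); ++fi) {
    const int f = feats_sorted[fi];
    const double* xcol = Xp + (size_t) n_train * f;
    for (int k = 0; k < n; ++k) {
      xv[k] = std::make_pair(xcol[boot0[members[k]]], k);
    }
    std::stable_sort(xv.begin(), xv.end(),
                     [](const std::pair<double,int>& a, const std::pair<double,int>& b) {
                       return a.first < b.first;
                     });
    if (xv[0].first == xv[n - 1].first) continue; // constant feature
    std::fill(SL.begin(), SL.end(), 0.0);
    for (int k = 0; k < n - 1; ++k) {
      const double* y = Yt + (size_t) d * boot0[members[xv[k].second]];
      for (int j = 0; j < d; ++j) SL[j] += y[j];
      if (xv[k + 1].first == xv[k].first) continue; // not a boundary
      const double nL = k + 1.0, nR = n - k - 1.0;
      double term = 0.0;
      for (int j = 0; j < d; ++j) {
        const double sl = SL[j], sr = Sp[j] - sl;
        term += sl * sl / nL + sr * sr / nR;
      }
      const double reward = term - parent_sq;
      if (reward > best.reward + tol) {
        best.feature = f;
        best.threshold = 0.5 * (xv[k].first + xv[k + 1].first);
        best.reward = reward;
      }
    }
  }

  if (best.feature >= 0) {
    const double* xcol = Xp + (size_t) n_train * best.feature;
    for (int k = 0; k < n; ++k) {
      if (xcol[boot0[members[k]]] <= best.threshold)
        best.left_rows.push_back(members[k]);
      else best.right_rows.push_back(members[k]);
    }
  }
  return best;
}

static NumericMatrix transpose_mat(const NumericMatrix& A) {
  NumericMatrix B(A.ncol(), A.nrow());
  for (int i = 0; i < A.nrow(); ++i)
    for (int j = 0; j < A.ncol(); ++j) B(j, i) = A(i, j);
  return B;
}

// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, NumericMatrix Y, IntegerVector boot,
                    IntegerVector members, IntegerVector subset) {
  NumericMatrix Yt = transpose_mat(Y);
  std::vector<int> boot0(boot.begin(), boot.end());
  for (size_t i = 0; i < boot0.size(); ++i) boot0[i] -= 1;
  std::vector<int> mem(members.begin(), members.end());
  for (size_t i = 0; i < mem.size(); ++i) mem[i] -= 1;
  std::vector<int> feats(subset.begin(), subset.end());
  for (size_t i = 0; i < feats.size(); ++i) feats[i] -= 1;
  std::sort(feats.begin(), feats.end());
  SplitResult s = best_split_scan(&X[0], X.nrow(), X.ncol(), &Yt[0],
                                  Yt.nrow(), boot0, mem, feats);
  if (s.feature < 0) return List::create(Named("feature") = R_NilValue);
  return List::create(Named("feature") = s.feature + 1,
                      Named("threshold") = s.threshold,
                      Named("reward") = s.reward);
}

// Grow a forest of regression trees with the SSD-family cost on transformed
// responses Y (n_train x d) and leaf payload means over Ypay (n_train x p).
// boot_mat holds per-tree bootstrap row ids (n x T, 1-based into X rows).
// Feature subsets of size mtry are drawn per node with R's RNG.
// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericMatrix Y, NumericMatrix Ypay,
                     IntegerMatrix boot_mat, int mtry, int n_size,
                     int max_depth) {
  const int M = X.ncol();
  const int n_train = X.nrow();
  const int n = boot_mat.nrow();
  const int T = boot_mat.ncol();
  const int p = Ypay.ncol();
  NumericMatrix Yt = transpose_mat(Y);
  const double* Xp = &X[0];
  const double* Ytp = &Yt[0];
  const int d = Yt.nrow();
  mtry = std::min(mtry, M);

  IntegerVector picked(M), selected(M);
  List trees(T);
  std::vector<int> pool(M), subset;

  for (int t = 0; t < T; ++t) {
    std::vector<int> boot0(n);
    for (int i = 0; i < n; ++i) boot0[i] = boot_mat(i, t) - 1;

    std::vector<int> feature, left, right, nsz, leaf_id;
    std::vector<double> threshold;
    std::vector<std::vector<int>> leaf_members;

    struct Work { int idx; std::vector<int> members; int depth; };
    std::vector<Work> stack;
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) all[i] = i;

    feature.push_back(NA_INTEGER); threshold.push_back(NA_REAL);
    left.push_back(NA_INTEGER); right.push_back(NA_INTEGER);
    nsz.push_back(n); leaf_id.push_back(NA_INTEGER);
    stack.push_back({0, all, 0});

    while (!stack.empty()) {
      Work w = std::move(stack.back());
      stack.pop_back();
      const int nn = (int) w.members.size();
      bool make_leaf = (nn <= n_size) ||
                       (max_depth >= 0 && w.depth >= max_depth) || nn < 2;
      SplitResult s;
      s.feature = -1;
      if (!make_leaf) {
        draw_subset(M, mtry, pool, subset);
        for (int j = 0; j < (int) subset.size(); ++j) picked[subset[j]]++;
        std::sort(subset.begin(), subset.end());
        s = best_split_scan(Xp, n_train, M, Ytp, d, boot0, w.members, subset);
        if (s.feature < 0) make_leaf = true;
      }
      if (make_leaf) {
        leaf_id[w.idx] = (int) leaf_members.size() + 1;
        leaf_members.push_back(std::move(w.members));
        continue;
      }
      selected[s.feature]++;
      feature[w.idx] = s.feature + 1;
      threshold[w.idx] = s.threshold;
      const int li = (int) feature.size();
      feature.push_back(NA_INTEGER); threshold.push_back(NA_REAL);
      left.push_back(NA_INTEGER); right.push_back(NA_INTEGER);
      nsz.push_back((int) s.left_rows.size()); leaf_id.push_back(NA_INTEGER);
      const int ri = (int) feature.size();
      feature.push_back(NA_INTEGER); threshold.push_back(NA_REAL);
      left.push_back(NA_INTEGER); right.push_back(NA_INTEGER);
      nsz.push_back((int) s.right_rows.size()); leaf_id.push_back(NA_INTEGER);
      left[w.idx] = li + 1;
      right[w.idx] = ri + 1;
      // depth-first, right pushed first so the left child is grown first
      stack.push_back({ri, std::move(s.right_rows), w.depth + 1});
      stack.push_back({li, std::move(s.left_rows), w.depth + 1});
    }

    const int L = (int) leaf_members.size();
    NumericMatrix leaf_means(L, p);
    List members_out(L);
    for (int l = 0; l < L; ++l) {
      const std::vector<int>& mem = leaf_members[l];
      IntegerVector ids(mem.size());
      for (size_t k = 0; k < mem.size(); ++k) {
        const int r = boot0[mem[k]];
        ids[k] = r + 1;
        for (int j = 0; j < p; ++j) leaf_means(l, j) += Ypay(r, j);
      }
      for (int j = 0; j < p; ++j) leaf_means(l, j) /= (double) mem.size();
      members_out[l] = ids;
    }

    IntegerVector boot_out(n);
    for (int i = 0; i < n; ++i) boot_out[i] = boot0[i] + 1;
    trees[t] = List::create(
      Named("feature") = wrap(feature),
      Named("threshold") = wrap(threshold),
      Named("left") = wrap(left),
      Named("right") = wrap(right),
      Named("n") = wrap(nsz),
      Named("leaf_id") = wrap(leaf_id),
      Named("leaf_members") = members_out,
      Named("leaf_means") = leaf_means,
      Named("boot") = boot_out);
  }

  return List::create(Named("trees") = trees,
                      Named("picked") = picked,
                      Named("selected") = selected);
}

// Route test rows through one tree; returns the 1-based leaf row (into
// leaf_means) for each test sample.
// [[Rcpp::export]]
IntegerVector cpp_route(List tree, NumericMatrix Xtest) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  IntegerVector leaf_id = tree["leaf_id"];
  const int nt = Xtest.nrow();
  IntegerVector out(nt);
  for (int i = 0; i < nt; ++i) {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      const double x = Xtest(i, feature[node] - 1);
      if (ISNAN(x)) stop("missing feature value needed for routing");
      node = (x <= threshold[node] ? left[node] : right[node]) - 1;
    }
    out[i] = leaf_id[node];
  }
  return out;
}

// Mean prediction: average over trees of the leaf payload mean reached by
// each test row (identical to the normalized-weight form of the forest
// prediction).
// [[Rcpp::export]]
NumericMatrix cpp_predict_mean(List trees, NumericMatrix Xtest) {
  const int T = trees.size();
  const int nt = Xtest.nrow();
  NumericMatrix first_means = as<List>(trees[0])["leaf_means"];
  const int p = first_means.ncol();
  NumericMatrix out(nt, p);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    NumericMatrix lm = tree["leaf_means"];
    IntegerVector leaf = cpp_route(tree, Xtest);
    for (int i = 0; i < nt; ++i) {
      const int l = leaf[i] - 1;
      for (int j = 0; j < p; ++j) out(i, j) += lm(l, j);
    }
  }
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < p; ++j) out(i, j) /= (double) T;
  return out;
}
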