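// Fused per-fold feature pipeline and the permutation-null engine.
// Mirrors the R module surface (compute_prototypes / fit_xdawn /
// augment_and_covary / frechet_mean / tangent_map) in one call so that
// grid search and permutation testing stay fast; an equality test in
// the suite pins the two paths together.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// declared in spd_core.cpp
arma::mat spd_invsqrtm_cpp(const arma::mat& A);
arma::mat spd_logm_cpp(const arma::mat& A);
Rcpp::List frechet_mean_impl(const arma::cube& C, double tol, int max_iter,
                             arma::mat M);
Rcpp::List xdawn_fit_cpp(const arma::mat& Cs, const arma::mat& Cx, int f);
Rcpp::List ridge_logistic_cpp(const arma::mat& X, const arma::vec& y,
                              double C, double tol, int max_iter);

static mat oas_of_local(const mat& X) {
  const uword p = X.n_rows, n = X.n_cols;
  mat Xc = X.each_col() - mean(X, 1);
  mat S = (Xc * Xc.t()) / (double)n;
  double trS = trace(S);
  double trS2 = accu(S % S);
  double mu = trS / (double)p;
  double num = (1.0 - 2.0 / (double)p) * trS2 + trS * trS;
  double den = ((double)n + 1.0 - 2.0 / (double)p) * (trS2 - trS * trS / (double)p);
  double rho = (den <= 0.0) ? 1.0 : std::min(1.0, num / den);
  mat out = (1.0 - rho) * S;
  out.diag() += rho * mu;
  return out;
}

static rowvec upper_vec_local(const mat& S) {
  const uword D = S.n_rows;
  rowvec v(D * (D + 1) / 2);
  const double s2 = std::sqrt(2.0);
  uword k = 0;
  for (uword j = 0; j < D; ++j)
    for (uword i = 0; i <= j; ++i)
      v(k++) = (i == j) ? S(i, j) : s2 * S(i, j);
  return v;
}

// One fold of the decoding pipeline: prototypes, xDAWN filters,
// augmented OAS covariances and the Frechet reference are fitted on the
// training trials only; every trial is then mapped into the tangent
// space at the reference.  `warm`, when non-null, seeds the Frechet
// iteration (used across permutations, where successive references are
// close); the converged reference is written back.
static mat features_core(const cube& X, const uvec& train, const ivec& y01,
                         int f, double tol, int max_iter,
                         mat* warm, mat& ref_out) {
  const uword n_ch = X.n_rows, ns = X.n_cols, ntr = X.n_slices;
  mat PA = zeros<mat>(n_ch, ns), PB = zeros<mat>(n_ch, ns);
  mat Cx = zeros<mat>(n_ch, n_ch);
  uword mA = 0, mB = 0;
  for (uword k = 0; k < train.n_elem; ++k) {
    uword i = train(k) - 1;
    const mat& Xi = X.slice(i);
    Cx += Xi * Xi.t();
    if (y01(i) == 1) { PA += Xi; ++mA; } else { PB += Xi; ++mB; }
  }
  if (mA == 0 || mB == 0)
    Rcpp::stop("a class is absent from the training subset");
  PA /= (double)mA; PB /= (double)mB;
  Cx /= (double)(train.n_elem * ns);
  mat CsA = PA * PA.t() / (double)ns;
  mat CsB = PB * PB.t() / (double)ns;
  Rcpp::List fitA = xdawn_fit_cpp(CsA, Cx, f);
  Rcpp::List fitB = xdawn_fit_cpp(CsB, Cx, f);
  mat WA = fitA["filters"], WB = fitB["filters"];
  mat W = join_cols(WA, WB);
  mat PAf = WA * PA, PBf = WB * PB;
  const uword D = 4 * (uword)f;
  cube covs(D, D, ntr);
  mat Xaug(D, ns);
  Xaug.rows(0, f - 1) = PAf;
  Xaug.rows(f, 2 * f - 1) = PBf;
  for (uword i = 0; i < ntr; ++i) {
    Xaug.rows(2 * f, D - 1) = W * X.slice(i);
    covs.slice(i) = oas_of_local(Xaug);
  }
  cube train_covs(D, D, train.n_elem);
  for (uword k = 0; k < train.n_elem; ++k)
    train_covs.slice(k) = covs.slice(train(k) - 1);
  mat init;
  if (warm != nullptr && warm->n_rows == D) {
    init = *warm;
  } else {
    init = zeros<mat>(D, D);
    for (uword k = 0; k < train.n_elem; ++k) init += train_covs.slice(k);
    init /= (double)train.n_elem;
  }
  Rcpp::List fm = frechet_mean_impl(train_covs, tol, max_iter, init);
  if (!Rcpp::as<bool>(fm["converged"])) {
    // a poor warm start can stall the iteration; retry cold once
    if (warm != nullptr && warm->n_rows == D) {
      init = zeros<mat>(D, D);
      for (uword k = 0; k < train.n_elem; ++k) init += train_covs.slice(k);
      init /= (double)train.n_elem;
      fm = frechet_mean_impl(train_covs, tol, max_iter, init);
    }
    if (!Rcpp::as<bool>(fm["converged"]))
      Rcpp::stop("Frechet mean did not converge (step norm %e)",
                 Rcpp::as<double>(fm["step_norm"]));
  }
  mat ref = fm["mean"];
  ref_out = ref;
  if (warm != nullptr) *warm = ref;
  mat is = spd_invsqrtm_cpp(ref);
  mat feats(ntr, D * (D + 1) / 2);
  for (uword i = 0; i < ntr; ++i)
    feats.row(i) = upper_vec_local(spd_logm_cpp(is * covs.slice(i) * is));
  return feats;
}

// [[Rcpp::export]]
Rcpp::List pipeline_features_cpp(const arma::cube& X,
                                 const arma::uvec& train,
                                 const arma::ivec& y01, int f,
                                 double tol = 1e-8, int max_iter = 50) {
  mat ref;
  mat feats = features_core(X, train, y01, f, tol, max_iter, nullptr, ref);
  return Rcpp::List::create(Rcpp::Named("features") = feats,
                            Rcpp::Named("reference") = ref);
}

// Newton solve of the L2-penalised logistic in a reduced basis Z
// (n x r) with unpenalised intercept; returns linear scores for Zte.
static vec logistic_scores(const mat& Z, const vec& y, const mat& Zte,
                           double C, double tol = 1e-6, int max_iter = 1000) {
  const uword n = Z.n_rows, r = Z.n_cols;
  vec wb = zeros<vec>(r + 1);
  const double lambda = 1.0 / C;
  mat Z1 = join_rows(Z, ones<vec>(n));
  for (int it = 0; it < max_iter; ++it) {
    vec eta = Z1 * wb;
    vec p = 1.0 / (1.0 + exp(-eta));
    vec g = Z1.t() * (p - y);
    g.head(r) += lambda * wb.head(r);
    vec wdiag = p % (1.0 - p);
    wdiag.transform([](double x) { return x < 1e-10 ? 1e-10 : x; });
    mat H = Z1.t() * (Z1.each_col() % wdiag);
    for (uword j = 0; j < r; ++j) H(j, j) += lambda;
    vec step = solve(H, g, solve_opts::likely_sympd);
    wb -= step;
    if (norm(step, 2) < tol) break;
  }
  return Zte * wb.head(r) + wb(r);
}

// Best-of-grid mean CV accuracy for one labelling.  warm: per (f, fold)
// Frechet warm-start cache, reused across calls.  The internal Frechet
// tolerance is 1e-6: tangent features move by less than that, far below
// the 1/12 accuracy granularity of a fold.
static double grid_stat(const cube& X, const ivec& y01, const ivec& folds,
                        int k, const ivec& f_grid, const vec& C_grid,
                        std::vector<std::vector<mat>>& warm) {
  const uword ntr = X.n_slices;
  double best = -1.0;
  for (uword fi = 0; fi < f_grid.n_elem; ++fi) {
    int f = f_grid(fi);
    mat acc(k, C_grid.n_elem);
    for (int fold = 1; fold <= k; ++fold) {
      std::vector<uword> tr, te;
      for (uword i = 0; i < ntr; ++i)
        (folds(i) == fold ? te : tr).push_back(i + 1);
      uvec train(tr);
      mat ref;
      mat feats = features_core(X, train, y01, f, 1e-6, 50,
                                &warm[fi][fold - 1], ref);
      mat Xtr(tr.size(), feats.n_cols), Xte(te.size(), feats.n_cols);
      vec ytr(tr.size());
      for (uword j = 0; j < tr.size(); ++j) {
        Xtr.row(j) = feats.row(tr[j] - 1);
        ytr(j) = y01(tr[j] - 1);
      }
      for (uword j = 0; j < te.size(); ++j) Xte.row(j) = feats.row(te[j] - 1);
      // factor the design once per fold, share across all C values
      mat U, V; vec s;
      if (!svd_econ(U, s, V, Xtr)) Rcpp::stop("SVD failed");
      uvec keep = find(s > s.max() * 1e-12);
      mat Z = U.cols(keep) * diagmat(s(keep));
      mat Zte = Xte * V.cols(keep);
      for (uword ci = 0; ci < C_grid.n_elem; ++ci) {
        vec eta = logistic_scores(Z, ytr, Zte, C_grid(ci));
        int correct = 0;
        for (uword j = 0; j < te.size(); ++j)
          if ((eta(j) > 0) == (y01(te[j] - 1) == 1)) ++correct;
        acc(fold - 1, ci) = (double)correct / (double)te.size();
      }
    }
    for (uword ci = 0; ci < C_grid.n_elem; ++ci)
      best = std::max(best, mean(acc.col(ci)));
  }
  return best;
}

// Permutation null of the selected (best-of-grid) CV accuracy: for each
// column of perm_y01 the full grid search is re-run — with folds
// re-stratified on the shuffled labels (column of perm_folds), exactly
// as the observed analysis stratified on the true labels — and its best
// accuracy recorded.  When stop_exceed > 0 the loop curtails as soon as
// that many null values have reached `observed`: the fixed-N p-value is
// then guaranteed to be non-significant, so the diagnosis cannot
// change.
// [[Rcpp::export]]
Rcpp::List perm_null_grid_cpp(const arma::cube& X,
                              const arma::imat& perm_y01,
                              const arma::imat& perm_folds,
                              const arma::ivec& f_grid,
                              const arma::vec& C_grid,
                              double observed,
                              int stop_exceed = -1) {
  const int k = perm_folds.max();
  const uword n_perm = perm_y01.n_cols;
  std::vector<std::vector<mat>> warm(
      f_grid.n_elem, std::vector<mat>(k));
  vec nulls(n_perm, fill::value(datum::nan));
  int exceed = 0;
  uword done = 0;
  for (uword b = 0; b < n_perm; ++b) {
    Rcpp::checkUserInterrupt();
    ivec y = perm_y01.col(b);
    ivec folds = perm_folds.col(b);
    double stat = grid_stat(X, y, folds, k, f_grid, C_grid, warm);
    nulls(b) = stat;
    ++done;
    if (stat >= observed - 1e-12) ++exceed;
    if (stop_exceed > 0 && exceed >= stop_exceed) break;
  }
  return Rcpp::List::create(
      Rcpp::Named("null") = nulls.head(done),
      Rcpp::Named("n_done") = (int)done,
      Rcpp::Named("n_exceed") = exceed);
}

// Same engine for a single fixed configuration (used when the null is
// built without re-selection, for comparison).
// [[Rcpp::export]]
Rcpp::List perm_null_fixed_cpp(const arma::cube& X,
                               const arma::imat& perm_y01,
                               const arma::imat& perm_folds,
                               int f, double C,
                               double observed,
                               int stop_exceed = -1) {
  ivec f_grid(1); f_grid(0) = f;
  vec C_grid(1); C_grid(0) = C;
  return perm_null_grid_cpp(X, perm_y01, perm_folds, f_grid, C_grid,
                            observed, stop_exceed);
}
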