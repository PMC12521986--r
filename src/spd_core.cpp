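// Numerical core: affine-invariant geometry on SPD matrices, the
// ERP-prototype covariance construction (xDAWN + OAS), and a ridge
// logistic solver.  Everything here is called many thousands of times
// during grid search and permutation testing, hence compiled.
#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EIG_FLOOR = 1e-12;

// Symmetric eigendecomposition via LAPACK dsyevd with a reusable
// workspace; this sits in the innermost loop of the Frechet mean and
// the tangent mapping, where Armadillo's per-call workspace management
// is measurable.  Falls back to Armadillo on failure.
static void sym_eig(const mat& A, vec& d, mat& V) {
  int n = (int)A.n_rows;
  V = 0.5 * (A + A.t());
  d.set_size(n);
  static std::vector<double> work;
  static std::vector<int> iwork;
  int lwork = 1 + 6 * n + 2 * n * n, liwork = 3 + 5 * n;
  if ((int)work.size() < lwork) work.resize(lwork);
  if ((int)iwork.size() < liwork) iwork.resize(liwork);
  int info = 0;
  F77_CALL(dsyevd)("V", "L", &n, V.memptr(), &n, d.memptr(),
                   work.data(), &lwork, iwork.data(), &liwork,
                   &info FCONE FCONE);
  if (info != 0) {
    mat As = 0.5 * (A + A.t());
    if (!eig_sym(d, V, As))
      Rcpp::stop("eigendecomposition failed");
  }
}

// Apply f to the eigenvalues of a symmetric matrix, flooring them first.
static mat sym_eig_fun(const mat& A, double (*f)(double)) {
  vec d; mat V;
  sym_eig(A, d, V);
  d.transform([](double x) { return x < EIG_FLOOR ? EIG_FLOOR : x; });
  vec fd = d;
  fd.transform(f);
  return (V.each_row() % fd.t()) * V.t();
}

static double f_log(double x)  { return std::log(x); }
static double f_sqrt(double x) { return std::sqrt(x); }
static double f_isqrt(double x){ return 1.0 / std::sqrt(x); }

// [[Rcpp::export]]
arma::mat spd_logm_cpp(const arma::mat& A)  { return sym_eig_fun(A, f_log); }

// [[Rcpp::export]]
arma::mat spd_sqrtm_cpp(const arma::mat& A) { return sym_eig_fun(A, f_sqrt); }

// [[Rcpp::export]]
arma::mat spd_invsqrtm_cpp(const arma::mat& A) { return sym_eig_fun(A, f_isqrt); }

// [[Rcpp::export]]
arma::mat sym_expm_cpp(const arma::mat& A) {
  vec d; mat V;
  sym_eig(A, d, V);
  vec ed = exp(d);
  return (V.each_row() % ed.t()) * V.t();
}

// [[Rcpp::export]]
double airm_distance_cpp(const arma::mat& A, const arma::mat& B) {
  mat is = spd_invsqrtm_cpp(A);
  mat M = is * B * is;
  mat L = spd_logm_cpp(M);
  return norm(L, "fro");
}

// Fixed-point iteration for the Frechet (geometric) mean under the
// affine-invariant metric: at the current estimate, average the
// tangent-space logarithms and map back through the exponential, until
// the tangent-step Frobenius norm falls below tol.  Initialised at the
// arithmetic mean.  Convergence of the plain map is linear, so the
// iterate sequence is Anderson-accelerated (depth 3) with a fallback to
// the plain update whenever the extrapolated matrix loses positive
// definiteness; the stopping criterion is the plain map's step norm
// either way.
Rcpp::List frechet_mean_impl(const arma::cube& C, double tol,
                             int max_iter, arma::mat M) {
  const uword n = C.n_slices, D = C.n_rows;
  const uword depth = 3;
  std::vector<vec> xs, fs;   // iterate and residual history (flattened)
  double step = datum::inf;
  int it = 0;
  for (; it < max_iter; ++it) {
    mat Ms  = spd_sqrtm_cpp(M);
    mat Mis = spd_invsqrtm_cpp(M);
    mat T = zeros<mat>(D, D);
    for (uword i = 0; i < n; ++i)
      T += spd_logm_cpp(Mis * C.slice(i) * Mis);
    T /= (double)n;
    step = norm(T, "fro");
    if (step < tol) break;
    mat G = Ms * sym_expm_cpp(T) * Ms;       // plain fixed-point update
    vec x = vectorise(M), f = vectorise(G) - x;
    xs.push_back(x); fs.push_back(f);
    if (xs.size() > depth) { xs.erase(xs.begin()); fs.erase(fs.begin()); }
    mat Mnext = G;
    const uword k = xs.size();
    if (k > 1) {
      mat dF(f.n_elem, k - 1), dX(f.n_elem, k - 1);
      for (uword j = 1; j < k; ++j) {
        dF.col(j - 1) = fs[j] - fs[0];
        dX.col(j - 1) = xs[j] - xs[0];
      }
      vec gamma;
      if (solve(gamma, dF.t() * dF, -(dF.t() * fs[0]))) {
        vec xn = xs[0] + dX * gamma + (fs[0] + dF * gamma);
        mat Macc = reshape(xn, D, D);
        Macc = 0.5 * (Macc + Macc.t());
        mat Lc;
        if (chol(Lc, Macc, "lower")) Mnext = Macc;
      }
    }
    M = Mnext;
  }
  return Rcpp::List::create(Rcpp::Named("mean") = M,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("step_norm") = step,
                            Rcpp::Named("converged") = step < tol);
}

// [[Rcpp::export]]
Rcpp::List frechet_mean_cpp(const arma::cube& C, double tol = 1e-8,
                            int max_iter = 50) {
  const uword n = C.n_slices, D = C.n_rows;
  mat M = zeros<mat>(D, D);
  for (uword i = 0; i < n; ++i) M += C.slice(i);
  M /= (double)n;
  return frechet_mean_impl(C, tol, max_iter, M);
}

// Vectorise the upper triangle of a symmetric matrix with off-diagonal
// entries scaled by sqrt(2), so the Euclidean norm equals the Frobenius
// norm of the matrix.
static rowvec upper_vec(const mat& S) {
  const uword D = S.n_rows;
  rowvec v(D * (D + 1) / 2);
  const double s2 = std::sqrt(2.0);
  uword k = 0;
  for (uword j = 0; j < D; ++j)
    for (uword i = 0; i <= j; ++i)
      v(k++) = (i == j) ? S(i, j) : s2 * S(i, j);
  return v;
}

// Tangent-space coordinates of each slice of C at reference ref.
// [[Rcpp::export]]
arma::mat tangent_map_cpp(const arma::cube& C, const arma::mat& ref) {
  const uword n = C.n_slices, D = C.n_rows;
  mat is = spd_invsqrtm_cpp(ref);
  mat out(n, D * (D + 1) / 2);
  for (uword i = 0; i < n; ++i) {
    mat S = spd_logm_cpp(is * C.slice(i) * is);
    out.row(i) = upper_vec(S);
  }
  return out;
}

// Inverse of tangent_map_cpp for a single vector (exponential map at ref).
// [[Rcpp::export]]
arma::mat tangent_unmap_cpp(const arma::rowvec& v, const arma::mat& ref) {
  const uword D = ref.n_rows;
  mat S(D, D);
  const double s2 = std::sqrt(2.0);
  uword k = 0;
  for (uword j = 0; j < D; ++j)
    for (uword i = 0; i <= j; ++i) {
      double x = v(k++);
      if (i == j) S(i, j) = x;
      else { S(i, j) = x / s2; S(j, i) = x / s2; }
    }
  mat rs = spd_sqrtm_cpp(ref);
  return rs * sym_expm_cpp(S) * rs;
}

// OAS shrinkage of the biased sample covariance of X (rows = variables,
// columns = observations); shrinks towards mu * I with mu = tr(S)/p.
static mat oas_of(const mat& X, double& rho_out) {
  const uword p = X.n_rows, n = X.n_cols;
  mat Xc = X.each_col() - mean(X, 1);
  mat S = (Xc * Xc.t()) / (double)n;
  double trS  = trace(S);
  double trS2 = accu(S % S);
  double mu = trS / (double)p;
  double num = (1.0 - 2.0 / (double)p) * trS2 + trS * trS;
  double den = ((double)n + 1.0 - 2.0 / (double)p) * (trS2 - trS * trS / (double)p);
  double rho = (den <= 0.0) ? 1.0 : std::min(1.0, num / den);
  rho_out = rho;
  mat out = (1.0 - rho) * S;
  out.diag() += rho * mu;
  return out;
}

// [[Rcpp::export]]
Rcpp::List oas_cov_cpp(const arma::mat& X) {
  double rho;
  mat S = oas_of(X, rho);
  return Rcpp::List::create(Rcpp::Named("sigma") = S,
                            Rcpp::Named("rho") = rho);
}

// Build the prototype-augmented trial matrices and their OAS covariances.
// X: channels x samples x trials; PA_f, PB_f: class prototypes already
// reduced by their own class's filters (f x samples each); W: all 2f
// filters stacked (2f x channels).  Each augmented trial has 4f rows.
// [[Rcpp::export]]
Rcpp::List augment_cov_cpp(const arma::cube& X, const arma::mat& PA_f,
                           const arma::mat& PB_f, const arma::mat& W) {
  const uword ntr = X.n_slices, ns = X.n_cols;
  const uword fa = PA_f.n_rows, fb = PB_f.n_rows, ftr = W.n_rows;
  const uword D = fa + fb + ftr;
  cube covs(D, D, ntr);
  vec rho(ntr);
  mat Xaug(D, ns);
  Xaug.rows(0, fa - 1) = PA_f;
  Xaug.rows(fa, fa + fb - 1) = PB_f;
  for (uword i = 0; i < ntr; ++i) {
    Xaug.rows(fa + fb, D - 1) = W * X.slice(i);
    double r;
    covs.slice(i) = oas_of(Xaug, r);
    rho(i) = r;
  }
  return Rcpp::List::create(Rcpp::Named("covs") = covs,
                            Rcpp::Named("rho") = rho);
}

// xDAWN-style spatial filters: the f leading generalized eigenvectors of
// the evoked covariance Cs against the total covariance Cx, solved by
// Cholesky whitening.  Filters are returned as rows, normalised so that
// w' Cx w = 1.
// [[Rcpp::export]]
Rcpp::List xdawn_fit_cpp(const arma::mat& Cs, const arma::mat& Cx, int f) {
  const uword p = Cs.n_rows;
  mat Cxr = 0.5 * (Cx + Cx.t());
  double jitter = 1e-10 * trace(Cxr) / (double)p;
  bool regularized = false;
  mat L;
  for (int k = 0; k < 12; ++k) {
    if (chol(L, Cxr + jitter * eye<mat>(p, p), "lower")) break;
    jitter *= 100.0; regularized = true;
    if (k == 11) Rcpp::stop("total covariance not positive definite");
  }
  // whiten: M = L^-1 Cs L^-T, symmetric
  mat Li = solve(trimatl(L), eye<mat>(p, p));
  mat M = Li * (0.5 * (Cs + Cs.t())) * Li.t();
  vec d; mat V;
  if (!eig_sym(d, V, 0.5 * (M + M.t())))
    Rcpp::stop("xDAWN eigendecomposition failed");
  // descending order, take top f; back-transform: w = L^-T v
  mat Wt = Li.t() * V;     // columns are filters
  mat filters(f, p);
  vec vals(f);
  for (int j = 0; j < f; ++j) {
    filters.row(j) = Wt.col(p - 1 - j).t();
    vals(j) = d(p - 1 - j);
  }
  return Rcpp::List::create(Rcpp::Named("filters") = filters,
                            Rcpp::Named("values") = vals,
                            Rcpp::Named("regularized") = regularized);
}

// IIR filter (direct form II transposed) with explicit initial state;
// building block for zero-phase filtering with steady-state
// initialisation, which avoids the long edge transients a narrow-band
// filter would otherwise leak into the data.
// [[Rcpp::export]]
arma::vec iir_filter_cpp(const arma::vec& b, const arma::vec& a,
                         const arma::vec& x, const arma::vec& zi) {
  const uword n = b.n_elem;
  vec z = zi;                    // length n - 1
  vec y(x.n_elem);
  for (uword i = 0; i < x.n_elem; ++i) {
    double xi = x(i);
    double yi = b(0) * xi + z(0);
    for (uword j = 0; j + 2 < n; ++j)
      z(j) = b(j + 1) * xi + z(j + 1) - a(j + 1) * yi;
    z(n - 2) = b(n - 1) * xi - a(n - 1) * yi;
    y(i) = yi;
  }
  return y;
}

// L2-regularised binary logistic regression (intercept unpenalised),
// Newton iterations; the weight vector is sought in the row space of X
// via thin SVD so high-dimensional tangent vectors stay cheap.
// Objective: sum_i loss_i + (0.5 / C) * ||w||^2  (C = inverse regularisation).
// [[Rcpp::export]]
Rcpp::List ridge_logistic_cpp(const arma::mat& X, const arma::vec& y,
                              double C, double tol = 1e-6,
                              int max_iter = 1000) {
  const uword n = X.n_rows;
  mat U; vec s; mat V;
  if (!svd_econ(U, s, V, X)) Rcpp::stop("SVD failed in logistic solver");
  uvec keep = find(s > s.max() * 1e-12);
  U = U.cols(keep); s = s(keep); V = V.cols(keep);
  mat Z = U * diagmat(s);          // n x r reduced design
  const uword r = Z.n_cols;
  vec wb = zeros<vec>(r + 1);      // [w_reduced; intercept]
  double lambda = 1.0 / C;
  mat Z1 = join_rows(Z, ones<vec>(n));
  int it = 0;
  for (; it < max_iter; ++it) {
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
    if (norm(step, 2) < tol) { ++it; break; }
  }
  vec w = V * wb.head(r);
  return Rcpp::List::create(Rcpp::Named("coef") = w,
                            Rcpp::Named("intercept") = wb(r),
                            Rcpp::Named("iterations") = it);
}
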