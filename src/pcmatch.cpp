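// Compiled kernels: genotype sampling under an admixture model and the
// per-variant IRLS logistic scan. Single-threaded; all randomness goes
// through R's RNG so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Binomial(2, p) by cdf inversion of a single uniform: u < (1-p)^2 -> 0,
// u < (1-p)^2 + 2p(1-p) -> 1, else 2 (plus one uniform for the missingness
// mask when enabled).
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_genotypes(const arma::mat& pop_freqs,  // K x M
                                     const arma::mat& Q,          // N x K
                                     double missing_rate) {
  const int K = pop_freqs.n_rows, M = pop_freqs.n_cols, N = Q.n_rows;
  if ((int)Q.n_cols != K)
    stop("admixture matrix has %d components but the panel has %d populations",
         (int)Q.n_cols, K);
  IntegerMatrix G(M, N);  // variants x samples
  for (int i = 0; i < N; ++i) {
    int* col = &G(0, i);
    for (int j = 0; j < M; ++j) {
      double p = 0.0;
      for (int k = 0; k < K; ++k) p += Q(i, k) * pop_freqs(k, j);
      if (p < 0.0) p = 0.0; else if (p > 1.0) p = 1.0;
      const double q = 1.0 - p;
      const double c0 = q * q, c1 = q * q + 2.0 * p * q;
      const double u = unif_rand();
      int g = (u >= c0) + (u >= c1);
      if (missing_rate > 0.0 && unif_rand() < missing_rate)
        col[j] = NA_INTEGER;
      else
        col[j] = g;
    }
  }
  return G;
}

struct IrlsFit {
  arma::vec beta;
  arma::vec se;
  bool converged;
  bool singular;
  int niter;
};

// Maximum-likelihood logistic regression by iteratively reweighted least
// squares (Newton-Raphson on the observed information).
static IrlsFit irls_logistic(const arma::mat& X, const arma::vec& y,
                             const arma::vec& init, int maxit, double tol) {
  const arma::uword p = X.n_cols;
  IrlsFit fit;
  fit.beta = init;
  fit.converged = false;
  fit.singular = false;
  fit.niter = 0;
  arma::vec eta, mu, w;
  arma::mat XtWX(p, p);
  bool have_info = false;
  for (int it = 0; it < maxit; ++it) {
    fit.niter = it + 1;
    eta = X * fit.beta;
    mu = 1.0 / (1.0 + arma::exp(-eta));
    w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    arma::mat Xw = X.each_col() % arma::sqrt(w);
    XtWX = Xw.t() * Xw;
    have_info = true;
    arma::vec score = X.t() * (y - mu);
    arma::vec step;
    if (!arma::solve(step, XtWX, score, arma::solve_opts::no_approx)) {
      fit.singular = true;
      break;
    }
    fit.beta += step;
    if (arma::abs(step).max() < tol) {
      fit.converged = true;
      break;
    }
    if (arma::abs(fit.beta).max() > 1e3) break;  // hopeless divergence
  }
  fit.se.set_size(p);
  fit.se.fill(NA_REAL);
  if (!fit.singular && have_info) {
    // XtWX from the final Newton step (coefficients have moved < tol since)
    arma::mat cov;
    if (arma::inv_sympd(cov, XtWX))
      fit.se = arma::sqrt(cov.diag());
    else
      fit.singular = true;
  }
  return fit;
}

// [[Rcpp::export]]
List cpp_fit_logistic(const arma::mat& X, const arma::vec& y,
                      int maxit = 50, double tol = 1e-8) {
  arma::vec init(X.n_cols, arma::fill::zeros);
  IrlsFit fit = irls_logistic(X, y, init, maxit, tol);
  return List::create(_["beta"] = fit.beta, _["se"] = fit.se,
                      _["converged"] = fit.converged,
                      _["singular"] = fit.singular, _["niter"] = fit.niter);
}

// Per-variant additive-dosage logistic scan with covariates. G is
// variants x samples with NA for missing calls; missing dosages are
// mean-imputed per variant. Returns Wald statistics plus flags marking
// records that a Firth-fallback policy should refit.
// [[Rcpp::export]]
List cpp_logistic_scan(const IntegerMatrix& G, const arma::mat& X,
                       const arma::vec& y, int maxit, double tol,
                       double beta_max) {
  const int M = G.nrow(), n = G.ncol();
  const arma::uword p = X.n_cols;
  if ((int)X.n_rows != n || (int)y.n_elem != n)
    stop("covariate/phenotype dimensions do not match the genotype matrix");

  // Null (covariate-only) fit used to warm-start every variant.
  arma::vec init0(p, arma::fill::zeros);
  init0[0] = std::log((arma::mean(y) + 1e-6) / (1.0 - arma::mean(y) + 1e-6));
  IrlsFit null_fit = irls_logistic(X, y, init0, maxit, tol);

  // transpose once (cache-blocked) so each variant's dosages are contiguous
  arma::Mat<int> Gt(n, M);
  const int B = 64;
  for (int jb = 0; jb < M; jb += B)
    for (int ib = 0; ib < n; ib += B) {
      const int je = std::min(jb + B, M), ie = std::min(ib + B, n);
      for (int j = jb; j < je; ++j)
        for (int i = ib; i < ie; ++i) Gt(i, j) = G(j, i);
    }

  arma::mat Xg(n, p + 1);
  Xg.cols(0, p - 1) = X;
  arma::vec start(p + 1);

  NumericVector beta(M, NA_REAL), se(M, NA_REAL), pval(M, NA_REAL),
      maf(M, NA_REAL), eaf(M, NA_REAL);
  IntegerVector mac(M, NA_INTEGER), nobs(M, NA_INTEGER),
      status(M);  // 0 ok, 1 flagged (refit with Firth), 2 monomorphic,
                  // 3 singular
  LogicalVector conv(M);

  for (int j = 0; j < M; ++j) {
    const int* gj = Gt.colptr(j);
    double sum = 0.0;
    int nmiss = 0;
    for (int i = 0; i < n; ++i) {
      if (gj[i] == NA_INTEGER) ++nmiss; else sum += gj[i];
    }
    const int nonmiss = n - nmiss;
    if (nonmiss == 0) { status[j] = 2; conv[j] = false; continue; }
    const double mean_dos = sum / nonmiss;
    const double af = mean_dos / 2.0;
    eaf[j] = af;
    maf[j] = af <= 0.5 ? af : 1.0 - af;
    int ac = (int)std::lround(af <= 0.5 ? sum : 2.0 * nonmiss - sum);
    mac[j] = ac;
    nobs[j] = nonmiss;
    if (ac == 0) { status[j] = 2; conv[j] = false; continue; }

    for (int i = 0; i < n; ++i)
      Xg(i, p) = (gj[i] == NA_INTEGER) ? mean_dos : (double)gj[i];
    start.head(p) = null_fit.beta;
    start[p] = 0.0;
    IrlsFit fit = irls_logistic(Xg, y, start, maxit, tol);
    if (fit.singular) { status[j] = 3; conv[j] = false; continue; }
    conv[j] = fit.converged;
    beta[j] = fit.beta[p];
    se[j] = fit.se[p];
    if (fit.converged && std::abs(fit.beta[p]) <= beta_max &&
        arma::is_finite(fit.se[p])) {
      double z = fit.beta[p] / fit.se[p];
      pval[j] = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
      status[j] = 0;
    } else {
      status[j] = 1;  // non-convergence or runaway effect: Firth candidate
    }
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["p"] = pval,
                      _["eaf"] = eaf, _["maf"] = maf, _["mac"] = mac,
                      _["n_obs"] = nobs, _["converged"] = conv,
                      _["status"] = status);
}

// ML log-odds-ratio for a batch of 2x2 tables (rows: n11 exposed cases,
// n10 unexposed cases, n01 exposed controls, n00 unexposed controls),
// fit through the same IRLS routine as the genome scan.
// [[Rcpp::export]]
NumericVector cpp_logor_2x2(const IntegerMatrix& tables, int maxit = 50,
                            double tol = 1e-8) {
  const int m = tables.nrow();
  NumericVector out(m, NA_REAL);
  for (int t = 0; t < m; ++t) {
    int n11 = tables(t, 0), n10 = tables(t, 1), n01 = tables(t, 2),
        n00 = tables(t, 3);
    int n = n11 + n10 + n01 + n00;
    arma::mat X(n, 2, arma::fill::ones);
    arma::vec y(n);
    int r = 0;
    for (int i = 0; i < n11; ++i, ++r) { X(r, 1) = 1; y[r] = 1; }
    for (int i = 0; i < n10; ++i, ++r) { X(r, 1) = 0; y[r] = 1; }
    for (int i = 0; i < n01; ++i, ++r) { X(r, 1) = 1; y[r] = 0; }
    for (int i = 0; i < n00; ++i, ++r) { X(r, 1) = 0; y[r] = 0; }
    arma::vec init(2, arma::fill::zeros);
    IrlsFit fit = irls_logistic(X, y, init, maxit, tol);
    if (fit.converged && !fit.singular) out[t] = fit.beta[1];
  }
  return out;
}
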