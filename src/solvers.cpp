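// Core numerical routines: IRLS logistic regression with an optional ridge
// stabilizer, and a cyclic coordinate-descent solver for the elastic-net
// penalized logistic path (proximal Newton with warm starts and active sets).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double clip(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static double binom_loglik(const arma::vec& y, const arma::vec& eta) {
  // sum y*eta - log(1 + exp(eta)), numerically stable
  double ll = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double e = eta[i];
    double lse = e > 0 ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    ll += y[i] * e - lse;
  }
  return ll;
}

// Iteratively reweighted least squares for binomial logistic regression.
// X has no intercept column; the intercept is fitted unpenalized and the
// ridge stabilizer applies to the slope coefficients only.
// [[Rcpp::export]]
List cpp_logistic_irls(const arma::mat& X, const arma::vec& y,
                       double ridge, int maxit, double tol) {
  const arma::uword n = y.n_elem, p = X.n_cols;
  arma::vec theta(p + 1, arma::fill::zeros);   // [intercept, beta]
  double ybar = arma::mean(y);
  ybar = clip(ybar, 1e-12, 1.0 - 1e-12);
  theta[0] = std::log(ybar / (1.0 - ybar));

  arma::mat Z(n, p + 1);
  Z.col(0).ones();
  if (p > 0) Z.cols(1, p) = X;

  arma::vec rvec(p + 1, arma::fill::value(ridge));
  rvec[0] = 0.0;                                // intercept unpenalized

  arma::vec eta = Z * theta;
  double pll = binom_loglik(y, eta) - 0.5 * ridge * arma::dot(theta.tail(p), theta.tail(p));
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= maxit; ++iter) {
    arma::vec mu(n), w(n);
    for (arma::uword i = 0; i < n; ++i) {
      double m = 1.0 / (1.0 + std::exp(-eta[i]));
      m = clip(m, 1e-10, 1.0 - 1e-10);
      mu[i] = m;
      w[i] = std::max(m * (1.0 - m), 1e-10);
    }
    arma::vec grad = Z.t() * (y - mu) - rvec % theta;
    arma::mat H = Z.t() * (Z.each_col() % w);
    H.diag() += rvec;
    arma::vec step;
    bool ok = arma::solve(step, H, grad, arma::solve_opts::likely_sympd);
    if (!ok) { converged = false; break; }

    // step halving on the (stabilized) objective
    double fac = 1.0;
    arma::vec theta_new;
    double pll_new = -arma::datum::inf;
    for (int h = 0; h < 30; ++h) {
      theta_new = theta + fac * step;
      arma::vec eta_new = Z * theta_new;
      pll_new = binom_loglik(y, eta_new) -
        0.5 * ridge * arma::dot(theta_new.tail(p), theta_new.tail(p));
      if (pll_new >= pll - 1e-12) { eta = eta_new; break; }
      fac *= 0.5;
    }
    double delta = arma::abs(fac * step).max();
    theta = theta_new;
    if (std::abs(pll_new - pll) < tol && delta < std::sqrt(tol)) {
      pll = pll_new; converged = true; break;
    }
    pll = pll_new;
  }

  return List::create(
    _["intercept"] = theta[0],
    _["coefficients"] = (p > 0) ? arma::vec(theta.tail(p)) : arma::vec(),
    _["loglik"] = binom_loglik(y, eta),
    _["converged"] = converged,
    _["iterations"] = iter);
}

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One pass of cyclic coordinate descent over the given index set on the
// penalized weighted least-squares subproblem; returns max |change| scaled
// by sqrt(weighted second moment). Allocation-free inner loops.
static double cd_pass(const arma::mat& Xs, const arma::vec& w,
                      const arma::vec& wx2, arma::vec& r, arma::vec& beta,
                      const std::vector<arma::uword>& idx, double lam_l1,
                      double lam_l2, const arma::vec& pf, double n) {
  const arma::uword nr = r.n_elem;
  double maxdel = 0.0;
  double* rp = r.memptr();
  const double* wp = w.memptr();
  for (size_t k = 0; k < idx.size(); ++k) {
    const arma::uword j = idx[k];
    const double* xj = Xs.colptr(j);
    double bj = beta[j];
    double acc = 0.0;
    for (arma::uword i = 0; i < nr; ++i) acc += wp[i] * xj[i] * rp[i];
    double num = acc / n + wx2[j] * bj;
    // small absolute guard so boundary cases (lambda == lambda_max) are
    // not tipped over by accumulation rounding
    double thr = lam_l1 * pf[j];
    if (thr > 0.0) thr += 1e-12 * (1.0 + std::abs(num));
    double bnew = soft(num, thr) / (wx2[j] + lam_l2 * pf[j]);
    if (bnew != bj) {
      double d = bj - bnew;
      for (arma::uword i = 0; i < nr; ++i) rp[i] += xj[i] * d;
      beta[j] = bnew;
      double dd = d * d * std::max(wx2[j], 1e-12);
      if (dd > maxdel) maxdel = dd;
    }
  }
  return maxdel;
}

// Elastic-net penalized logistic regression along a lambda path.
// Objective: -(1/N) sum[y*eta - log(1+e^eta)]
//            + lambda * sum_j pf_j [ (1-alpha)/2 beta_j^2 + alpha |beta_j| ]
// on internally standardized predictors (mean 0, 1/N-variance 1);
// the intercept is unpenalized. Warm starts along the descending path.
// [[Rcpp::export]]
List cpp_enet_path(const arma::mat& X, const arma::vec& y, double alpha,
                   const arma::vec& lambdas, const arma::vec& pf,
                   double tol, int maxit_outer, int maxit_inner,
                   double dev_stop = 0.0) {
  const arma::uword n = X.n_rows, p = X.n_cols, L = lambdas.n_elem;
  const double N = static_cast<double>(n);

  arma::rowvec ctr = arma::mean(X, 0);
  arma::rowvec scl(p);
  arma::mat Xs(n, p);
  arma::uvec usable(p);
  for (arma::uword j = 0; j < p; ++j) {
    arma::vec xc = X.col(j) - ctr[j];
    double s = std::sqrt(arma::dot(xc, xc) / N);
    usable[j] = s > 1e-12 ? 1 : 0;
    scl[j] = usable[j] ? s : 1.0;
    Xs.col(j) = xc / scl[j];
  }

  arma::vec beta(p, arma::fill::zeros);
  double ybar = clip(arma::mean(y), 1e-12, 1.0 - 1e-12);
  double b0 = std::log(ybar / (1.0 - ybar));

  arma::mat beta_path(p, L, arma::fill::zeros);
  arma::vec b0_path(L, arma::fill::zeros);
  IntegerVector conv(L);

  std::vector<arma::uword> all_idx;
  for (arma::uword j = 0; j < p; ++j) if (usable[j]) all_idx.push_back(j);

  for (arma::uword l = 0; l < L; ++l) {
    double lam = lambdas[l];
    double lam_l1 = lam * alpha, lam_l2 = lam * (1.0 - alpha);
    bool outer_ok = false;

    for (int it = 0; it < maxit_outer; ++it) {
      arma::vec eta = b0 + Xs * beta;
      arma::vec mu(n), w(n), z(n);
      for (arma::uword i = 0; i < n; ++i) {
        double m = 1.0 / (1.0 + std::exp(-eta[i]));
        m = clip(m, 1e-8, 1.0 - 1e-8);
        mu[i] = m;
        w[i] = std::max(m * (1.0 - m), 1e-8);
        z[i] = eta[i] + (y[i] - m) / w[i];
      }
      arma::vec wx2(p, arma::fill::zeros);
      for (arma::uword j = 0; j < p; ++j)
        if (usable[j]) wx2[j] = arma::dot(w, arma::square(Xs.col(j))) / N;
      double wsum = arma::accu(w);

      arma::vec beta_old = beta;
      double b0_old = b0;
      arma::vec r = z - b0 - Xs * beta;

      // solve the penalized WLS subproblem: converge on the active set,
      // then verify with a full pass; repeat until the full pass is quiet
      int budget = maxit_inner;
      while (budget > 0) {
        for (; budget > 0; --budget) {
          std::vector<arma::uword> act;
          for (arma::uword j = 0; j < p; ++j)
            if (beta[j] != 0.0) act.push_back(j);
          double d2 = act.empty() ? 0.0 :
            cd_pass(Xs, w, wx2, r, beta, act, lam_l1, lam_l2, pf, N);
          double db = arma::dot(w, r) / wsum;
          b0 += db; r -= db;
          if (std::max(d2, db * db * wsum / N) < tol) break;
        }
        double del = cd_pass(Xs, w, wx2, r, beta, all_idx, lam_l1, lam_l2,
                             pf, N);
        double db0 = arma::dot(w, r) / wsum;
        b0 += db0; r -= db0;
        --budget;
        if (std::max(del, db0 * db0 * wsum / N) < tol) break;
      }

      double dmax = (b0 - b0_old) * (b0 - b0_old) * wsum / N;
      for (arma::uword j = 0; j < p; ++j) {
        double d = beta[j] - beta_old[j];
        d = d * d * std::max(wx2[j], 1e-12);
        if (d > dmax) dmax = d;
      }
      if (dmax < tol) { outer_ok = true; break; }
    }
    conv[l] = outer_ok ? 1 : 0;
    beta_path.col(l) = beta;
    b0_path[l] = b0;

    // optional early exit once the training deviance is saturated: the
    // remaining (smaller) lambdas inherit the current solution
    if (dev_stop > 0.0 && l + 1 < L) {
      double ll = binom_loglik(y, b0 + Xs * beta);
      double ll0 = N * (ybar * std::log(ybar) +
                        (1.0 - ybar) * std::log(1.0 - ybar));
      double ratio = (ll0 - ll) / ll0;   // fraction of null deviance explained
      if (ratio > dev_stop) {
        for (arma::uword l2 = l + 1; l2 < L; ++l2) {
          beta_path.col(l2) = beta;
          b0_path[l2] = b0;
          conv[l2] = conv[l];
        }
        break;
      }
    }
  }

  // back-transform to the original predictor scale
  arma::mat beta_orig = beta_path;
  arma::vec b0_orig = b0_path;
  for (arma::uword j = 0; j < p; ++j) {
    beta_orig.row(j) /= scl[j];
    b0_orig -= beta_orig.row(j).t() * ctr[j];
  }

  return List::create(
    _["beta"] = beta_orig,
    _["intercept"] = b0_orig,
    _["beta_std"] = beta_path,
    _["intercept_std"] = b0_path,
    _["center"] = ctr,
    _["scale"] = scl,
    _["converged"] = conv);
}
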