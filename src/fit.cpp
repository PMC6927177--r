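// Per-bin Poisson-log-gamma (marginal negative binomial) regression fitted by
// gradient ascent with backtracking line search; Wald se from observed Fisher
// information (central finite differences of the analytic gradient).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// log(exp(eta) + psi), overflow-safe
static inline double log_exp_plus(double eta, double log_psi) {
  double a = std::max(eta, log_psi);
  return a + std::log(std::exp(eta - a) + std::exp(log_psi - a));
}

// marginal log-likelihood: sum_i Y_i*eta_i + psi*log(psi) + lgamma(Y_i+psi)
//   - lgamma(Y_i+1) - lgamma(psi) - (Y_i+psi)*log(exp(eta_i)+psi)
static double loglik(const arma::vec& y, const arma::vec& eta, double psi) {
  double lp = std::log(psi);
  double ll = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    ll += y[i] * eta[i] + psi * lp + std::lgamma(y[i] + psi)
        - std::lgamma(y[i] + 1.0) - std::lgamma(psi)
        - (y[i] + psi) * log_exp_plus(eta[i], lp);
  }
  return ll;
}

// gradient over (coefficients b, psi); returns length p+1 vector
static arma::vec gradient(const arma::vec& y, const arma::mat& M,
                          const arma::vec& b, double psi) {
  arma::uword n = y.n_elem, p = M.n_cols;
  arma::vec eta = M * b;
  double lp = std::log(psi);
  arma::vec g(p + 1, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    double lsum = log_exp_plus(eta[i], lp);
    double frac = std::exp(eta[i] - lsum);            // e^eta/(e^eta+psi)
    double resid = y[i] - (y[i] + psi) * frac;
    for (arma::uword k = 0; k < p; ++k) g[k] += resid * M(i, k);
    g[p] += lp + 1.0 - (y[i] + psi) * std::exp(-lsum) - lsum
          + R::digamma(y[i] + psi) - R::digamma(psi);
  }
  return g;
}

struct FitResult {
  arma::vec b;
  double psi, loglik, se_beta0;
  int niter, converged, info_code; // info_code 0=full inverse,1=block,2=singular
};

static const double LOG_PSI_MIN = std::log(1e-4);
static const double LOG_PSI_MAX = std::log(1e8);

// gradient ascent over (b, log psi) with Armijo backtracking
static FitResult fit_one(const arma::vec& y, const arma::mat& M,
                         double tol, int max_iter) {
  arma::uword p = M.n_cols;
  FitResult res;
  arma::vec b(p, arma::fill::zeros);
  double ybar = arma::mean(y);
  b[0] = std::log(ybar + 0.5);
  double yvar = arma::var(y); // sample variance (n-1)
  double psi0 = ybar * ybar / std::max(yvar - ybar, 1e-8);
  psi0 = std::min(std::max(psi0, 0.1), 1e4);
  double lpsi = std::log(psi0);

  double ll = loglik(y, M * b, std::exp(lpsi));
  int it = 0;
  bool converged = false;
  const double c_armijo = 1e-4;
  arma::vec theta(p + 1), theta_prev(p + 1), g_prev(p + 1);
  theta.head(p) = b; theta[p] = lpsi;
  bool have_prev = false;
  for (it = 1; it <= max_iter; ++it) {
    arma::vec g = gradient(y, M, b, std::exp(lpsi));
    g[p] *= std::exp(lpsi);                 // chain rule d/d(log psi)
    double gnorm2 = arma::dot(g, g);
    if (std::sqrt(gnorm2) < 1e-8) { converged = true; break; }
    // Barzilai-Borwein spectral step as the line-search starting point;
    // badly conditioned surfaces (mu vs log psi scales) crawl otherwise
    double step = 1.0;
    if (have_prev) {
      arma::vec dt = theta - theta_prev, dg = g - g_prev;
      double denom = -arma::dot(dt, dg);    // positive near a maximum
      if (denom > 0) step = arma::dot(dt, dt) / denom;
      if (!std::isfinite(step) || step <= 0) step = 1.0;
      step = std::min(std::max(step, 1e-10), 1e6);
    }
    arma::vec b_new = b;
    double lpsi_new = lpsi, ll_new = ll;
    bool accepted = false;
    for (int ls = 0; ls < 80; ++ls) {
      b_new = b + step * g.head(p);
      lpsi_new = std::min(std::max(lpsi + step * g[p], LOG_PSI_MIN), LOG_PSI_MAX);
      ll_new = loglik(y, M * b_new, std::exp(lpsi_new));
      if (std::isfinite(ll_new) && ll_new >= ll + c_armijo * step * gnorm2) {
        accepted = true; break;
      }
      step *= 0.5;
    }
    if (!accepted) { converged = true; break; } // flat to machine precision
    double delta = ll_new - ll;
    theta_prev = theta; g_prev = g; have_prev = true;
    b = b_new; lpsi = lpsi_new; ll = ll_new;
    theta.head(p) = b; theta[p] = lpsi;
    if (delta < tol && std::sqrt(arma::dot(g, g)) < 1e-5 * (1.0 + std::fabs(ll))) {
      converged = true; break;
    }
  }

  double psi = std::exp(lpsi);
  res.b = b; res.psi = psi; res.loglik = ll;
  res.niter = std::min(it, max_iter);
  res.converged = converged ? 1 : 0;

  // observed information: -Hessian by central FD of analytic gradient in
  // (b, psi) parameterization, step 1e-5*(1+|theta|)
  arma::uword q = p + 1;
  arma::mat H(q, q, arma::fill::zeros);
  theta.head(p) = b; theta[q - 1] = psi;
  for (arma::uword j = 0; j < q; ++j) {
    double h = 1e-5 * (1.0 + std::fabs(theta[j]));
    arma::vec tp = theta, tm = theta;
    tp[j] += h; tm[j] -= h;
    if (j == q - 1 && tm[j] <= 0) tm[j] = theta[j] * 0.5;
    arma::vec gp = gradient(y, M, tp.head(p), tp[q - 1]);
    arma::vec gm = gradient(y, M, tm.head(p), tm[q - 1]);
    H.col(j) = (gp - gm) / (tp[j] - tm[j]);
  }
  H = 0.5 * (H + H.t());
  arma::mat info = -H;
  arma::mat cov;
  bool ok = arma::inv_sympd(cov, info);
  if (ok && cov(1, 1) > 0) {
    res.se_beta0 = std::sqrt(cov(1, 1));
    res.info_code = 0;
  } else {
    // psi direction can be flat (psi at bound); fall back to regression block
    arma::mat cov2;
    bool ok2 = arma::inv_sympd(cov2, info.submat(0, 0, p - 1, p - 1));
    if (!ok2) ok2 = arma::pinv(cov2, info.submat(0, 0, p - 1, p - 1));
    if (ok2 && cov2(1, 1) > 0) {
      res.se_beta0 = std::sqrt(cov2(1, 1));
      res.info_code = 1;
    } else {
      res.se_beta0 = NA_REAL;
      res.info_code = 2;
    }
  }
  return res;
}

// [[Rcpp::export(name = ".pg_loglik_cpp")]]
double pg_loglik_cpp(NumericVector y, NumericVector eta, double psi) {
  arma::vec yy(y.begin(), y.size(), false), ee(eta.begin(), eta.size(), false);
  return loglik(yy, ee, psi);
}

// [[Rcpp::export(name = ".pg_grad_cpp")]]
NumericVector pg_grad_cpp(NumericVector y, NumericMatrix M,
                          NumericVector b, double psi) {
  arma::vec yy(y.begin(), y.size(), false), bb(b.begin(), b.size(), false);
  arma::mat MM(M.begin(), M.nrow(), M.ncol(), false);
  arma::vec g = gradient(yy, MM, bb, psi);
  return NumericVector(g.begin(), g.end());
}

// [[Rcpp::export(name = ".fit_bin_cpp")]]
NumericVector fit_bin_cpp(NumericVector y, NumericMatrix M,
                          double tol, int max_iter) {
  arma::vec yy(y.begin(), y.size(), false);
  arma::mat MM(M.begin(), M.nrow(), M.ncol(), false);
  FitResult r = fit_one(yy, MM, tol, max_iter);
  arma::uword p = MM.n_cols;
  NumericVector out(p + 6);
  for (arma::uword k = 0; k < p; ++k) out[k] = r.b[k];
  out[p] = r.psi; out[p + 1] = r.se_beta0; out[p + 2] = r.loglik;
  out[p + 3] = r.niter; out[p + 4] = r.converged; out[p + 5] = r.info_code;
  return out;
}

// [[Rcpp::export(name = ".fit_bins_cpp")]]
NumericMatrix fit_bins_cpp(NumericMatrix Y, NumericMatrix M,
                           double tol, int max_iter) {
  arma::mat YY(Y.begin(), Y.nrow(), Y.ncol(), false);
  arma::mat MM(M.begin(), M.nrow(), M.ncol(), false);
  arma::uword p = MM.n_cols, nb = YY.n_rows;
  NumericMatrix out(nb, p + 6);
  for (arma::uword i = 0; i < nb; ++i) {
    arma::vec y = YY.row(i).t();
    FitResult r = fit_one(y, MM, tol, max_iter);
    for (arma::uword k = 0; k < p; ++k) out(i, k) = r.b[k];
    out(i, p) = r.psi; out(i, p + 1) = r.se_beta0; out(i, p + 2) = r.loglik;
    out(i, p + 3) = r.niter; out(i, p + 4) = r.converged; out(i, p + 5) = r.info_code;
    if (i % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
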