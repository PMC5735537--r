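// Adaptive-ridge fixed-point solver for L0-penalized GLMs.
//
// Each pass is one Newton/ridge step against the working response
// Z = V * theta + (Y - mu), with a per-feature penalty lambda / eta_j^2
// where eta is the previous coefficient estimate.  Features whose
// coefficients fall below the hard threshold are set to exact zero and,
// because the step is premultiplied by diag(eta^2), zeros are absorbing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

const double THETA_CAP = 30.0;  // overflow guard on the linear predictor

// family codes: 0 = linear, 1 = logistic, 2 = poisson
void fam_moments(const arma::vec& theta, int fam, arma::vec& mu, arma::vec& v) {
  switch (fam) {
  case 0:
    mu = theta;
    v.ones(theta.n_elem);
    break;
  case 1: {
    arma::vec tc = arma::clamp(theta, -THETA_CAP, THETA_CAP);
    mu = 1.0 / (1.0 + arma::exp(-tc));
    v = mu % (1.0 - mu);
    break;
  }
  case 2: {
    arma::vec tc = arma::clamp(theta, -std::numeric_limits<double>::max(),
                               THETA_CAP);
    mu = arma::exp(tc);
    v = mu;
    break;
  }
  default:
    stop("unknown family code");
  }
}

// beta = (D X'VX + lambda I)^{-1} D X'Z solved through the symmetric
// substitution beta = W (W X'VX W + lambda I)^{-1} W X'Z with W = diag(eta),
// D = W^2.  Rows with eta_j = 0 decouple and give beta_j = 0 exactly.
arma::vec primal_core(const arma::mat& X, const arma::vec& z,
                      const arma::vec& v, const arma::vec& eta,
                      double lambda) {
  arma::mat Xv = X.each_col() % v;       // V X (rows scaled by v)
  arma::mat A = X.t() * Xv;              // X' V X
  A.each_col() %= eta;                   // W A
  A.each_row() %= eta.t();               // W A W
  double ridge = (lambda == 0.0) ? 1e-12 : lambda;
  A.diag() += ridge;
  arma::vec b = eta % (X.t() * z);
  arma::vec gamma = arma::solve(A, b);
  return eta % gamma;
}

// beta = D X' (V X D X' + lambda I_N)^{-1} Z : the same step through the
// N x N matrix identity, valid for lambda > 0.
arma::vec dual_core(const arma::mat& X, const arma::vec& z,
                    const arma::vec& v, const arma::vec& eta,
                    double lambda) {
  arma::mat Xe = X.each_row() % eta.t();  // X diag(eta)
  arma::mat M = Xe * Xe.t();              // X D X'
  M.each_col() %= v;                      // V X D X'
  M.diag() += lambda;
  arma::vec u = arma::solve(M, z);
  return eta % (Xe.t() * u);              // D X' u
}

}  // namespace

// [[Rcpp::export(name = ".primal_step_cpp")]]
arma::vec primal_step_cpp(const arma::mat& X, const arma::vec& z,
                          const arma::vec& v, const arma::vec& eta,
                          double lambda) {
  return primal_core(X, z, v, eta, lambda);
}

// [[Rcpp::export(name = ".dual_step_cpp")]]
arma::vec dual_step_cpp(const arma::mat& X, const arma::vec& z,
                        const arma::vec& v, const arma::vec& eta,
                        double lambda) {
  if (lambda <= 0.0)
    stop("the dual update requires lambda > 0");
  return dual_core(X, z, v, eta, lambda);
}

// family-standard IRLS starting means (as stats::glm.fit mustart)
void irls_start(const arma::vec& Y, int fam, arma::vec& theta, arma::vec& mu,
                arma::vec& v) {
  switch (fam) {
  case 0:
    mu = Y;
    theta = Y;
    v.ones(Y.n_elem);
    break;
  case 1:
    mu = (Y + 0.5) / 2.0;
    theta = arma::log(mu / (1.0 - mu));
    v = mu % (1.0 - mu);
    break;
  case 2:
    mu = Y + 0.1;
    theta = arma::log(mu);
    v = mu;
    break;
  default:
    stop("unknown family code");
  }
}

// update_mode: 0 = auto (dual when N < active P), 1 = primal, 2 = dual
//
// eta0 sets the initial adaptive weights (D = diag(eta0^2)); the first
// Newton pass linearizes at the family's standard IRLS starting means, so
// it is a plain (weighted) ridge solve.  Thereafter the adaptive weights
// and the linearization point are both the previous iterate.
// [[Rcpp::export(name = ".l0fit_cpp")]]
List l0fit_cpp(const arma::mat& X, const arma::vec& Y, int fam, double lambda,
               const arma::vec& eta0, int max_iter, double tol,
               double zero_eps, int update_mode, bool threshold_each_iter,
               bool keep_path) {
  const arma::uword N = X.n_rows;
  arma::vec beta(X.n_cols, arma::fill::zeros);
  arma::vec eta = eta0;
  bool converged = false;
  int it = 0;
  std::vector<arma::vec> path;

  for (it = 1; it <= max_iter; ++it) {
    arma::uvec active = arma::find(eta != 0.0);
    arma::vec beta_new(beta.n_elem, arma::fill::zeros);
    if (active.n_elem > 0) {
      arma::mat Xa = X.cols(active);
      arma::vec theta, mu, v;
      if (it == 1) {
        irls_start(Y, fam, theta, mu, v);
      } else {
        theta = Xa * beta.elem(active);
        fam_moments(theta, fam, mu, v);
      }
      arma::vec z = v % theta + (Y - mu);
      arma::vec eta_a = eta.elem(active);
      bool use_dual = (update_mode == 2) ||
                      (update_mode == 0 && N < active.n_elem);
      arma::vec ba = use_dual ? dual_core(Xa, z, v, eta_a, lambda)
                              : primal_core(Xa, z, v, eta_a, lambda);
      if (threshold_each_iter)
        ba.elem(arma::find(arma::abs(ba) < zero_eps)).zeros();
      beta_new.elem(active) = ba;
    }
    if (!beta_new.is_finite())
      stop("solver diverged (non-finite coefficients) at iteration %d", it);
    double delta = arma::norm(beta_new - beta, "inf");
    beta = beta_new;
    eta = beta;
    if (keep_path) path.push_back(beta);
    if (delta < tol) {
      converged = true;
      break;
    }
  }
  if (it > max_iter) it = max_iter;

  // final hard threshold so the reported support is exact
  beta.elem(arma::find(arma::abs(beta) < zero_eps)).zeros();

  List out = List::create(_["beta"] = beta,
                          _["n_iter"] = it,
                          _["converged"] = converged);
  if (keep_path) {
    arma::mat pm(beta.n_elem, path.size());
    for (size_t k = 0; k < path.size(); ++k) pm.col(k) = path[k];
    out["path"] = pm;
  }
  return out;
}
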