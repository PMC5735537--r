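# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: GLM fits go through stats::glm.fit and the
# simplified log-likelihood is recomputed term by term.

# scalar recomputation of the simplified log-likelihood (independent of
# simplified_loglik's vectorized implementation)
oracle_loglik <- function(y, theta, family) {
  B <- switch(family,
              linear = function(t) t^2 / 2,
              logistic = function(t) log(1 + exp(t)),
              poisson = function(t) exp(t))
  total <- 0
  for (i in seq_along(y)) total <- total + y[i] * theta[i] - B(theta[i])
  total
}

# unpenalized restricted MLE via stats::glm.fit; returns the fitted linear
# predictor for the given support (empty support -> theta = 0)
oracle_restricted_theta <- function(x, y, support, family) {
  if (length(support) == 0L) return(rep(0, length(y)))
  xs <- x[, support, drop = FALSE]
  glm_fam <- switch(family, poisson = stats::poisson(),
                    logistic = stats::quasibinomial(),
                    linear = stats::gaussian())
  fit <- suppressWarnings(stats::glm.fit(xs, y, family = glm_fam))
  drop(xs %*% fit$coefficients)
}

# exhaustive best-subset search: minimize -L + (lambda/2)|s| over all 2^P
# supports, each scored at its restricted MLE
oracle_best_subset <- function(x, y, family, lambda) {
  P <- ncol(x)
  best <- Inf
  best_s <- integer(0)
  for (m in 0:(2^P - 1)) {
    s <- which(bitwAnd(m, 2^(0:(P - 1))) > 0)
    theta <- oracle_restricted_theta(x, y, s, family)
    obj <- -oracle_loglik(y, theta, family) + lambda / 2 * length(s)
    if (obj < best) {
      best <- obj
      best_s <- s
    }
  }
  list(objective = best, support = best_s)
}

# score a given support the same way the subset oracle scores candidates
oracle_support_objective <- function(x, y, support, family, lambda) {
  theta <- oracle_restricted_theta(x, y, support, family)
  -oracle_loglik(y, theta, family) + lambda / 2 * length(support)
}

# small random step instance for primal/dual comparisons
random_step_instance <- function(n, p, seed) {
  set.seed(seed)
  list(x = matrix(rnorm(n * p), n, p),
       z = rnorm(n),
       v = runif(n, 0.05, 2),
       eta = rnorm(p) * rbinom(p, 1, 0.8))  # some exact zeros
}
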