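#' Solver control parameters
#'
#' @param max_iter Maximum number of adaptive-ridge passes.
#' @param tol Convergence tolerance: the iteration stops when the sup-norm
#'   change of the (thresholded) coefficient vector falls below `tol`.
#' @param zero_eps Hard threshold: coefficients with absolute value below
#'   `zero_eps` are set to exact zero.
#' @param init Initial weight vector \eqn{\eta^0}: `"ones"` (the first pass
#'   is then a plain ridge solve) or `"random"` (independent standard-normal
#'   draws).
#' @param seed Integer seed used when `init = "random"`; `NULL` draws from
#'   the current RNG state.
#' @param update_mode `"auto"` picks the dual \eqn{N \times N} update when
#'   the active feature count exceeds \eqn{N} and the primal
#'   \eqn{P \times P} update otherwise; `"primal"` / `"dual"` force one.
#' @param threshold_each_iter Apply the hard threshold after every pass
#'   (default) rather than only after convergence.  Zeros are absorbing
#'   either way; per-pass thresholding just converges in fewer passes.
#' @param keep_path Record the coefficient vector after every pass (for
#'   diagnostics) in the fit's `path` element.
#' @return A list of class `l0_control`.
#' @export
l0_control <- function(max_iter = 100L, tol = 1e-8, zero_eps = 1e-6,
                       init = c("ones", "random"), seed = NULL,
                       update_mode = c("auto", "primal", "dual"),
                       threshold_each_iter = TRUE, keep_path = FALSE) {
  init <- match.arg(init)
  update_mode <- match.arg(update_mode)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("'max_iter' must be at least 1")
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be positive")
  if (!is.numeric(zero_eps) || zero_eps <= 0)
    stop("'zero_eps' must be positive")
  structure(list(max_iter = max_iter, tol = tol, zero_eps = zero_eps,
                 init = init, seed = seed, update_mode = update_mode,
                 threshold_each_iter = isTRUE(threshold_each_iter),
                 keep_path = isTRUE(keep_path)),
            class = "l0_control")
}

check_step_args <- function(x, z, v, eta, lambda) {
  x <- as.matrix(x)
  if (!all(is.finite(x), is.finite(z), is.finite(v), is.finite(eta),
           is.finite(lambda)))
    stop("all step inputs must be finite")
  if (length(z) != nrow(x) || length(v) != nrow(x))
    stop("'z' and 'v' must have length nrow(x)")
  if (length(eta) != ncol(x))
    stop("'eta' must have length ncol(x)")
  if (lambda < 0) stop("'lambda' must be nonnegative")
  x
}

#' One primal adaptive-ridge Newton step
#'
#' Solves the \eqn{P \times P} system
#' \eqn{(D X^t V X + \lambda I)\beta = D X^t Z} with \eqn{D =
#' \mathrm{diag}(\eta^2)}.  Features with \eqn{\eta_j = 0} decouple and
#' return \eqn{\beta_j = 0} exactly (zeros are absorbing).  At
#' \eqn{\lambda = 0} a jitter of `1e-12` is added to the diagonal; the
#' system must then be otherwise nonsingular.
#'
#' @param x Numeric \eqn{N \times P} design matrix.
#' @param z Working response \eqn{Z = V\theta + (Y - \mu)}, length \eqn{N}.
#' @param v Variance weights \eqn{V(\mu_i)}, length \eqn{N}.
#' @param eta Adaptive weights (previous coefficient estimate), length
#'   \eqn{P}.
#' @param lambda Penalty weight \eqn{\lambda \ge 0}.
#' @return Numeric vector of length \eqn{P}.
#' @seealso [dual_step()] for the equivalent \eqn{N \times N} form.
#' @export
primal_step <- function(x, z, v, eta, lambda) {
  x <- check_step_args(x, z, v, eta, lambda)
  beta <- .primal_step_cpp(x, as.numeric(z), as.numeric(v), as.numeric(eta),
                           lambda)
  if (!all(is.finite(beta)))
    stop("primal step produced non-finite coefficients; ",
         "the system is singular (increase lambda)")
  drop(beta)
}

#' One dual adaptive-ridge Newton step
#'
#' Computes the same update as [primal_step()] through the matrix identity
#' \eqn{(D X^t V X + \lambda I_P)^{-1} D X^t =
#' D X^t (V X D X^t + \lambda I_N)^{-1}}, i.e.
#' \eqn{\beta = D X^t (V X D X^t + \lambda I_N)^{-1} Z}, which only inverts
#' an \eqn{N \times N} matrix and is the efficient choice when
#' \eqn{N \ll P}.  Requires \eqn{\lambda > 0}.
#'
#' @inheritParams primal_step
#' @return Numeric vector of length \eqn{P}, identical (to numerical
#'   accuracy) to the primal step on the same inputs.
#' @export
dual_step <- function(x, z, v, eta, lambda) {
  x <- check_step_args(x, z, v, eta, lambda)
  if (lambda <= 0) stop("the dual update requires lambda > 0")
  drop(.dual_step_cpp(x, as.numeric(z), as.numeric(v), as.numeric(eta),
                      lambda))
}

#' L0-penalized objective
#'
#' The criterion the adaptive-ridge solver approximately minimizes:
#' \eqn{\sum_i [B(\theta_i) - Y_i\theta_i] + (\lambda/2)\,|\beta|_0}, where
#' \eqn{|\beta|_0} counts nonzero coefficients and \eqn{\theta = X\beta}.
#'
#' @param x Design matrix (including any intercept column `beta` refers
#'   to).
#' @param y Response vector.
#' @param beta Coefficient vector of length `ncol(x)`.
#' @param family A family name or [l0_family()] object.
#' @param lambda Penalty weight.
#' @return A single numeric value (smaller is better).
#' @export
l0_objective <- function(x, y, beta, family, lambda) {
  x <- as.matrix(x)
  if (length(beta) != ncol(x)) stop("'beta' must have length ncol(x)")
  if (!all(is.finite(beta))) stop("'beta' must be finite")
  theta <- drop(x %*% beta)
  -simplified_loglik(y, theta, family) + lambda / 2 * sum(beta != 0)
}

#' Fit an L0-penalized GLM by adaptive ridge
#'
#' Approximates the L0-penalized GLM
#' \deqn{\min_\beta \; \sum_i [B(\theta_i) - Y_i\theta_i] +
#'       \frac{\lambda}{2}|\beta|_0, \qquad \theta = X\beta,}
#' by a fixed-point iteration of ridge solves in which feature \eqn{j}
#' carries the penalty \eqn{\lambda/(2\eta_j^2)} with \eqn{\eta} set to the
#' previous coefficient estimate.  Small coefficients receive an ever
#' larger penalty and collapse to exact zero (they are hard-thresholded at
#' `zero_eps` and zeros are absorbing); large coefficients escape
#' shrinkage.  Each pass is one Newton step against the working response
#' \eqn{Z = V\theta + (Y - \mu)}, solved in the primal \eqn{P \times P} or
#' dual \eqn{N \times N} form (see [l0_control()]).
#'
#' @param x Numeric \eqn{N \times P} feature matrix.
#' @param y Response vector of length \eqn{N} (continuous for linear,
#'   counts for poisson, binary or probability-valued in \eqn{[0,1]} for
#'   logistic).
#' @param family A family name (`"linear"`, `"logistic"`, `"poisson"`) or
#'   [l0_family()] object.
#' @param lambda Penalty weight \eqn{\lambda \ge 0}.  \eqn{\lambda = 0} is
#'   only accepted with the primal update.
#' @param intercept Prepend an all-ones column named `"(Intercept)"`?  The
#'   intercept is penalized like any other coefficient.
#' @param control A [l0_control()] list.
#' @return An object of class `l0fit`: a list with elements `beta` (named
#'   coefficient vector of length \eqn{P} plus one if `intercept`),
#'   `support` (sorted indices of nonzero coefficients), `n_iter`,
#'   `converged`, `neg_loglik`, `objective`
#'   (\eqn{-L + (\lambda/2)|\beta|_0}), `lambda`, `family`, `intercept`,
#'   `nobs`, and optionally `path` (coefficients after every pass, when
#'   `control$keep_path`).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200 * 10), 200, 10)
#' y <- rpois(200, exp(1 + 0.5 * x[, 1] - 0.4 * x[, 2]))
#' fit <- l0adridge(x, y, "poisson", lambda = log(200))
#' coef(fit)[fit$support]
#' @export
l0adridge <- function(x, y, family = c("linear", "logistic", "poisson"),
                      lambda, intercept = TRUE, control = l0_control()) {
  family <- l0_family(family)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("'x' must be a nonempty matrix")
  if (!all(is.finite(x))) stop("'x' must be finite")
  if (!all(is.finite(y))) stop("'y' must be finite")
  family$check_y(y)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0)
    stop("'lambda' must be a single nonnegative number")
  if (!inherits(control, "l0_control")) control <- do.call(l0_control, control)

  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (intercept) x <- cbind(`(Intercept)` = 1, x)
  p <- ncol(x)

  um <- match(control$update_mode, c("auto", "primal", "dual")) - 1L
  if (lambda == 0) {
    if (um == 2L)
      stop("lambda = 0 is not allowed with the dual update; use 'primal'")
    um <- 1L  # auto falls back to the (jittered) primal form
  }

  beta0 <- if (control$init == "ones") rep(1, p) else
    with_seed(control$seed, rnorm(p))

  res <- .l0fit_cpp(x, y, fam_code(family), lambda, beta0,
                    control$max_iter, control$tol, control$zero_eps, um,
                    control$threshold_each_iter, control$keep_path)
  beta <- drop(res$beta)
  names(beta) <- colnames(x)
  support <- which(beta != 0)
  theta <- drop(x %*% beta)
  negll <- -simplified_loglik(y, theta, family)
  structure(list(beta = beta,
                 support = support,
                 n_iter = res$n_iter,
                 converged = res$converged,
                 neg_loglik = negll,
                 objective = negll + lambda / 2 * length(support),
                 lambda = lambda,
                 family = family$name,
                 intercept = isTRUE(intercept),
                 nobs = length(y),
                 path = res$path),
            class = "l0fit")
}

# run expr under a temporary seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @export
coef.l0fit <- function(object, ...) object$beta

#' Predict from an L0-penalized GLM fit
#'
#' @param object An `l0fit` object.
#' @param newx Feature matrix with the same columns the model was fit on
#'   (without the intercept column; it is added automatically when the fit
#'   used one).
#' @param type `"response"` for the mean \eqn{G(X\beta)}, `"link"` for the
#'   linear predictor \eqn{X\beta}.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.l0fit <- function(object, newx,
                          type = c("response", "link"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  if (object$intercept) newx <- cbind(`(Intercept)` = 1, newx)
  if (ncol(newx) != length(object$beta))
    stop("'newx' has ", ncol(newx) - object$intercept,
         " columns; the fit used ",
         length(object$beta) - object$intercept)
  theta <- drop(newx %*% object$beta)
  if (type == "link") theta else l0_family(object$family)$linkinv(theta)
}

#' @export
print.l0fit <- function(x, ...) {
  cat(sprintf("L0 adaptive-ridge %s fit (N = %d)\n", x$family, x$nobs))
  cat(sprintf("  lambda = %.6g, selected %d of %d coefficients\n",
              x$lambda, length(x$support), length(x$beta)))
  cat(sprintf("  %d iterations, %sconverged; -loglik = %.4f, objective = %.4f\n",
              x$n_iter, if (x$converged) "" else "NOT ", x$neg_loglik,
              x$objective))
  if (length(x$support) > 0 && length(x$support) <= 20) {
    cat("  support:", paste(names(x$beta)[x$support], collapse = ", "), "\n")
  }
  invisible(x)
}
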