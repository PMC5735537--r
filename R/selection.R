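#' AIC- and BIC-tuned fits
#'
#' Information-criterion tuning of the L0 penalty weight.  With the
#' objective \eqn{-L + (\lambda/2)|\beta|_0}, setting \eqn{\lambda = 2}
#' reproduces AIC (\eqn{-2L + 2k} after doubling) and
#' \eqn{\lambda = \log N} reproduces the classical BIC
#' (\eqn{-2L + k\log N}).
#'
#' @inheritParams l0adridge
#' @param ... Passed on to [l0adridge()] (e.g. `intercept`, `control`).
#' @return An [l0adridge()] fit at the criterion's \eqn{\lambda}.
#' @export
l0adridge_aic <- function(x, y, family, ...) {
  l0adridge(x, y, family, lambda = 2, ...)
}

#' @rdname l0adridge_aic
#' @export
l0adridge_bic <- function(x, y, family, ...) {
  n <- nrow(as.matrix(x))
  if (is.null(n) || n < 2L)
    stop("BIC tuning needs at least 2 observations (log N must be positive)")
  l0adridge(x, y, family, lambda = log(n), ...)
}

#' Log-spaced penalty grid
#'
#' `n_intervals` equal intervals in log scale from `lambda_min` to
#' `lambda_max` inclusive, i.e. `n_intervals + 1` geometrically spaced
#' values with both endpoints present exactly.
#'
#' @param lambda_min,lambda_max Positive grid endpoints,
#'   `lambda_min < lambda_max`.
#' @param n_intervals Number of log-scale intervals (at least 1).
#' @return Strictly increasing numeric vector of length `n_intervals + 1`.
#' @examples
#' lambda_grid(1e-4, 1, 4)  # 1e-4, 1e-3, 1e-2, 1e-1, 1
#' @export
lambda_grid <- function(lambda_min = 1e-4, lambda_max, n_intervals = 100) {
  if (!is.numeric(lambda_min) || !is.numeric(lambda_max) ||
      lambda_min <= 0 || lambda_max <= lambda_min)
    stop("need 0 < lambda_min < lambda_max")
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1L) stop("'n_intervals' must be at least 1")
  g <- exp(seq(log(lambda_min), log(lambda_max),
               length.out = n_intervals + 1L))
  g[1L] <- lambda_min
  g[n_intervals + 1L] <- lambda_max
  g
}

# Default upper grid endpoint: the smallest 2^k * log(N), k = 0, 1, ...,
# whose full-data fit has an empty (or intercept-only) support, capped at
# 2^10 * log(N).  Guarantees the grid brackets the whole sparsity range.
default_lambda_max <- function(x, y, family, intercept, control) {
  base <- log(nrow(x))
  lam <- base
  for (k in 0:10) {
    lam <- base * 2^k
    fit <- l0adridge(x, y, family, lambda = lam, intercept = intercept,
                     control = control)
    supp <- fit$support
    if (intercept) supp <- setdiff(supp, 1L)
    if (length(supp) == 0L) break
  }
  lam
}

#' Cross-validated penalty selection
#'
#' Standard k-fold cross-validation of the L0 penalty weight over a
#' log-spaced grid.  Rows are shuffled into `nfolds` disjoint folds
#' (seeded); for every \eqn{\lambda} and fold the model is fit on the
#' training part and scored on the held-out part by the mean squared
#' difference between the held-out response and the predicted mean
#' \eqn{\hat\mu} (for binary data this is the Brier score; for
#' probability-valued logistic responses it is the squared probability
#' error).  The \eqn{\lambda} with the smallest mean test error wins, with
#' ties broken toward the larger (sparser) value — deliberately *not* the
#' one-standard-error rule — and the final model is refit on all rows at
#' that \eqn{\lambda}.
#'
#' When `lambda` is `NULL` the grid runs from `lambda_min` over
#' `n_intervals` equal log-scale intervals up to a pilot-determined upper
#' endpoint: the smallest \eqn{2^k \log N} at which the full-data fit
#' selects nothing beyond the intercept (capped at \eqn{2^{10}\log N}).
#'
#' @inheritParams l0adridge
#' @param nfolds Number of folds (at least 2, at most \eqn{N}).
#' @param lambda Optional penalty grid; sorted ascending if supplied.
#' @param lambda_min,n_intervals Grid construction parameters used when
#'   `lambda` is `NULL` (see [lambda_grid()]).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `cv_l0fit`: list with `lambda` (the grid),
#'   `cvm` (mean held-out squared error per \eqn{\lambda}), `cvsd` (its SD
#'   across folds), `lambda_best`, `fit` (the full-data refit at
#'   `lambda_best`), `heldout_mu` (each row's held-out predicted mean at
#'   `lambda_best`), `fold_id`, `nfolds` and `seed`.
#' @export
cv_l0adridge <- function(x, y, family = c("linear", "logistic", "poisson"),
                         nfolds = 5, lambda = NULL, seed = NULL,
                         intercept = TRUE, control = l0_control(),
                         lambda_min = 1e-4, n_intervals = 100) {
  family <- l0_family(family)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x)
  nfolds <- as.integer(nfolds)
  if (nfolds < 2L) stop("'nfolds' must be at least 2")
  if (n < nfolds) stop("need at least as many rows as folds")
  if (!inherits(control, "l0_control")) control <- do.call(l0_control, control)

  if (is.null(lambda)) {
    lam_max <- default_lambda_max(x, y, family, intercept, control)
    lambda <- lambda_grid(lambda_min, lam_max, n_intervals)
  } else {
    lambda <- sort(as.numeric(lambda))
  }
  nlam <- length(lambda)

  fold_id <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  preds <- matrix(NA_real_, n, nlam)
  fold_mse <- matrix(NA_real_, nfolds, nlam)
  for (k in seq_len(nfolds)) {
    test <- which(fold_id == k)
    train <- which(fold_id != k)
    if (family$name == "logistic" && length(unique(y[train])) == 1L)
      warning("fold ", k, " has a constant training response")
    for (l in seq_len(nlam)) {
      fit <- l0adridge(x[train, , drop = FALSE], y[train], family,
                       lambda = lambda[l], intercept = intercept,
                       control = control)
      mu <- predict(fit, x[test, , drop = FALSE], type = "response")
      preds[test, l] <- mu
      fold_mse[k, l] <- mean((y[test] - mu)^2)
    }
  }
  cvm <- colMeans((y - preds)^2)
  cvsd <- apply(fold_mse, 2, sd)
  best <- max(which(cvm == min(cvm)))  # ties -> larger lambda
  final <- l0adridge(x, y, family, lambda = lambda[best],
                     intercept = intercept, control = control)
  structure(list(lambda = lambda, cvm = cvm, cvsd = cvsd,
                 lambda_best = lambda[best], fit = final,
                 heldout_mu = preds[, best], fold_id = fold_id,
                 nfolds = nfolds, seed = seed),
            class = "cv_l0fit")
}

#' @export
print.cv_l0fit <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated L0 adaptive-ridge %s fit\n",
              x$nfolds, x$fit$family))
  cat(sprintf("  grid: %d values in [%.3g, %.3g]; lambda_best = %.6g\n",
              length(x$lambda), min(x$lambda), max(x$lambda),
              x$lambda_best))
  cat(sprintf("  held-out MSE at lambda_best = %.6g (trMSE = %.4f)\n",
              min(x$cvm), sqrt(min(x$cvm))))
  print(x$fit)
  invisible(x)
}

#' @export
coef.cv_l0fit <- function(object, ...) object$fit$beta

#' @export
predict.cv_l0fit <- function(object, newx, ...) predict(object$fit, newx, ...)
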