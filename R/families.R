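#' Canonical exponential-family descriptions
#'
#' Construct the family object used by [l0adridge()].  A family is the
#' canonical-link triple: the cumulant function \eqn{B(\theta)}, its first
#' derivative \eqn{G(\theta) = B'(\theta)} (the inverse link, giving the
#' conditional mean \eqn{\mu}) and its second derivative
#' \eqn{V(\mu) = B''(\theta)} (the variance function).  The dispersion is
#' fixed at 1 and the normalising terms of the exponential-family density
#' are dropped, so the log-likelihood used throughout the package is the
#' simplified form \eqn{\sum_i \{Y_i \theta_i - B(\theta_i)\}}.
#'
#' The three supported families are:
#' \describe{
#'   \item{linear}{\eqn{B(\theta) = \theta^2/2}, identity link,
#'     \eqn{V(\mu) = 1}.}
#'   \item{logistic}{\eqn{B(\theta) = \log(1 + e^\theta)}, logit link,
#'     \eqn{V(\mu) = \mu(1-\mu)}.  Responses may be binary or
#'     probability-valued in \eqn{[0, 1]} (quasi-likelihood working
#'     responses); only \eqn{Y - \mu} enters the fitting equations.}
#'   \item{poisson}{\eqn{B(\theta) = e^\theta}, log link,
#'     \eqn{V(\mu) = \mu}.}
#' }
#'
#' To guard against overflow the linear predictor is clipped before
#' exponentiation: to \eqn{[-30, 30]} for the logistic family and to
#' \eqn{(-\infty, 30]} for the Poisson family.  At the effect sizes this
#' package targets the clip is never active at convergence.
#'
#' @param name One of `"linear"`, `"logistic"`, `"poisson"`.  An
#'   `l0_family` object is passed through unchanged.
#' @return An object of class `l0_family`: a list with elements `name`,
#'   `B` (cumulant function), `linkinv` (mean function \eqn{G}), `linkfun`
#'   (\eqn{G^{-1}}), `variance` (\eqn{V(\mu)}), `theta_cap` (clip bounds)
#'   and `check_y` (response-domain validator).
#' @examples
#' fam <- l0_family("logistic")
#' fam$linkinv(0)        # 0.5
#' fam$variance(0.5)     # 0.25
#' @export
l0_family <- function(name = c("linear", "logistic", "poisson")) {
  if (inherits(name, "l0_family")) return(name)
  if (!is.character(name) || length(name) < 1L)
    stop("'name' must be a family name or an 'l0_family' object")
  name <- match.arg(name)
  fam <- switch(name,
    linear = list(
      name = "linear",
      B = function(theta) theta^2 / 2,
      linkinv = function(theta) theta,
      linkfun = function(mu) mu,
      variance = function(mu) rep(1, length(mu)),
      theta_cap = c(-Inf, Inf),
      check_y = function(y) invisible(TRUE)
    ),
    logistic = list(
      name = "logistic",
      B = function(theta) {
        th <- pmin(pmax(theta, -30), 30)
        pmax(th, 0) + log1p(exp(-abs(th)))
      },
      linkinv = function(theta) plogis(pmin(pmax(theta, -30), 30)),
      linkfun = function(mu) qlogis(mu),
      variance = function(mu) mu * (1 - mu),
      theta_cap = c(-30, 30),
      check_y = function(y) {
        if (any(y < 0 | y > 1))
          stop("logistic responses must lie in [0, 1] ",
               "(binary or probability-valued)")
        invisible(TRUE)
      }
    ),
    poisson = list(
      name = "poisson",
      B = function(theta) exp(pmin(theta, 30)),
      linkinv = function(theta) exp(pmin(theta, 30)),
      linkfun = function(mu) log(mu),
      variance = function(mu) mu,
      theta_cap = c(-Inf, 30),
      check_y = function(y) {
        if (any(y < 0))
          stop("poisson responses must be nonnegative counts")
        invisible(TRUE)
      }
    )
  )
  structure(fam, class = "l0_family")
}

# integer code used by the compiled solver
fam_code <- function(family) {
  match(family$name, c("linear", "logistic", "poisson")) - 1L
}

#' Mean and variance of a GLM family along a linear predictor
#'
#' Evaluates \eqn{\mu_i = G(\theta_i)} and \eqn{v_i = V(\mu_i)} for each
#' element of `theta`, applying the family's overflow clip before
#' exponentiation.
#'
#' @param theta Numeric vector of linear-predictor values (finite).
#' @param family A family name or [l0_family()] object.
#' @return A list with numeric vectors `mu` and `v`.
#' @examples
#' eval_moments(0, "logistic")  # mu = 0.5, v = 0.25
#' @export
eval_moments <- function(theta, family) {
  family <- l0_family(family)
  if (!is.numeric(theta)) stop("'theta' must be numeric")
  if (!all(is.finite(theta))) stop("'theta' must be finite")
  mu <- family$linkinv(theta)
  list(mu = mu, v = family$variance(mu))
}

#' Simplified exponential-family log-likelihood
#'
#' Computes \eqn{\sum_i \{Y_i \theta_i - B(\theta_i)\}}, the log-likelihood
#' with the dispersion fixed at 1 and the response-only normalising terms
#' dropped.  Larger is better.
#'
#' @param y Response vector (counts \eqn{\ge 0} for poisson; values in
#'   \eqn{[0,1]} for logistic).
#' @param theta Linear-predictor vector, same length as `y`.
#' @param family A family name or [l0_family()] object.
#' @return A single numeric value.
#' @examples
#' simplified_loglik(c(1, 0), c(0, 0), "logistic")  # -2 log 2
#' @export
simplified_loglik <- function(y, theta, family) {
  family <- l0_family(family)
  if (length(y) != length(theta))
    stop("'y' and 'theta' must have the same length")
  if (!all(is.finite(y)) || !all(is.finite(theta)))
    stop("'y' and 'theta' must be finite")
  family$check_y(y)
  sum(y * theta - family$B(theta))
}
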