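test_that("primal step solves the weighted ridge system with absorbing zeros", {
  # all weights off: the right-hand side is annihilated
  set.seed(1)
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(primal_step(x, rnorm(5), runif(5), rep(0, 4), 1),
               rep(0, 4))

  # fixed eta = 1, linear weights: closed-form ridge normal equations
  set.seed(2)
  x <- matrix(rnorm(8), 4, 2)
  y <- rnorm(4)
  lam <- 0.7
  ridge <- solve(crossprod(x) + lam * diag(2), crossprod(x, y))
  expect_equal(primal_step(x, y, rep(1, 4), rep(1, 2), lam), drop(ridge),
               tolerance = 1e-10)

  # mixed eta: zeros stay exactly zero, and the step equals the
  # per-feature-penalty ridge solve (lambda_j = lambda / eta_j^2) on the
  # active coordinates -- larger |eta_j| means a smaller penalty
  set.seed(3)
  x <- matrix(rnorm(15), 5, 3)
  z <- rnorm(5)
  v <- runif(5, 0.1, 1)
  eta <- c(0.8, 0, -1.3)
  b <- primal_step(x, z, v, eta, 2)
  expect_identical(b[2], 0)
  act <- c(1, 3)
  xa <- x[, act]
  alt <- solve(t(xa) %*% (v * xa) + 2 * diag(1 / eta[act]^2),
               crossprod(xa, z))
  expect_equal(b[act], drop(alt), tolerance = 1e-10)
})

test_that("effective per-feature penalty decreases in the weight magnitude", {
  lam <- 3
  etas <- c(1e-4, 1e-2, 0.5, 1, 5, 50)
  pen <- lam / (2 * etas^2)
  expect_true(all(diff(pen) < 0))
  # and the solver's step reflects it: growing one eta never shrinks that
  # coefficient's magnitude on an orthogonal design
  x <- diag(4)
  z <- c(2, 2, 2, 2)
  b1 <- primal_step(x, z, rep(1, 4), c(0.1, 0.5, 1, 5), lam)
  expect_true(all(diff(abs(b1)) > 0))
})

test_that("dual step matches the scalar ridge and rejects lambda = 0", {
  expect_equal(dual_step(matrix(1, 1, 1), 2, 1, 1, 1), 1)
  expect_equal(dual_step(matrix(rnorm(12), 3, 4), rnorm(3), runif(3),
                         rep(0, 4), 0.5),
               rep(0, 4))
  expect_error(dual_step(matrix(1, 1, 1), 2, 1, 1, 0), "lambda > 0")
})

test_that("primal and dual updates agree on random instances", {
  worst <- 0
  k <- 0
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(3:10, 1)
    p <- sample(2:60, 1)
    lam <- sample(c(0.1, 1, 10), 1)
    inst <- random_step_instance(n, p, seed)
    d <- max(abs(primal_step(inst$x, inst$z, inst$v, inst$eta, lam) -
                 dual_step(inst$x, inst$z, inst$v, inst$eta, lam)))
    worst <- max(worst, d)
    k <- k + 1
  }
  expect_equal(k, 50)
  expect_lt(worst, 1e-8)
})

test_that("vanishing penalty recovers the unpenalized GLM MLE", {
  d <- simulate_poisson_design(200, 5,
                               beta = c("1" = 0.5, "2" = -0.3, "4" = 0.4),
                               seed = 11)
  fit <- l0adridge(d$x, d$y, "poisson", lambda = 1e-10,
                   control = l0_control(update_mode = "primal"))
  mle <- glm(d$y ~ d$x, family = stats::poisson())
  expect_lt(max(abs(coef(fit) - coef(mle))), 1e-4)

  # same for probability-valued logistic responses (quasi-likelihood IRLS)
  dl <- simulate_logistic_design(200, 4, beta = c("1" = 0.7, "3" = -0.5),
                                 seed = 12)
  fl <- l0adridge(dl$x, dl$y, "logistic", lambda = 1e-10,
                  control = l0_control(update_mode = "primal"))
  ml <- suppressWarnings(glm(dl$y ~ dl$x, family = stats::quasibinomial()))
  expect_lt(max(abs(coef(fl) - coef(ml))), 1e-4)
})

test_that("a signal-free design yields the empty model", {
  x <- matrix(0, 10, 6)
  y <- rpois(10, 2)
  fit <- l0adridge(x, y, "poisson", lambda = 1, intercept = FALSE)
  expect_identical(unname(fit$support), integer(0))
  expect_equal(unname(coef(fit)), rep(0, 6))
})

test_that("zeros are absorbing along the whole iteration path", {
  for (seed in 1:6) {
    d <- simulate_poisson_design(60, 30, seed = seed)
    init <- if (seed %% 2 == 0) "random" else "ones"
    fit <- l0adridge_bic(d$x, d$y, "poisson",
                         control = l0_control(keep_path = TRUE, init = init,
                                              seed = seed))
    path <- fit$path
    for (j in seq_len(nrow(path))) {
      zeros <- which(path[j, ] == 0)
      if (length(zeros) > 0)
        expect_true(all(path[j, min(zeros):ncol(path)] == 0))
    }
  }
})

test_that("objective is the penalized negative log-likelihood", {
  # beta = 0, logistic: 4 log 2 and a zero count
  x <- matrix(rnorm(8), 4, 2)
  expect_equal(l0_objective(x, c(1, 0, 1, 0), c(0, 0), "logistic", 5),
               4 * log(2), tolerance = 1e-12)
  # adding a zero coefficient leaves the objective unchanged
  set.seed(21)
  x <- matrix(rnorm(10), 5, 2)
  y <- rpois(5, 2)
  o2 <- l0_objective(x, y, c(0.3, 0), "poisson", 2)
  o1 <- l0_objective(x[, 1, drop = FALSE], y, 0.3, "poisson", 2)
  expect_equal(o2, o1)
  # independent term-by-term recomputation
  expect_equal(o2, -oracle_loglik(y, 0.3 * x[, 1], "poisson") + 1,
               tolerance = 1e-12)
  # a fit's stored objective is recomputable from its own fields
  d <- simulate_poisson_design(80, 20, seed = 5)
  f <- l0adridge_bic(d$x, d$y, "poisson")
  expect_equal(f$objective,
               f$neg_loglik + f$lambda / 2 * length(f$support),
               tolerance = 1e-10)
  expect_identical(unname(f$support), unname(which(f$beta != 0)))
})

test_that("objective decreases along the path up to thresholding trades", {
  # hard thresholding can trade a small likelihood uptick for sparsity in
  # a single pass; the trajectory is monotone to within that trade
  for (seed in 1:5) {
    d <- simulate_poisson_design(100, 50, seed = seed)
    f <- l0adridge_bic(d$x, d$y, "poisson",
                       control = l0_control(keep_path = TRUE))
    x <- cbind(1, d$x)
    objs <- apply(f$path, 2, function(b)
      l0_objective(x, d$y, b, "poisson", f$lambda))
    if (length(objs) > 2) {
      expect_lt(max(diff(objs[-1])), 0.05)
      expect_lt(objs[length(objs)], objs[2])
    }
  }
})

test_that("at convergence the support coefficients sit at the ridge fixed point", {
  # on well-separated signals the adaptive shrinkage vanishes and the fit
  # agrees with the unpenalized IRLS refit on its own support
  d <- simulate_poisson_design(500, 10,
                               beta = c("1" = 0.6, "3" = 0.5, "7" = -0.5),
                               seed = 3)
  f <- l0adridge(d$x, d$y, "poisson", lambda = 0.5)
  expect_identical(unname(f$support), c(1L, 2L, 4L, 8L))
  theta <- oracle_restricted_theta(cbind(1, d$x), d$y, f$support, "poisson")
  refit <- suppressWarnings(
    stats::glm.fit(cbind(1, d$x)[, f$support], d$y,
                   family = stats::poisson()))
  expect_lt(max(abs(f$beta[f$support] - refit$coefficients)), 1e-3)
})

test_that("lambda = 0 falls back to the primal update and dual is refused", {
  d <- simulate_poisson_design(50, 3, beta = c("1" = 0.5), seed = 41)
  expect_error(l0adridge(d$x, d$y, "poisson", lambda = 0,
                         control = l0_control(update_mode = "dual")),
               "dual")
  f <- l0adridge(d$x, d$y, "poisson", lambda = 0)  # auto -> primal
  expect_s3_class(f, "l0fit")
})

test_that("input validation rejects malformed problems", {
  x <- matrix(rnorm(20), 5, 4)
  expect_error(l0adridge(x, rnorm(4), "linear", lambda = 1), "length")
  expect_error(l0adridge(x, c(1, 2, NA, 4, 5), "linear", lambda = 1),
               "finite")
  expect_error(l0adridge(x, rnorm(5), "linear", lambda = -1),
               "nonnegative")
  expect_error(l0adridge(x, c(-1, 1, 2, 0, 3), "poisson", lambda = 1),
               "nonnegative counts")
  expect_error(l0_control(max_iter = 0))
  expect_error(l0_control(zero_eps = 0))
})

test_that("prediction applies the inverse link with the stored intercept", {
  d <- simulate_poisson_design(100, 8, beta = c("2" = 0.6), seed = 51)
  f <- l0adridge_bic(d$x, d$y, "poisson")
  mu <- predict(f, d$x)
  th <- predict(f, d$x, type = "link")
  expect_equal(mu, exp(pmin(th, 30)))
  expect_equal(th, drop(cbind(1, d$x) %*% coef(f)))
})
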