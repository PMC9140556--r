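small_censored_data <- function() {
  s1 <- gphc_sample(c(30, 80), removals = c(1, 0), t_star = 100,
                    terminal_removals = 1, case = "II")
  s2 <- gphc_sample(c(55, 140), removals = c(1, 0), t_star = 160,
                    terminal_removals = 1, case = "II")
  stress <- gphc_sample(c(110, 350), removals = c(2, 0), t_star = 400,
                        terminal_removals = 1, case = "II")
  mss_data(list(s1, s2), stress)
}

test_that("joint log-likelihood composes from per-sample GPHC likelihoods", {
  d <- small_censored_data()
  p <- list(alpha = 0.004, eta = 0.006, theta = 0.005, beta = 0.35)
  expected <- sum(vapply(d$strength, gphc_loglik, 1,
                         logpdf = function(x) dgompertz(x, p$alpha, p$eta, log = TRUE),
                         cdf = function(x) pgompertz(x, p$alpha, p$eta))) +
    gphc_loglik(d$stress,
                logpdf = function(y) dchen(y, p$theta, p$beta, log = TRUE),
                cdf = function(y) pchen(y, p$theta, p$beta))
  expect_equal(mss_loglik(p, d), expected, tolerance = 1e-9)
  expect_error(mss_loglik(list(alpha = -1, eta = 1, theta = 1, beta = 1), d))
})

test_that("log-likelihood is finite at the published estimates on the bundled data", {
  d <- reservoir_data()
  ll <- mss_loglik(list(alpha = 0.0010, eta = 1.96e-5,
                        theta = 0.0021, beta = 0.2922), d)
  expect_true(is.finite(ll))
})

test_that("observed information matches a central-difference Hessian", {
  d <- small_censored_data()
  p <- mss_params(0.004, 0.006, 0.005, 0.35)
  I <- observed_information(p, d)
  # finite-difference oracle on mss_loglik
  pv <- unlist(p)
  num_hess <- matrix(0, 4, 4)
  h <- 1e-4 * pv
  for (a in 1:4) for (b in 1:4) {
    pp <- function(da, db) {
      q <- pv; q[a] <- q[a] + da; q[b] <- q[b] + db
      mss_loglik(as.list(q), d)
    }
    num_hess[a, b] <- (pp(h[a], h[b]) - pp(h[a], -h[b]) -
                       pp(-h[a], h[b]) + pp(-h[a], -h[b])) / (4 * h[a] * h[b])
  }
  expect_equal(unname(I), -num_hess, tolerance = 1e-4)
  # exact symmetry and block structure (the likelihood factorizes)
  expect_identical(I, t(I))
  expect_true(all(I[1:2, 3:4] == 0))
})

test_that("the fit is a stationary point and recovers simulated truth", {
  p <- sim_truth()
  set.seed(301)
  d <- simulate_mss(p, gphc_scheme(18, 15, 8, Inf, c(rep(0, 14), 3)),
                    gphc_scheme(210, 200, 120, Inf, c(rep(0, 199), 10)))
  fit <- mss_mle(d)
  expect_true(fit$converged)
  # natural-scale gradient is numerically zero relative to curvature
  expect_lt(sqrt(sum((fit$gradient * coef(fit))^2)), 1e-6)
  se <- sqrt(diag(vcov(fit)))
  truth <- unlist(p)
  expect_true(all(abs(coef(fit) - truth) < 3 * se))
  # user-supplied inits converge to the same optimum
  fit2 <- mss_mle(d, init = mss_params(0.01, 0.02, 0.02, 0.5))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-6)
})

test_that("asymptotic intervals scale linearly with the standard error", {
  d <- reservoir_data()
  fit <- mss_mle(d)
  ci95 <- confint(fit, level = 0.95)
  expect_true(all(ci95[, "lower"] <= coef(fit) & coef(fit) <= ci95[, "upper"]))
  # degenerate interval at level 0
  ci0 <- confint(fit, level = 0)
  expect_equal(ci0[, "lower"], ci0[, "upper"])
  expect_equal(ci0[, "lower"], coef(fit)[rownames(ci0)])
  # doubling the SE doubles the half-width
  half <- (ci95[, "upper"] - ci95[, "lower"]) / 2
  fit2 <- fit
  fit2$vcov <- 4 * fit$vcov
  half2 <- (confint(fit2)[, "upper"] - confint(fit2)[, "lower"]) / 2
  expect_equal(half2, 2 * half, tolerance = 1e-12)
})

test_that("delta-method reliability interval is consistent with its gradient", {
  fit <- mss_mle(reservoir_data())
  ri <- aci_reliability(fit, 1, 6)
  expect_s3_class(ri, "mss_interval")
  # the interval may legitimately exceed [0, 1]; clipping is opt-in
  ric <- aci_reliability(fit, 1, 6, clip = TRUE)
  expect_gte(ric$lower, 0)
  expect_lte(ric$upper, 1)
  # the reliability surface seen by the quadrature must agree with the
  # surface seen by direct simulation of the defining event: compare
  # matched finite differences along beta
  est <- coef(fit)
  k <- 4
  h <- 0.02 * est[k]
  up <- est; up[k] <- up[k] + h
  dn <- est; dn[k] <- dn[k] - h
  fd_quad <- (as.numeric(rsj(1, 6, up[1], up[2], up[3], up[4])) -
              as.numeric(rsj(1, 6, dn[1], dn[2], dn[3], dn[4]))) / (2 * h)
  mcu <- rsj_mc(1, 6, up[1], up[2], up[3], up[4], n_rep = 4e5, seed = 91)
  mcd <- rsj_mc(1, 6, dn[1], dn[2], dn[3], dn[4], n_rep = 4e5, seed = 92)
  fd_mc <- (mcu$estimate - mcd$estimate) / (2 * h)
  se_fd <- sqrt(mcu$se^2 + mcd$se^2) / (2 * h)
  expect_lt(abs(fd_quad - fd_mc), 3 * se_fd)
  # and the delta-method gradient is the small-step limit of the same
  # quadrature difference quotient
  hs <- 1e-3 * est[k]
  up[k] <- est[k] + hs; dn[k] <- est[k] - hs
  fd_small <- (as.numeric(rsj(1, 6, up[1], up[2], up[3], up[4])) -
               as.numeric(rsj(1, 6, dn[1], dn[2], dn[3], dn[4]))) / (2 * hs)
  expect_equal(ri$gradient[k], unname(fd_small), tolerance = 1e-3)
})

test_that("strength-only and stress-only information separates cleanly", {
  # the separable likelihood means each block's estimate is unaffected
  # by the other sample: perturbing the stress data leaves (alpha, eta)
  # untouched
  d <- reservoir_data()
  fit <- mss_mle(d)
  X <- strength_matrix(d)
  d2 <- mss_data(X, d$stress$times * 2)
  fit2 <- mss_mle(d2)
  expect_equal(coef(fit2)[c("alpha", "eta")], coef(fit)[c("alpha", "eta")],
               tolerance = 1e-8)
})
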