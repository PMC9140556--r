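test_that("gamma conditional parameters follow the likelihood coefficients", {
  # three uncensored tiny stresses: A3 = M* + a3 = 4, A4 -> b3 = 1
  strength <- list(gphc_sample(1), gphc_sample(1), gphc_sample(1))
  stress <- gphc_sample(c(1e-8, 2e-8, 3e-8))
  d <- mss_data(strength, stress)
  pr <- mss_priors(a3 = 1, b3 = 1)
  A <- conditional_gamma_params(list(alpha = 1, eta = 1, theta = 1,
                                     beta = 0.5), d, pr)
  expect_equal(unname(A["A3"]), 4)
  expect_equal(unname(A["A4"]), 1, tolerance = 1e-3)
  # A1 counts every observed strength plus the prior shape
  expect_equal(unname(A["A1"]), 3 + pr$a1)
})

test_that("posterior mean reduces to the arithmetic chain mean", {
  fake <- structure(list(
    draws = matrix(c(1, 3), 2, 4,
                   dimnames = list(NULL, c("alpha", "eta", "theta", "beta"))),
    reliability = NULL, burn_in = 0L), class = "mss_bayes")
  expect_equal(unname(coef(fake)), rep(2, 4))
  fake$draws <- matrix(5, 10, 4,
                       dimnames = list(NULL, c("alpha", "eta", "theta", "beta")))
  fake$burn_in <- 3L
  expect_equal(unname(coef(fake)), rep(5, 4))
  # streaming-mean oracle on a long chain (matrix fills column-wise)
  set.seed(601)
  v <- rexp(1e5)
  fake$draws <- matrix(v, ncol = 4,
                       dimnames = list(NULL, c("alpha", "eta", "theta", "beta")))
  fake$burn_in <- 0L
  acc <- 0
  for (chunk in split(v[1:25000], rep(1:25, each = 1000)))
    acc <- acc + sum(chunk)
  expect_equal(unname(coef(fake))[1], acc / 25000, tolerance = 1e-12)
})

test_that("HPD interval is the shortest window and behaves on known shapes", {
  set.seed(602)
  u <- runif(2e5)
  h <- hpd_interval(u, 0.95)
  expect_equal(h$upper - h$lower, 0.95, tolerance = 0.01)
  # exhaustive-window oracle on a small sample
  x <- rgamma(500, 2, 1)
  h2 <- hpd_interval(x, 0.9)
  oracle <- brute_hpd(x, 0.9)
  expect_equal(c(h2$lower, h2$upper), oracle, tolerance = 1e-12)
  # contains the mode of a unimodal sample
  z <- rnorm(5e4)
  hz <- hpd_interval(z, 0.5)
  expect_lt(hz$lower, 0); expect_gt(hz$upper, 0)
  # never wider than the equal-tailed interval
  for (draws in list(u[1:5000], x, z)) {
    hp <- hpd_interval(draws, 0.95)
    eq <- quantile(draws, c(0.025, 0.975), names = FALSE)
    expect_lte(hp$upper - hp$lower, eq[2] - eq[1] + 1e-12)
  }
  expect_error(hpd_interval(1:10, 1.2), "level")
})

test_that("sampler recovers simulated truth and mixes", {
  p <- sim_truth()
  set.seed(603)
  d <- simulate_mss(p, gphc_scheme(14, 12, 6, Inf, c(rep(0, 11), 2)),
                    gphc_scheme(110, 100, 60, Inf, c(rep(0, 99), 10)))
  bb <- mss_bayes(d, n_iter = 2500, burn_in = 500, seed = 604)
  keep <- 501:2500
  post <- bb$draws[keep, ]
  means <- colMeans(post); sds <- apply(post, 2, sd)
  truth <- unlist(p)
  expect_true(all(abs(means - truth) < 3.5 * sds))
  expect_true(all(bb$acceptance > 0.05 & bb$acceptance < 0.95))
  expect_true(all(post > 0))
  # split-half stationarity smoke test with batch-means standard errors
  # (the random-walk chain is autocorrelated, so i.i.d. SEs undercount)
  batch_se <- function(m) {
    bm <- apply(m, 2, function(v) tapply(v, rep(1:10, each = 100), mean))
    apply(bm, 2, sd) / sqrt(10)
  }
  h1 <- colMeans(post[1:1000, ]); h2 <- colMeans(post[1001:2000, ])
  se <- sqrt(batch_se(post[1:1000, ])^2 + batch_se(post[1001:2000, ])^2)
  expect_true(all(abs(h1 - h2) < 5 * se))
  # seeded reproducibility
  b2 <- mss_bayes(d, n_iter = 300, burn_in = 100, seed = 99)
  b3 <- mss_bayes(d, n_iter = 300, burn_in = 100, seed = 99)
  expect_identical(b2$draws, b3$draws)
})

test_that("near-flat priors leave the posterior mode at the MLE", {
  p <- sim_truth()
  set.seed(605)
  d <- simulate_mss(p, gphc_scheme(12, 10, 6, Inf, c(rep(0, 9), 2)),
                    gphc_scheme(110, 100, 60, Inf, c(rep(0, 99), 10)))
  fit <- mss_mle(d)
  # genuinely flat priors: gamma shape 1 makes the prior density constant
  # up to the e^(-b p) factor, so the posterior mode is the MLE
  pr <- mss_priors(a1 = 1, b1 = 1e-8, a2 = 1, b2 = 1e-8,
                   a3 = 1, b3 = 1e-8, a4 = 1, b4 = 1e-8)
  logpost <- function(u) {
    q <- exp(u)
    mss_loglik(list(alpha = q[1], eta = q[2], theta = q[3], beta = q[4]), d) +
      sum((unlist(pr)[c("a1", "a2", "a3", "a4")] - 1) * u) -
      sum(unlist(pr)[c("b1", "b2", "b3", "b4")] * q)
  }
  opt <- optim(log(coef(fit)), logpost,
               control = list(fnscale = -1, reltol = 1e-14, maxit = 2000))
  mode <- exp(opt$par)
  expect_true(all(abs(mode - coef(fit)) / coef(fit) < 0.02))
})

test_that("gibbs draws of alpha and theta match their analytic conditionals", {
  # freeze (eta, beta) by giving the random walk zero step size: the
  # sampler then draws alpha and theta from their full conditionals at
  # fixed (eta, beta), which must be exactly the analytic gammas
  p <- sim_truth()
  set.seed(606)
  d <- simulate_mss(p, gphc_scheme(8, 6, 4, Inf, c(0, 0, 0, 0, 0, 2)),
                    gphc_scheme(10, 5, 3, Inf, c(0, 0, 0, 0, 5)))
  pr <- mss_priors()
  bb <- mss_bayes(d, priors = pr, n_iter = 4000, burn_in = 0,
                  proposal_sd = c(0, 0), init = p, seed = 607)
  expect_true(all(bb$draws[, "eta"] == p$eta))
  expect_true(all(bb$draws[, "beta"] == p$beta))
  A <- conditional_gamma_params(p, d, pr)
  expect_gt(suppressWarnings(
    ks.test(bb$draws[, "alpha"], pgamma,
            shape = A[["A1"]], rate = A[["A2"]]))$p.value, 0.01)
  expect_gt(suppressWarnings(
    ks.test(bb$draws[, "theta"], pgamma,
            shape = A[["A3"]], rate = A[["A4"]]))$p.value, 0.01)
})
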