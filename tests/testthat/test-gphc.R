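test_that("scheme validation names the violated constraint", {
  s <- gphc_scheme(8, 6, 4, 500, c(0, 0, 0, 0, 0, 2))
  expect_s3_class(s, "gphc_scheme")
  expect_error(gphc_scheme(8, 6, 6, 500, rep(0, 6)), "c < m")
  expect_error(gphc_scheme(8, 8, 4, 500, rep(0, 8)), "m < n")
  expect_error(gphc_scheme(8, 6, 4, 500, c(0, 0, 0, 0, 0, 1)),
               "sum\\(removals\\)")
  expect_error(gphc_scheme(8, 6, 4, 500, c(0, 0, 0, 0, -1, 3)),
               "removals >= 0")
})

test_that("termination resolves the three cases correctly", {
  sch <- gphc_scheme(8, 6, 4, 3, c(0, 0, 0, 0, 0, 2))
  times <- 1:6
  # time limit before the guaranteed c-th failure: stop at the c-th,
  # terminal removals sum_(i>c) (R_i + 1)
  s1 <- gphc_termination(times, sch)
  expect_identical(s1$case, "I")
  expect_identical(s1$j_star, 4L)
  expect_equal(s1$t_star, 4)
  expect_identical(s1$terminal_removals, 4L)
  # limit between the c-th and m-th failure: stop at T
  sch2 <- gphc_scheme(8, 6, 4, 5.5, c(0, 0, 0, 0, 0, 2))
  s2 <- gphc_termination(times, sch2)
  expect_identical(s2$case, "II")
  expect_identical(s2$j_star, 5L)
  expect_equal(s2$t_star, 5.5)
  expect_identical(s2$terminal_removals, 8L - 0L - 5L)
  # no effective limit: progressive type-II censoring
  sch3 <- gphc_scheme(8, 6, 4, Inf, c(0, 0, 0, 0, 0, 2))
  s3 <- gphc_termination(times, sch3)
  expect_identical(s3$case, "III")
  expect_identical(s3$j_star, 6L)
  expect_identical(s3$terminal_removals, 0L)
  # bookkeeping identity n = J* + sum(removals) + terminal
  for (s in list(s1, s2, s3))
    expect_identical(s$n, 8L)
  expect_error(gphc_termination(c(1, 2, 2, 3, 4, 5), sch3), "tied")
})

test_that("simulated samples satisfy the termination invariants", {
  sch <- gphc_scheme(8, 6, 4, 120, c(0, 0, 0, 0, 0, 2))
  set.seed(42)
  for (i in 1:200) {
    s <- rgphc(sch, function(u) qgompertz(u, 0.0061, 0.009))
    expect_gte(s$j_star, sch$c)
    expect_lte(s$j_star, sch$m)
    expect_true(!is.unsorted(s$times))
    if (s$case == "I") expect_equal(s$t_star, s$times[sch$c])
    if (s$case == "II") expect_equal(s$t_star, sch$t_max)
    if (s$case == "III") expect_identical(s$terminal_removals, 0L)
  }
  # T = Inf puts all mass on case III with j_star = m
  set.seed(43)
  sch_inf <- gphc_scheme(8, 6, 4, Inf, c(0, 0, 0, 0, 0, 2))
  js <- replicate(100, rgphc(sch_inf, function(u) qchen(u, 0.009, 0.2922))$j_star)
  expect_true(all(js == 6L))
  # fixed seed reproduces the sample exactly
  a <- rgphc(sch, function(u) qgompertz(u, 0.0061, 0.009), seed = 7)
  b <- rgphc(sch, function(u) qgompertz(u, 0.0061, 0.009), seed = 7)
  expect_identical(a$times, b$times)
})

test_that("spacings construction matches explicit survivor withdrawal", {
  # distributional check of the quantile-spacings simulator against a
  # brute-force simulator that withdraws survivors one by one
  sch <- gphc_scheme(8, 6, 4, Inf, c(0, 2, 0, 0, 0, 0))
  set.seed(101)
  n_rep <- 3000
  first_q <- last_q <- first_b <- last_b <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    q <- rprogressive(sch, function(u) qexp(u))
    b <- brute_progressive(8, c(0, 2, 0, 0, 0, 0), rexp)
    first_q[i] <- q[1]; last_q[i] <- q[6]
    first_b[i] <- b[1]; last_b[i] <- b[6]
  }
  expect_gt(suppressWarnings(ks.test(first_q, first_b))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(last_q, last_b))$p.value, 0.01)
  # with no early removals the first failure is the minimum of n i.i.d.
  # draws: mean within 3 standard errors of 1/n for Exp(1)
  sch2 <- gphc_scheme(6, 5, 3, Inf, c(0, 0, 0, 0, 1))
  set.seed(102)
  firsts <- replicate(1e4, rprogressive(sch2, qexp)[1])
  expect_lt(abs(mean(firsts) - 1 / 6), 3 * sd(firsts) / sqrt(1e4))
})

test_that("generalized spacings of simulated samples are standard exponential", {
  # the at-risk-scaled gaps must be i.i.d. Exp(1); this pins down the
  # 1/n normalization of the first spacing
  sch <- gphc_scheme(10, 5, 3, Inf, c(0, 0, 0, 0, 5))
  set.seed(103)
  sp <- replicate(4000, {
    q <- rprogressive(sch, qexp)
    at_risk <- 10 - cumsum(c(0, sch$removals[-5])) - seq_len(5) + 1
    at_risk * diff(c(0, q))
  })
  expect_gt(suppressWarnings(ks.test(as.numeric(sp), pexp))$p.value, 0.01)
})

test_that("GPHC log-likelihood matches a direct product oracle", {
  logpdf <- function(x) dgompertz(x, 0.0061, 0.009, log = TRUE)
  cdf <- function(x) pgompertz(x, 0.0061, 0.009)
  pdf <- function(x) dgompertz(x, 0.0061, 0.009)
  # censored 4-point sample with terminal removals
  s <- gphc_sample(c(12, 40, 95, 130), removals = c(1, 0, 2, 0),
                   t_star = 150, terminal_removals = 3, case = "II")
  expect_equal(exp(gphc_loglik(s, logpdf, cdf)),
               brute_gphc_lik(s, pdf, cdf), tolerance = 1e-12)
  # complete sample: all censoring terms vanish
  sc <- gphc_sample(c(5, 17, 60))
  expect_equal(gphc_loglik(sc, logpdf, cdf), sum(logpdf(c(5, 17, 60))))
  # degenerate single observation
  s1 <- gphc_sample(7)
  expect_equal(gphc_loglik(s1, logpdf, cdf), logpdf(7))
  # cdf hitting 1 at an observed point signals -Inf rather than erroring
  s2 <- gphc_sample(c(1, 2), removals = c(1, 1))
  expect_identical(gphc_loglik(s2, function(x) rep(0, length(x)),
                               function(x) rep(1, length(x))), -Inf)
})
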