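# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: the progressive-censoring oracle
# withdraws survivors explicitly, the likelihood oracle multiplies the
# censored-sample factors term by term, and the HPD oracle enumerates
# every candidate window.

# explicit-withdrawal simulation of a progressively censored sample:
# draw n i.i.d. lifetimes, observe the smallest survivor, withdraw
# removals[i] random survivors, repeat
brute_progressive <- function(n, removals, rdist) {
  pool <- rdist(n)
  m <- length(removals)
  obs <- numeric(m)
  for (i in seq_len(m)) {
    k <- which.min(pool)
    obs[i] <- pool[k]
    pool <- pool[-k]
    if (removals[i] > 0)
      pool <- pool[-sample.int(length(pool), removals[i])]
  }
  obs
}

# direct product evaluation of the GPHC likelihood
brute_gphc_lik <- function(sample, pdf, cdf) {
  x <- sample$times
  prod(pdf(x) * (1 - cdf(x))^sample$removals) *
    (1 - cdf(sample$t_star))^sample$terminal_removals
}

# exhaustive shortest window containing ceiling(level * n) sorted draws
brute_hpd <- function(draws, level) {
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(level * n)
  best <- c(Inf, NA, NA)
  for (i in seq_len(n - k + 1)) {
    w <- x[i + k - 1] - x[i]
    if (w < best[1]) best <- c(w, x[i], x[i + k - 1])
  }
  best[2:3]
}

# dense-grid sup-distance between the ECDF and a fitted CDF
brute_ks <- function(x, cdf) {
  n <- length(x)
  xs <- sort(x)
  Fv <- cdf(xs)
  max(abs(seq_len(n) / n - Fv), abs((seq_len(n) - 1) / n - Fv))
}

# Simpson normalization of an unnormalized log-density on a uniform grid
simpson_normalize <- function(grid, logf) {
  lv <- logf - max(logf)
  fv <- exp(lv)
  h <- grid[2] - grid[1]
  w <- c(1, rep(c(4, 2), length.out = length(grid) - 2), 1)
  if (length(grid) %% 2 == 0) w[length(w)] <- 1  # guard; use odd grids
  fv / (sum(w * fv) * h / 3)
}

# study truth used throughout the simulation-based tests
sim_truth <- function() mss_params(0.0061, 0.009, 0.009, 0.2922)

# fixed case-III (time-unbounded) designs with the simulation-study sizes:
# the number of observed failures is then constant across replicates,
# which the pivot-distribution and exact-coverage checks require
scheme_strength_8 <- function() gphc_scheme(8, 6, 4, Inf, c(0, 0, 0, 0, 0, 2))
scheme_stress_10 <- function() gphc_scheme(10, 5, 3, Inf, c(0, 0, 0, 0, 5))
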