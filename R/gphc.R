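#' Generalized progressive hybrid censoring scheme
#'
#' A GPHC life test on \code{n} units observes at most \code{m} failures,
#' requires at least \code{c} of them, and is bounded by a time limit
#' \code{t_max}.  At the i-th observed failure, \code{removals[i]} of the
#' surviving units are withdrawn.  The test ends at
#' \eqn{T^* = \max\{X_{c:m:n}, \min\{X_{m:m:n}, T\}\}}, which resolves into
#' three cases: the time limit cuts in before the guaranteed \code{c}-th
#' failure (case I), between the \code{c}-th and \code{m}-th (case II), or
#' never (case III, ordinary progressive type-II censoring).
#'
#' @param n number of units on test.
#' @param m maximum number of observed failures; \code{c < m < n}.
#' @param c minimum number of observed failures.
#' @param t_max time limit of the experiment; \code{Inf} gives progressive
#'   type-II censoring (case III always).
#' @param removals integer vector of length \code{m} of planned withdrawals;
#'   must satisfy \code{sum(removals) + m == n}.
#' @return an object of class \code{"gphc_scheme"}.
#' @examples
#' gphc_scheme(n = 8, m = 6, c = 4, t_max = 500, removals = c(0, 0, 0, 0, 0, 2))
#' @export
gphc_scheme <- function(n, m, c, t_max = Inf, removals) {
  stopifnot(length(n) == 1L, length(m) == 1L, length(c) == 1L,
            length(t_max) == 1L)
  n <- as.integer(n); m <- as.integer(m); c <- as.integer(c)
  if (!(c < m)) stop("scheme constraint violated: c < m (got c = ", c,
                     ", m = ", m, ")")
  if (!(m < n)) stop("scheme constraint violated: m < n (got m = ", m,
                     ", n = ", n, ")")
  if (c < 1L) stop("scheme constraint violated: c >= 1")
  removals <- as.integer(removals)
  if (length(removals) != m)
    stop("scheme constraint violated: length(removals) == m")
  if (any(removals < 0))
    stop("scheme constraint violated: removals >= 0")
  if (sum(removals) + m != n)
    stop("scheme constraint violated: sum(removals) + m == n (got sum = ",
         sum(removals) + m, ", n = ", n, ")")
  if (!(is.numeric(t_max) && (t_max > 0)))
    stop("scheme constraint violated: t_max > 0")
  structure(list(n = n, m = m, c = c, t_max = t_max, removals = removals),
            class = "gphc_scheme")
}

#' @export
print.gphc_scheme <- function(x, ...) {
  cat(sprintf("GPHC scheme: n = %d, m = %d, c = %d, T = %g\n",
              x$n, x$m, x$c, x$t_max))
  cat("  removals:", paste(x$removals, collapse = " "), "\n")
  invisible(x)
}

#' Simulate progressively censored order statistics
#'
#' Draws the \code{m} progressively type-II censored order statistics of a
#' scheme by the uniform-spacings construction: standard exponential
#' spacings \eqn{Z_i} are rescaled by the number of units still on test,
#' \eqn{Q_1 = Z_1/n}, \eqn{Q_i = Q_{i-1} + Z_i/(n - \sum_{j<i} R_j - i + 1)},
#' mapped to uniforms \eqn{W_i = 1 - e^{-Q_i}} and through the target
#' quantile function.  No explicit survivor bookkeeping is needed; the
#' construction is exact.
#'
#' @param scheme a [gphc_scheme()].
#' @param quantile_fn quantile function of the lifetime law, taking a
#'   probability vector.
#' @return increasing numeric vector of length \code{scheme$m}.
#' @export
rprogressive <- function(scheme, quantile_fn) {
  stopifnot(inherits(scheme, "gphc_scheme"))
  m <- scheme$m; n <- scheme$n; R <- scheme$removals
  z <- stats::rexp(m)
  on_test <- n - cumsum(c(0L, R[-m])) - seq_len(m) + 1L  # units at risk
  q <- cumsum(z / on_test)
  w <- -expm1(-q)
  x <- quantile_fn(w)
  if (any(diff(x) < 0)) stop("quantile_fn produced non-increasing values")
  x
}

#' Apply GPHC termination to a progressive sample
#'
#' Classifies a full progressive sample of length \code{m} into GPHC case
#' I/II/III, truncates it at the realized end of the experiment, and
#' records the number of units removed en bloc at termination.
#'
#' @param times strictly increasing numeric vector of length \code{scheme$m}.
#' @param scheme a [gphc_scheme()].
#' @param ties \code{"error"} rejects tied times (a zero-probability event
#'   under a continuous law, so a tie signals a data problem in simulated
#'   samples); \code{"allow"} accepts them, as needed when replaying a
#'   design on recorded data rounded to a coarse grid.
#' @return an object of class \code{"gphc_sample"} with elements
#'   \code{times} (the \eqn{J^*} observed failures), \code{case},
#'   \code{j_star}, \code{t_star}, \code{terminal_removals},
#'   \code{removals} (the per-failure withdrawals actually applied),
#'   \code{n}, and \code{scheme}.
#' @export
gphc_termination <- function(times, scheme, ties = c("error", "allow")) {
  stopifnot(inherits(scheme, "gphc_scheme"))
  ties <- match.arg(ties)
  m <- scheme$m; n <- scheme$n; c <- scheme$c
  T <- scheme$t_max; R <- scheme$removals
  if (length(times) != m) stop("'times' must have length m")
  if (ties == "error" && any(duplicated(times)))
    stop("tied failure times: zero-probability event under a continuous law")
  if (is.unsorted(times)) stop("'times' must be increasing")
  if (T < times[c]) {                      # case I: stop at the c-th failure
    j <- c
    out <- gphc_sample(times[seq_len(j)], R[seq_len(j)],
                       t_star = times[j],
                       terminal_removals = n - sum(R[seq_len(j)]) - j,
                       case = "I", scheme = scheme)
  } else if (T < times[m]) {               # case II: stop at the time limit
    j <- sum(times < T)
    out <- gphc_sample(times[seq_len(j)], R[seq_len(j)],
                       t_star = T,
                       terminal_removals = n - sum(R[seq_len(j)]) - j,
                       case = "II", scheme = scheme)
  } else {                                 # case III: all m failures observed
    out <- gphc_sample(times, R, t_star = times[m],
                       terminal_removals = 0L, case = "III", scheme = scheme)
  }
  out
}

#' Construct a GPHC sample object
#'
#' Low-level constructor for an observed GPHC sample.  \code{n} is implied
#' by the accounting identity
#' \code{n = j_star + sum(removals) + terminal_removals}.
#'
#' @param times increasing vector of observed failure times.
#' @param removals withdrawals applied at each observed failure (same
#'   length as \code{times}).
#' @param t_star realized end time of the experiment.
#' @param terminal_removals units removed en bloc at \code{t_star}.
#' @param case one of \code{"I"}, \code{"II"}, \code{"III"}.
#' @param scheme the generating [gphc_scheme()], or \code{NULL} for data
#'   not tied to a designed experiment (e.g. complete samples).
#' @return an object of class \code{"gphc_sample"}.
#' @export
gphc_sample <- function(times, removals = rep(0L, length(times)),
                        t_star = max(times), terminal_removals = 0L,
                        case = "III", scheme = NULL) {
  stopifnot(length(times) >= 1L, all(times > 0),
            length(removals) == length(times), all(removals >= 0),
            terminal_removals >= 0, t_star >= max(times))
  if (is.unsorted(times)) stop("'times' must be non-decreasing")
  case <- match.arg(case, c("I", "II", "III"))
  if (case == "III" && terminal_removals != 0L)
    stop("case III has no terminal removals")
  structure(list(times = as.numeric(times),
                 removals = as.integer(removals),
                 j_star = length(times),
                 t_star = as.numeric(t_star),
                 terminal_removals = as.integer(terminal_removals),
                 case = case,
                 n = length(times) + sum(removals) + as.integer(terminal_removals),
                 scheme = scheme),
            class = "gphc_sample")
}

#' @export
print.gphc_sample <- function(x, ...) {
  cat(sprintf("GPHC sample (case %s): J* = %d of n = %d, T* = %g\n",
              x$case, x$j_star, x$n, x$t_star))
  cat("  times:", paste(signif(x$times, 6), collapse = " "), "\n")
  cat("  removals:", paste(x$removals, collapse = " "),
      "| terminal:", x$terminal_removals, "\n")
  invisible(x)
}

#' Simulate a GPHC sample
#'
#' Simulates the full progressive sample with [rprogressive()] and applies
#' the case-I/II/III termination rule.
#'
#' @param scheme a [gphc_scheme()].
#' @param quantile_fn quantile function of the lifetime law.
#' @param seed optional integer seed for reproducibility.
#' @return a \code{"gphc_sample"}.
#' @export
rgphc <- function(scheme, quantile_fn, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gphc_termination(rprogressive(scheme, quantile_fn), scheme)
}

#' GPHC log-likelihood for an arbitrary lifetime law
#'
#' Evaluates \eqn{\sum_{i \le J^*} [\log f(x_i) + R_i \log S(x_i)]
#' + R_{J^*}^{**} \log S(T^*)} for the observed sample, where \eqn{S = 1-F}.
#' A distribution function reaching 1 at an observed point yields
#' \code{-Inf} (a signal, not an error).
#'
#' @param sample a \code{"gphc_sample"}.
#' @param logpdf,cdf vectorized density (log scale) and distribution
#'   functions of the lifetime law.
#' @return scalar log-likelihood.
#' @export
gphc_loglik <- function(sample, logpdf, cdf) {
  stopifnot(inherits(sample, "gphc_sample"))
  x <- sample$times
  lsf <- log1p(-cdf(x))
  ll <- sum(logpdf(x) + sample$removals * lsf)
  if (sample$terminal_removals > 0)
    ll <- ll + sample$terminal_removals * log1p(-cdf(sample$t_star))
  ll
}
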