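#' Pivotal quantities of the stress sample
#'
#' For the ordered stress sample \eqn{Y_1 < \dots < Y_{M^*}} the
#' transforms \eqn{V_j = \theta(e^{Y_j^\beta} - 1)} are progressively
#' censored standard-exponential order statistics, so their generalized
#' spacings are i.i.d. Exp(1).  Two functions of them are parameter-free
#' pivots:
#' \deqn{B_1 = \frac{\sum_j (S_j+1)(V_j - V_1)}{n_2(M^*-1)V_1}
#'   \sim F(2M^*-2,\, 2), \qquad
#'   B_2 = 2\sum_j (S_j+1) V_j \sim \chi^2(2M^*),}
#' and \eqn{B_1} does not involve \eqn{\theta}.  \eqn{B_1} is strictly
#' increasing in \eqn{\beta}, which is what makes exact interval
#' inversion possible.
#'
#' @param beta,theta Chen parameter values at which to evaluate.
#' @param data an [mss_data()] object with at least two observed stresses.
#' @return named numeric vector \code{c(b1, b2)}.
#' @export
stress_pivots <- function(beta, theta, data) {
  stopifnot(inherits(data, "mss_data"))
  sy <- stress_stats(data)
  if (sy$m_star < 2) stop("b1 undefined for M* < 2")
  if (any(duplicated(sy$y)))
    stop("tied stress values: strict ordering required")
  n2 <- data$stress$n
  V <- expm1(sy$y^beta)
  b1 <- (sum(sy$w * V) - n2 * V[1]) / (n2 * (sy$m_star - 1) * V[1])
  b2 <- 2 * theta * sum(sy$w * V)
  c(b1 = b1, b2 = b2)
}

#' Pivotal quantities of the strength sample
#'
#' Analogue of [stress_pivots()] for the component strengths: with
#' \eqn{U_{it} = (\alpha/\eta)(e^{\eta x_{it}} - 1)},
#' \deqn{T_1 = \frac{\sum_i\sum_t (R_t+1)(e^{\eta x_{it}}-1)}
#'   {n_1(J^*-1)\sum_i (e^{\eta x_{i1}}-1)} - \frac{1}{J^*-1}
#'   \sim F(2M^*(J^*-1),\, 2M^*), \qquad
#'   T_2 = 2\sum_i\sum_t (R_t+1) U_{it} \sim \chi^2(2M^* J^*),}
#' with \eqn{T_1} free of \eqn{\alpha} and strictly increasing in
#' \eqn{\eta}.  Requires the common-design assumption (equal \eqn{J^*}
#' across systems, at least 2).
#'
#' @param eta,alpha Gompertz parameter values at which to evaluate.
#' @param data an [mss_data()] object.
#' @return named numeric vector \code{c(t1, t2)}.
#' @export
strength_pivots <- function(eta, alpha, data) {
  stopifnot(inherits(data, "mss_data"))
  X <- strength_matrix(data)               # errors if J* differs
  J <- ncol(X)
  if (J < 2) stop("t1 undefined for J* < 2")
  n1 <- data$strength[[1]]$n
  w <- data$strength[[1]]$removals + 1
  U <- expm1(eta * X)
  num <- sum(sweep(U, 2, w, `*`))
  t1 <- num / (n1 * (J - 1) * sum(U[, 1])) - 1 / (J - 1)
  t2 <- 2 * (alpha / eta) * num
  c(t1 = t1, t2 = t2)
}

# bracket-expansion + uniroot solver for a strictly increasing pivot map
solve_pivot_root <- function(pivot_fn, w, feasibility_bound,
                             lower = 1e-8, max_doublings = 200L) {
  if (w <= feasibility_bound)
    stop("no positive root: target ", signif(w, 6),
         " is at or below the zero-parameter limit ",
         signif(feasibility_bound, 6))
  # overflow of e^(eta x) (or e^(y^beta)) far above the root evaluates
  # the monotone pivot as Inf/Inf; treat that as "past the root"
  safe <- function(p) {
    v <- pivot_fn(p)
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  lo <- lower
  while (safe(lo) > w) {
    lo <- lo / 4
    if (lo < 1e-300) stop("failed to bracket root from below")
  }
  hi <- max(lo * 2, 1)
  k <- 0L
  while (safe(hi) < w) {
    hi <- hi * 2
    k <- k + 1L
    if (k > max_doublings) stop("failed to bracket root from above")
  }
  stats::uniroot(function(p) safe(p) - w, c(lo, hi),
                 tol = .Machine$double.eps^0.75)$root
}

# beta -> 0+ limit of B1: V_j = e^{y_j^beta} - 1 -> (e-1) + e*beta*log(y_j),
# so numerator and denominator both stay positive and B1 -> 0; every
# positive target (every F quantile) therefore has a unique root
stress_b1_limit <- function(data) 0

# eta -> 0+ limit of T1: e^{eta x} - 1 -> eta x, giving a strictly
# positive floor below which T1(eta) = w has no positive root
strength_t1_limit <- function(data) {
  X <- strength_matrix(data)
  J <- ncol(X)
  n1 <- data$strength[[1]]$n
  w <- data$strength[[1]]$removals + 1
  sum(sweep(X, 2, w, `*`)) / (n1 * (J - 1) * sum(X[, 1])) - 1 / (J - 1)
}

#' Exact confidence interval for the Chen shape beta
#'
#' Inverts the pivot \eqn{B_1(\beta) \sim F(2M^*-2, 2)}: the interval
#' endpoints are the (unique) roots of \eqn{B_1(\beta) = w} at the upper
#' \eqn{1-\tau/2} and \eqn{\tau/2} F percentiles.  If a percentile falls
#' below the \eqn{\beta \to 0} limit of the pivot no positive root
#' exists and the corresponding endpoint is reported as 0 with attribute
#' \code{"one_sided"}.
#'
#' @param data an [mss_data()] object.
#' @param level nominal coverage \eqn{1-\tau}.
#' @return an \code{"mss_interval"}.
#' @export
eci_beta <- function(data, level = 0.95) {
  tau <- 1 - level
  m <- data$stress$j_star
  q <- stats::qf(c(tau / 2, 1 - tau / 2), 2 * m - 2, 2)  # lower-tail quantiles
  lim <- stress_b1_limit(data)
  root <- function(w) {
    if (w <= lim) return(NA_real_)
    solve_pivot_root(function(b) stress_pivots(b, 1, data)[["b1"]], w, lim)
  }
  lo <- root(q[1]); hi <- root(q[2])
  one_sided <- is.na(lo) || is.na(hi)
  out <- interval_estimate(if (is.na(lo)) 0 else lo,
                           if (is.na(hi)) 0 else hi, level, "ECI")
  attr(out, "one_sided") <- one_sided
  out
}

#' Exact confidence interval for the Gompertz scale eta
#'
#' Inverts \eqn{T_1(\eta) \sim F(2M^*(J^*-1), 2M^*)} exactly as
#' [eci_beta()] inverts \eqn{B_1}.
#'
#' @inheritParams eci_beta
#' @return an \code{"mss_interval"}.
#' @export
eci_eta <- function(data, level = 0.95) {
  tau <- 1 - level
  X <- strength_matrix(data)
  m <- nrow(X); J <- ncol(X)
  q <- stats::qf(c(tau / 2, 1 - tau / 2), 2 * m * (J - 1), 2 * m)
  lim <- strength_t1_limit(data)
  root <- function(w) {
    if (w <= lim) return(NA_real_)
    solve_pivot_root(function(e) strength_pivots(e, 1, data)[["t1"]], w, lim)
  }
  lo <- root(q[1]); hi <- root(q[2])
  one_sided <- is.na(lo) || is.na(hi)
  out <- interval_estimate(if (is.na(lo)) 0 else lo,
                           if (is.na(hi)) 0 else hi, level, "ECI")
  attr(out, "one_sided") <- one_sided
  out
}

#' Joint exact confidence region for (beta, theta)
#'
#' Splits the joint level between the two independent pivots
#' (\eqn{\sqrt{1-\tau}} each, via \eqn{\tau_1 = (1+\sqrt{1-\tau})/2},
#' \eqn{\tau_2 = (1-\sqrt{1-\tau})/2}): the \eqn{\beta} range comes from
#' \eqn{B_1} and, for each \eqn{\beta}, the \eqn{\theta} range from
#' \eqn{B_2 \sim \chi^2(2M^*)}.  The region is not a rectangle; this
#' function reports the conservative bounding rectangle obtained by
#' extremizing the \eqn{\theta} bounds over the \eqn{\beta} endpoints,
#' and also returns the exact region as a membership predicate.
#'
#' @inheritParams eci_beta
#' @return list with elements \code{beta}, \code{theta} (both
#'   \code{"mss_interval"}) and \code{contains(beta, theta)}.
#' @export
joint_eci_beta_theta <- function(data, level = 0.95) {
  tau <- 1 - level
  tau1 <- (1 + sqrt(1 - tau)) / 2
  tau2 <- (1 - sqrt(1 - tau)) / 2
  m <- data$stress$j_star
  sy <- stress_stats(data)
  # upper-tail percentiles as in the pivot construction
  qF <- stats::qf(c(tau1, tau2), 2 * m - 2, 2, lower.tail = FALSE)
  lim <- stress_b1_limit(data)
  root <- function(w) {
    if (w <= lim) return(NA_real_)
    solve_pivot_root(function(b) stress_pivots(b, 1, data)[["b1"]], w, lim)
  }
  b_lo <- root(qF[1]); b_hi <- root(qF[2])
  qC <- stats::qchisq(c(tau1, tau2), 2 * m, lower.tail = FALSE)
  denom <- function(b) 2 * sum(sy$w * expm1(sy$y^b))
  theta_bounds <- function(b) c(qC[1], qC[2]) / denom(b)
  ends <- c(b_lo, b_hi); ends <- ends[!is.na(ends)]
  tb <- vapply(ends, theta_bounds, numeric(2))
  th_lo <- min(tb[1, ]); th_hi <- max(tb[2, ])
  contains <- function(beta, theta) {
    b1 <- stress_pivots(beta, theta, data)
    b1[["b1"]] >= qF[1] && b1[["b1"]] <= qF[2] &&
      b1[["b2"]] >= qC[1] && b1[["b2"]] <= qC[2]
  }
  list(beta = interval_estimate(if (is.na(b_lo)) 0 else b_lo,
                                if (is.na(b_hi)) 0 else b_hi, level, "ECI"),
       theta = interval_estimate(th_lo, th_hi, level, "ECI"),
       contains = contains)
}

#' Joint exact confidence region for (eta, alpha)
#'
#' Strength-side analogue of [joint_eci_beta_theta()]: \eqn{\eta} from
#' \eqn{T_1} at the split levels, then
#' \eqn{\alpha \in \eta\,\chi^2(2M^*J^*)\text{-band} /
#' (2\sum\sum (R_t+1)(e^{\eta x_{it}}-1))} extremized over the \eqn{\eta}
#' endpoints.
#'
#' @inheritParams eci_beta
#' @return list with elements \code{eta}, \code{alpha}, \code{contains}.
#' @export
joint_eci_eta_alpha <- function(data, level = 0.95) {
  tau <- 1 - level
  tau1 <- (1 + sqrt(1 - tau)) / 2
  tau2 <- (1 - sqrt(1 - tau)) / 2
  X <- strength_matrix(data)
  m <- nrow(X); J <- ncol(X)
  n1 <- data$strength[[1]]$n
  w <- data$strength[[1]]$removals + 1
  qF <- stats::qf(c(tau1, tau2), 2 * m * (J - 1), 2 * m, lower.tail = FALSE)
  lim <- strength_t1_limit(data)
  root <- function(q) {
    if (q <= lim) return(NA_real_)
    solve_pivot_root(function(e) strength_pivots(e, 1, data)[["t1"]], q, lim)
  }
  e_lo <- root(qF[1]); e_hi <- root(qF[2])
  qC <- stats::qchisq(c(tau1, tau2), 2 * m * J, lower.tail = FALSE)
  alpha_bounds <- function(e) {
    denom <- 2 * sum(sweep(expm1(e * X), 2, w, `*`))
    e * c(qC[1], qC[2]) / denom
  }
  ends <- c(e_lo, e_hi); ends <- ends[!is.na(ends)]
  ab <- vapply(ends, alpha_bounds, numeric(2))
  a_lo <- min(ab[1, ]); a_hi <- max(ab[2, ])
  contains <- function(eta, alpha) {
    tv <- strength_pivots(eta, alpha, data)
    tv[["t1"]] >= qF[1] && tv[["t1"]] <= qF[2] &&
      tv[["t2"]] >= qC[1] && tv[["t2"]] <= qC[2]
  }
  list(eta = interval_estimate(if (is.na(e_lo)) 0 else e_lo,
                               if (is.na(e_hi)) 0 else e_hi, level, "ECI"),
       alpha = interval_estimate(a_lo, a_hi, level, "ECI"),
       contains = contains)
}
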