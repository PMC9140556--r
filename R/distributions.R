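#' The Gompertz distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Gompertz distribution with shape \code{alpha} and scale
#' \code{eta}.  The distribution function is
#' \deqn{G(x) = 1 - \exp\{-(\alpha/\eta)(e^{\eta x} - 1)\}, \quad x \ge 0,}
#' so that \code{eta -> 0} recovers the exponential law with rate
#' \code{alpha}.  All evaluations use \code{expm1()}/\code{log1p()} so the
#' functions remain accurate for scale parameters as small as 1e-9 and
#' lifetimes in the thousands, the regime met in reservoir-storage data.
#'
#' @param x,q vector of non-negative quantiles.
#' @param p vector of probabilities in \code{[0, 1)}.
#' @param n number of draws.
#' @param alpha shape parameter, positive.
#' @param eta scale parameter, positive.
#' @param log,log.p logical; if \code{TRUE}, probabilities/densities are
#'   returned on the log scale.
#' @param lower.tail logical; if \code{TRUE} (default), probabilities are
#'   \eqn{P(X \le x)}.
#' @return a numeric vector.
#' @examples
#' pgompertz(1, alpha = 0.5, eta = 1e-12)  # ~ 1 - exp(-0.5)
#' qgompertz(pgompertz(2, 1, 1), 1, 1)     # 2
#' @name gompertz
NULL

check_gompertz <- function(alpha, eta) {
  stopifnot(is.numeric(alpha), is.numeric(eta), length(alpha) == 1L,
            length(eta) == 1L, is.finite(alpha), is.finite(eta))
  if (alpha <= 0) stop("'alpha' must be positive")
  if (eta <= 0) stop("'eta' must be positive")
  invisible(NULL)
}

check_chen <- function(theta, beta) {
  stopifnot(is.numeric(theta), is.numeric(beta), length(theta) == 1L,
            length(beta) == 1L, is.finite(theta), is.finite(beta))
  if (theta <= 0) stop("'theta' must be positive")
  if (beta <= 0) stop("'beta' must be positive")
  invisible(NULL)
}

# cumulative hazard (alpha/eta) * (exp(eta*x) - 1), stable for small eta*x
gompertz_chaz <- function(x, alpha, eta) (alpha / eta) * expm1(eta * x)

#' @rdname gompertz
#' @export
pgompertz <- function(q, alpha, eta, lower.tail = TRUE, log.p = FALSE) {
  check_gompertz(alpha, eta)
  if (any(!is.finite(q) & !is.infinite(q)) || any(q < 0, na.rm = FALSE))
    stop("'q' must be finite and non-negative (or +Inf)")
  lsf <- -gompertz_chaz(q, alpha, eta)          # log survival
  if (lower.tail) {
    if (log.p) log(-expm1(lsf)) else -expm1(lsf)
  } else {
    if (log.p) lsf else exp(lsf)
  }
}

#' @rdname gompertz
#' @export
qgompertz <- function(p, alpha, eta) {
  check_gompertz(alpha, eta)
  if (any(p < 0 | p >= 1)) stop("'p' must lie in [0, 1)")
  log1p(-(eta / alpha) * log1p(-p)) / eta
}

#' @rdname gompertz
#' @export
dgompertz <- function(x, alpha, eta, log = FALSE) {
  check_gompertz(alpha, eta)
  if (any(x <= 0)) stop("'x' must be positive")
  ld <- log(alpha) + eta * x - gompertz_chaz(x, alpha, eta)
  if (log) ld else exp(ld)
}

#' @rdname gompertz
#' @export
rgompertz <- function(n, alpha, eta) qgompertz(stats::runif(n), alpha, eta)

#' The Chen distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Chen lifetime distribution with shape parameters \code{theta}
#' and \code{beta}, whose distribution function is
#' \deqn{F(y) = 1 - \exp\{\theta(1 - e^{y^\beta})\}, \quad y \ge 0.}
#' The hazard is bathtub-shaped for \code{beta < 1}; \code{theta = 1}
#' recovers the exponential power distribution.  The survival exponent is
#' computed as \code{-theta * expm1(y^beta)} so that large lifetimes with
#' small \code{beta} (e.g. y = 2000, beta = 0.29) do not overflow.
#'
#' @param y,q vector of non-negative quantiles.
#' @param p vector of probabilities in \code{[0, 1)}.
#' @param n number of draws.
#' @param theta,beta shape parameters, positive.
#' @param log,log.p logical; return log densities/probabilities.
#' @param lower.tail logical; if \code{TRUE} (default), \eqn{P(Y \le y)}.
#' @return a numeric vector.
#' @examples
#' pchen(1, theta = 1, beta = 1)  # 1 - exp(1 - e)
#' @name chen
NULL

#' @rdname chen
#' @export
pchen <- function(q, theta, beta, lower.tail = TRUE, log.p = FALSE) {
  check_chen(theta, beta)
  if (any(q < 0)) stop("'q' must be non-negative")
  lsf <- -theta * expm1(q^beta)
  if (lower.tail) {
    if (log.p) log(-expm1(lsf)) else -expm1(lsf)
  } else {
    if (log.p) lsf else exp(lsf)
  }
}

#' @rdname chen
#' @export
qchen <- function(p, theta, beta) {
  check_chen(theta, beta)
  if (any(p < 0 | p >= 1)) stop("'p' must lie in [0, 1)")
  log1p(-log1p(-p) / theta)^(1 / beta)
}

#' @rdname chen
#' @export
dchen <- function(y, theta, beta, log = FALSE) {
  check_chen(theta, beta)
  if (any(y <= 0)) stop("'y' must be positive")
  yb <- y^beta
  ld <- log(theta) + log(beta) + (beta - 1) * log(y) - theta * expm1(yb) + yb
  if (log) ld else exp(ld)
}

#' @rdname chen
#' @export
rchen <- function(n, theta, beta) qchen(stats::runif(n), theta, beta)

#' Model parameter bundle for the stress-strength pair
#'
#' Convenience container holding the Gompertz strength parameters and Chen
#' stress parameters used throughout the package.
#'
#' @param alpha,eta Gompertz strength shape and scale, positive.
#' @param theta,beta Chen stress shapes, positive.
#' @return a named list of class \code{"mss_params"}.
#' @export
mss_params <- function(alpha, eta, theta, beta) {
  check_gompertz(alpha, eta)
  check_chen(theta, beta)
  structure(list(alpha = alpha, eta = eta, theta = theta, beta = beta),
            class = "mss_params")
}

#' @export
print.mss_params <- function(x, ...) {
  cat("Stress-strength model parameters\n")
  cat(sprintf("  strength ~ Gompertz(alpha = %g, eta = %g)\n", x$alpha, x$eta))
  cat(sprintf("  stress   ~ Chen(theta = %g, beta = %g)\n", x$theta, x$beta))
  invisible(x)
}
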