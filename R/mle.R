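#' Joint MSS-GPHC log-likelihood
#'
#' Log-likelihood of the four model parameters given an [mss_data()]
#' object.  The strength side contributes, for every system \eqn{i} and
#' observed component failure \eqn{x_{it}},
#' \eqn{\log\alpha + \eta x_{it} - (\alpha/\eta)(e^{\eta x_{it}}-1)(R_t+1)}
#' plus one terminal-censoring term
#' \eqn{-(\alpha/\eta)(e^{\eta T^*_i}-1)R^{**}_i} per system; the stress
#' side contributes
#' \eqn{\log(\theta\beta) + (\beta-1)\log y_i + y_i^\beta +
#' \theta(1-e^{y_i^\beta})(S_i+1)} per observed stress plus the single
#' terminal term \eqn{\theta S^{**}(1-e^{B^{*\beta}})}.  The two sides
#' share no parameters, so the likelihood factorizes over
#' \eqn{(\alpha,\eta)} and \eqn{(\theta,\beta)}.
#'
#' @param params an [mss_params()] object (or a named list with elements
#'   \code{alpha}, \code{eta}, \code{theta}, \code{beta}).
#' @param data an [mss_data()] object.
#' @return scalar log-likelihood (possibly \code{-Inf}).
#' @export
mss_loglik <- function(params, data) {
  stopifnot(inherits(data, "mss_data"))
  st <- strength_stats(data)
  sy <- stress_stats(data)
  strength_loglik(params$alpha, params$eta, st) +
    stress_loglik(params$theta, params$beta, sy)
}

# ---- sufficient pieces ----------------------------------------------------

strength_stats <- function(data) {
  xs <- lapply(data$strength, function(s) s$times)
  ws <- lapply(data$strength, function(s) s$removals + 1)   # R_t + 1
  list(x = unlist(xs), w = unlist(ws),
       t_star = vapply(data$strength, function(s) s$t_star, 1),
       r_term = vapply(data$strength, function(s) s$terminal_removals, 1L),
       n_obs = length(unlist(xs)),
       sum_x = sum(unlist(xs)))
}

stress_stats <- function(data) {
  s <- data$stress
  list(y = s$times, w = s$removals + 1, b_star = s$t_star,
       s_term = s$terminal_removals, m_star = s$j_star,
       sum_logy = sum(log(s$times)))
}

# K(eta) and derivatives: weighted sums of expm1(eta * x) over observed
# times plus per-system terminal terms
strength_K <- function(eta, st, order = 0L) {
  ex <- exp(eta * st$x); et <- exp(eta * st$t_star)
  K <- sum(st$w * (ex - 1)) + sum(st$r_term * (et - 1))
  if (order == 0L) return(K)
  K1 <- sum(st$w * st$x * ex) + sum(st$r_term * st$t_star * et)
  if (order == 1L) return(c(K, K1))
  K2 <- sum(st$w * st$x^2 * ex) + sum(st$r_term * st$t_star^2 * et)
  c(K, K1, K2)
}

strength_loglik <- function(alpha, eta, st) {
  if (alpha <= 0 || eta <= 0) stop("parameters must be positive")
  if (eta * max(st$x, st$t_star) > 700) return(-Inf)
  st$n_obs * log(alpha) + eta * st$sum_x - (alpha / eta) * strength_K(eta, st)
}

# L(beta) and derivatives: weighted sums of expm1(y^beta) plus terminal term
stress_L <- function(beta, sy, order = 0L) {
  yb <- sy$y^beta; bb <- sy$b_star^beta
  if (max(yb, bb) > 700) return(rep(Inf, order + 1L))
  ey <- exp(yb); eb <- exp(bb)
  L <- sum(sy$w * (ey - 1)) + sy$s_term * (eb - 1)
  if (order == 0L) return(L)
  ly <- log(sy$y); lb <- log(sy$b_star)
  L1 <- sum(sy$w * yb * ly * ey) + sy$s_term * bb * lb * eb
  if (order == 1L) return(c(L, L1))
  L2 <- sum(sy$w * yb * ly^2 * ey * (1 + yb)) +
    sy$s_term * bb * lb^2 * eb * (1 + bb)
  c(L, L1, L2)
}

stress_loglik <- function(theta, beta, sy) {
  if (theta <= 0 || beta <= 0) stop("parameters must be positive")
  L <- stress_L(beta, sy)
  if (!is.finite(L)) return(-Inf)
  sy$m_star * log(theta * beta) + (beta - 1) * sy$sum_logy +
    sum(sy$y^beta) - theta * L
}

# analytic gradient, natural scale, order (alpha, eta, theta, beta)
mss_score <- function(params, st, sy) {
  a <- params$alpha; e <- params$eta; th <- params$theta; b <- params$beta
  K <- strength_K(e, st, order = 1L)
  ga <- st$n_obs / a - K[1] / e
  ge <- st$sum_x - a * (K[2] / e - K[1] / e^2)
  L <- stress_L(b, sy, order = 1L)
  yb <- sy$y^b; ly <- log(sy$y)
  gt <- sy$m_star / th - L[1]
  gb <- sy$m_star / b + sy$sum_logy + sum(yb * ly) - th * L[2]
  c(alpha = ga, eta = ge, theta = gt, beta = gb)
}

#' Observed Fisher information
#'
#' Negative Hessian of [mss_loglik()] at \code{params}, computed from the
#' analytic second derivatives.  The matrix is block diagonal: the
#' likelihood factorizes over the strength pair \eqn{(\alpha,\eta)} and
#' the stress pair \eqn{(\theta,\beta)}, so all cross blocks are exactly
#' zero.
#'
#' @inheritParams mss_loglik
#' @return symmetric 4 x 4 matrix with dimnames
#'   \code{c("alpha","eta","theta","beta")}.
#' @export
observed_information <- function(params, data) {
  stopifnot(inherits(data, "mss_data"))
  st <- strength_stats(data)
  sy <- stress_stats(data)
  a <- params$alpha; e <- params$eta; th <- params$theta; b <- params$beta
  K <- strength_K(e, st, order = 2L)
  h_aa <- -st$n_obs / a^2
  h_ae <- -(K[2] / e - K[1] / e^2)
  h_ee <- -a * (K[3] / e - 2 * K[2] / e^2 + 2 * K[1] / e^3)
  L <- stress_L(b, sy, order = 2L)
  yb <- sy$y^b; ly <- log(sy$y)
  h_tt <- -sy$m_star / th^2
  h_tb <- -L[2]
  h_bb <- -sy$m_star / b^2 + sum(yb * ly^2) - th * L[3]
  H <- matrix(0, 4, 4, dimnames = list(c("alpha", "eta", "theta", "beta"),
                                       c("alpha", "eta", "theta", "beta")))
  H[1, 1] <- h_aa; H[1, 2] <- H[2, 1] <- h_ae; H[2, 2] <- h_ee
  H[3, 3] <- h_tt; H[3, 4] <- H[4, 3] <- h_tb; H[4, 4] <- h_bb
  -H
}

# ---- fitting --------------------------------------------------------------

# closed-form conditional MLEs: alpha given eta, theta given beta
alpha_hat <- function(eta, st) st$n_obs * eta / strength_K(eta, st)
theta_hat <- function(beta, sy) {
  L <- stress_L(beta, sy)
  if (!is.finite(L)) return(0)
  sy$m_star / L
}

# profiles return a large negative finite value (not -Inf) on overflow
# plateaus so that optimize() does not warn while bracketing
profile_strength <- function(eta, st) {
  a <- alpha_hat(eta, st)
  if (!is.finite(a) || a <= 0) return(-.Machine$double.xmax)
  ll <- strength_loglik(a, eta, st)
  if (!is.finite(ll)) -.Machine$double.xmax else ll
}
profile_stress <- function(beta, sy) {
  th <- theta_hat(beta, sy)
  if (th <= 0) return(-.Machine$double.xmax)
  ll <- stress_loglik(th, beta, sy)
  if (!is.finite(ll)) -.Machine$double.xmax else ll
}

# damped Newton on one 2-parameter block in log space
newton_block <- function(par, fn_ll, fn_grad, fn_hess,
                         max_iter = 200L, tol_grad = 1e-10, tol_step = 1e-12) {
  u <- log(par)
  ll <- fn_ll(exp(u))
  for (it in seq_len(max_iter)) {
    p <- exp(u)
    g <- fn_grad(p)            # natural scale
    H <- fn_hess(p)
    gu <- g * p                # chain rule to log scale
    Hu <- diag(p) %*% H %*% diag(p) + diag(gu)
    step <- tryCatch(solve(Hu, -gu), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)) || sum(step * gu) < 0)
      step <- gu / max(1, sqrt(sum(gu^2)))   # fallback: scaled ascent
    if (sqrt(sum(gu^2)) < 1e-4) {
      # quadratic-convergence regime: the predicted gain is below the
      # floating-point noise of the log-likelihood, so a monotonicity
      # line search would stall; take the full Newton step
      u_new <- u + step
      ll_new <- fn_ll(exp(u_new))
      if (!is.finite(ll_new)) { u_new <- u; ll_new <- ll }
    } else {
      lambda <- 1
      repeat {
        u_new <- u + lambda * step
        ll_new <- fn_ll(exp(u_new))
        if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
        lambda <- lambda / 2
        if (lambda < 1e-12) { u_new <- u; ll_new <- ll; break }
      }
    }
    moved <- sqrt(sum((u_new - u)^2))
    u <- u_new; ll <- ll_new
    gn <- sqrt(sum((fn_grad(exp(u)) * exp(u))^2))
    if (gn < tol_grad || moved < tol_step)
      return(list(par = exp(u), loglik = ll, n_iter = it,
                  converged = gn < 1e-8, grad_norm = gn))
  }
  gn <- sqrt(sum((fn_grad(exp(u)) * exp(u))^2))
  list(par = exp(u), loglik = ll, n_iter = max_iter,
       converged = gn < 1e-8, grad_norm = gn)
}

#' Maximum-likelihood fit of the MSS-GPHC model
#'
#' Fits the Gompertz strength and Chen stress parameters jointly by
#' maximum likelihood.  Because the likelihood factorizes, each pair is
#' fitted separately: the conditionally linear parameter
#' (\eqn{\alpha} given \eqn{\eta}; \eqn{\theta} given \eqn{\beta}) is
#' profiled out in closed form and the remaining one-dimensional profile
#' is maximized by golden-section search, after which a damped Newton
#' polish in log-parameter space drives the gradient norm below 1e-8.
#' The covariance matrix is the inverse observed Fisher information.
#'
#' @param data an [mss_data()] object.
#' @param init optional [mss_params()] starting point; by default the
#'   profile construction provides its own start.
#' @param eta_range,beta_range search ranges for the profiled parameters.
#' @return an object of class \code{"mss_mle"} with components
#'   \code{coefficients}, \code{loglik}, \code{vcov}, \code{info},
#'   \code{gradient}, \code{gradient_norm}, \code{converged},
#'   \code{boundary} (\code{TRUE} when the likelihood is maximized at the
#'   \eqn{\eta \to 0} exponential boundary and \eqn{\eta} was pinned at
#'   the search floor), \code{n_iter}, and \code{data}.
#' @examples
#' fit <- mss_mle(reservoir_data())
#' coef(fit)
#' confint(fit)
#' @export
mss_mle <- function(data, init = NULL,
                    eta_range = NULL, beta_range = c(0.01, 3)) {
  stopifnot(inherits(data, "mss_data"))
  st <- strength_stats(data)
  sy <- stress_stats(data)
  if (st$n_obs < 1 || sy$m_star < 1) stop("empty dataset")

  if (is.null(eta_range)) {
    eta_hi <- 500 / max(st$x, st$t_star)
    eta_range <- c(eta_hi * 1e-9, eta_hi)
  }
  if (is.null(init)) {
    # coarse grid to localize the 1-d profile maximum (the profile can be
    # -Inf on overflow plateaus), then golden-section refinement inside
    # the bracketing grid cells
    grid_refine <- function(fn, grid) {
      vals <- vapply(grid, fn, 1)
      if (all(!is.finite(vals))) stop("profile likelihood non-finite ",
                                      "everywhere on the search grid")
      i <- which.max(vals)
      lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
      stats::optimize(fn, c(lo, hi), maximum = TRUE, tol = 1e-12)$maximum
    }
    eta_grid <- exp(seq(log(eta_range[1]), log(eta_range[2]),
                        length.out = 61))
    eta0 <- grid_refine(function(e) profile_strength(e, st), eta_grid)
    alpha0 <- alpha_hat(eta0, st)
    beta_grid <- exp(seq(log(beta_range[1]), log(beta_range[2]),
                         length.out = 61))
    beta0 <- grid_refine(function(b) profile_stress(b, sy), beta_grid)
    theta0 <- theta_hat(beta0, sy)
  } else {
    alpha0 <- init$alpha; eta0 <- init$eta
    theta0 <- init$theta; beta0 <- init$beta
  }

  fit_s <- newton_block(c(alpha0, eta0),
    fn_ll   = function(p) strength_loglik(p[1], p[2], st),
    fn_grad = function(p) {
      K <- strength_K(p[2], st, order = 1L)
      c(st$n_obs / p[1] - K[1] / p[2],
        st$sum_x - p[1] * (K[2] / p[2] - K[1] / p[2]^2))
    },
    fn_hess = function(p) {
      K <- strength_K(p[2], st, order = 2L)
      matrix(c(-st$n_obs / p[1]^2,
               -(K[2] / p[2] - K[1] / p[2]^2),
               -(K[2] / p[2] - K[1] / p[2]^2),
               -p[1] * (K[3] / p[2] - 2 * K[2] / p[2]^2 + 2 * K[1] / p[2]^3)),
             2, 2)
    })
  # exponential boundary: for some censored samples the likelihood is
  # decreasing in eta everywhere, so the supremum sits at eta -> 0 (the
  # Gompertz law degenerating to Exponential(alpha)); pin eta at the
  # search floor and flag the fit rather than reporting non-convergence
  boundary <- FALSE
  if (!fit_s$converged && fit_s$par[2] <= eta_range[1]) {
    eta_b <- eta_range[1]
    fit_s <- list(par = c(alpha_hat(eta_b, st), eta_b),
                  loglik = profile_strength(eta_b, st),
                  n_iter = fit_s$n_iter, converged = TRUE,
                  grad_norm = NA_real_)
    boundary <- TRUE
  }

  fit_y <- newton_block(c(theta0, beta0),
    fn_ll   = function(p) stress_loglik(p[1], p[2], sy),
    fn_grad = function(p) {
      L <- stress_L(p[2], sy, order = 1L)
      yb <- sy$y^p[2]
      c(sy$m_star / p[1] - L[1],
        sy$m_star / p[2] + sy$sum_logy + sum(yb * log(sy$y)) - p[1] * L[2])
    },
    fn_hess = function(p) {
      L <- stress_L(p[2], sy, order = 2L)
      yb <- sy$y^p[2]; ly <- log(sy$y)
      matrix(c(-sy$m_star / p[1]^2, -L[2], -L[2],
               -sy$m_star / p[2]^2 + sum(yb * ly^2) - p[1] * L[3]),
             2, 2)
    })

  est <- mss_params(fit_s$par[1], fit_s$par[2], fit_y$par[1], fit_y$par[2])
  info <- observed_information(est, data)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 4, 4))
  dimnames(vc) <- dimnames(info)
  grad <- mss_score(est, st, sy)
  converged <- fit_s$converged && fit_y$converged
  if (!converged)
    warning("Newton polish did not reach gradient tolerance (norms ",
            signif(fit_s$grad_norm, 3), ", ", signif(fit_y$grad_norm, 3), ")")
  structure(list(coefficients = unlist(est[c("alpha", "eta", "theta", "beta")]),
                 params = est,
                 loglik = fit_s$loglik + fit_y$loglik,
                 vcov = vc, info = info,
                 gradient = grad,
                 gradient_norm = sqrt(sum((grad * unlist(est))^2)),
                 converged = converged,
                 boundary = boundary,
                 n_iter = fit_s$n_iter + fit_y$n_iter,
                 data = data),
            class = "mss_mle")
}

#' @export
coef.mss_mle <- function(object, ...) object$coefficients

#' @export
vcov.mss_mle <- function(object, ...) object$vcov

#' @export
logLik.mss_mle <- function(object, ...) {
  structure(object$loglik, df = 4L, class = "logLik")
}

#' @export
print.mss_mle <- function(x, digits = 4, ...) {
  cat("MSS-GPHC maximum likelihood fit\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("log-likelihood %.4f (%sconverged, %d iterations)\n",
              x$loglik, if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' Asymptotic normal-theory confidence intervals
#'
#' \eqn{\hat\Omega \pm z_{\tau/2}\sqrt{\widehat{Var}(\hat\Omega)}} per
#' parameter, from the inverse observed information.  Intervals are not
#' truncated at zero: near-boundary parameters can yield a negative lower
#' endpoint, which is reported as is.
#'
#' @param object an \code{"mss_mle"} fit.
#' @param parm parameters to report (default all four).
#' @param level confidence level.
#' @param ... unused.
#' @return matrix with columns \code{lower}, \code{upper}.
#' @export
confint.mss_mle <- function(object, parm = c("alpha", "eta", "theta", "beta"),
                            level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  v <- diag(object$vcov)[parm]
  if (any(!is.finite(v) | v < 0))
    stop("non-positive variance estimate; fit may not have converged")
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients[parm]
  out <- cbind(lower = est - z * se, upper = est + z * se)
  rownames(out) <- parm
  attr(out, "level") <- level
  out
}

#' Delta-method interval for the system reliability
#'
#' Plugs the MLE into [rsj()] and propagates the parameter covariance
#' through the gradient of the reliability surface (computed by central
#' differences on the quadrature).  The interval is a plain normal-theory
#' one and may extend beyond [0, 1]; set \code{clip = TRUE} to truncate.
#'
#' @param object an \code{"mss_mle"} fit.
#' @param s,j system configuration: at least \code{s} of \code{j}
#'   components must survive.
#' @param level confidence level.
#' @param clip truncate the interval to [0, 1]?
#' @param h relative step for the central differences.
#' @return an object of class \code{"mss_interval"} with the point
#'   estimate attached as attribute \code{"estimate"}; element
#'   \code{gradient} carries the delta-method gradient.
#' @export
aci_reliability <- function(object, s, j, level = 0.95, clip = FALSE,
                            h = 1e-4) {
  stopifnot(inherits(object, "mss_mle"))
  est <- object$coefficients
  R <- as.numeric(rsj(s, j, est[1], est[2], est[3], est[4]))
  b <- vapply(seq_along(est), function(k) {
    dp <- est; dm <- est
    step <- h * est[k]
    dp[k] <- dp[k] + step; dm[k] <- dm[k] - step
    (as.numeric(rsj(s, j, dp[1], dp[2], dp[3], dp[4])) -
     as.numeric(rsj(s, j, dm[1], dm[2], dm[3], dm[4]))) / (2 * step)
  }, 1)
  v <- drop(t(b) %*% object$vcov %*% b)
  if (!is.finite(v) || v < 0)
    stop("non-positive delta-method variance; fit may not have converged")
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- R - z * sqrt(v); hi <- R + z * sqrt(v)
  if (clip) { lo <- max(0, lo); hi <- min(1, hi) }
  out <- interval_estimate(lo, hi, level, "ACI")
  attr(out, "estimate") <- R
  out$gradient <- b
  out
}

#' @export
summary.mss_mle <- function(object, level = 0.95, s = NULL, j = NULL, ...) {
  ci <- confint(object, level = level)
  tab <- cbind(estimate = object$coefficients,
               se = sqrt(diag(object$vcov)), ci)
  rel <- if (!is.null(s) && !is.null(j))
    aci_reliability(object, s, j, level = level) else NULL
  structure(list(table = tab, level = level, reliability = rel,
                 loglik = object$loglik, converged = object$converged),
            class = "summary.mss_mle")
}

#' @export
print.summary.mss_mle <- function(x, digits = 4, ...) {
  cat("MSS-GPHC maximum likelihood fit\n\n")
  print(signif(x$table, digits))
  if (!is.null(x$reliability)) {
    cat(sprintf("\nR[s,j] = %.4f, %g%% ACI (%.4f, %.4f)\n",
                attr(x$reliability, "estimate"), 100 * x$level,
                x$reliability$lower, x$reliability$upper))
  }
  cat(sprintf("\nlog-likelihood %.4f\n", x$loglik))
  invisible(x)
}

#' Interval estimate container
#'
#' @param lower,upper interval endpoints, \code{lower <= upper}.
#' @param level nominal coverage.
#' @param method one of \code{"ACI"}, \code{"ECI"}, \code{"HPDCI"}.
#' @return a list of class \code{"mss_interval"}.
#' @export
interval_estimate <- function(lower, upper, level, method) {
  if (is.finite(lower) && is.finite(upper) && lower > upper)
    stop("lower > upper")
  structure(list(lower = lower, upper = upper, level = level,
                 method = match.arg(method, c("ACI", "ECI", "HPDCI"))),
            class = "mss_interval")
}

#' @export
print.mss_interval <- function(x, digits = 6, ...) {
  cat(sprintf("%g%% %s: (%s, %s)\n", 100 * x$level, x$method,
              signif(x$lower, digits), signif(x$upper, digits)))
  if (!is.null(attr(x, "estimate")))
    cat("  point estimate:", signif(attr(x, "estimate"), digits), "\n")
  invisible(x)
}
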