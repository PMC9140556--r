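#' One-sample Kolmogorov-Smirnov goodness of fit
#'
#' Sup-distance between the empirical distribution function of the data
#' and a fitted continuous distribution function, with the classical
#' p-value.  Thin wrapper over [stats::ks.test()] that tolerates tied
#' observations (ties occur in the bundled reservoir data).
#'
#' @param x numeric data vector.
#' @param cdf vectorized distribution function.
#' @return list with \code{statistic} (D) and \code{p.value}.
#' @export
ks_goodness_of_fit <- function(x, cdf) {
  if (any(!is.finite(x))) stop("non-finite values in 'x'")
  kt <- suppressWarnings(stats::ks.test(x, cdf))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Progressively censor a complete sample
#'
#' Replays a GPHC design on an already-observed complete sample: at the
#' i-th smallest remaining value, \code{scheme$removals[i]} of the
#' surviving units are withdrawn uniformly at random, and the case
#' I/II/III termination rule is then applied.  Used to impose the
#' censoring schemes of a designed experiment on real data; which
#' surviving units are withdrawn is seed-controlled.
#'
#' @param values complete sample (length \code{scheme$n}, any order).
#' @param scheme a [gphc_scheme()].
#' @param seed optional integer seed.
#' @return list with \code{sample} (a \code{"gphc_sample"}) and
#'   \code{observed_idx}, the positions in \code{values} of the observed
#'   failures in failure order.
#' @export
progressively_censor <- function(values, scheme, seed = NULL) {
  stopifnot(inherits(scheme, "gphc_scheme"), length(values) == scheme$n)
  if (!is.null(seed)) set.seed(seed)
  alive <- seq_along(values)
  obs_idx <- integer(scheme$m)
  for (i in seq_len(scheme$m)) {
    fail <- alive[which.min(values[alive])]
    obs_idx[i] <- fail
    alive <- setdiff(alive, fail)
    r <- scheme$removals[i]
    if (r > 0) {
      drop <- alive[sample.int(length(alive), r)]
      alive <- setdiff(alive, drop)
    }
  }
  times <- values[obs_idx]
  samp <- gphc_termination(times, scheme, ties = "allow")
  list(sample = samp, observed_idx = obs_idx[seq_len(samp$j_star)])
}

#' Monte Carlo evaluation of the estimators
#'
#' Runs the full two-stage design repeatedly at a known truth and
#' summarizes each estimand (the four parameters and \eqn{R_{s,j}}) by
#' bias and MSE of the point estimators and by average interval length
#' (AIL) and empirical coverage probability (CP) of the interval
#' estimators.  Replicates whose fit fails are excluded and counted.
#'
#' @param params an [mss_params()] truth.
#' @param s,j system configuration.
#' @param strength_scheme,stress_scheme [gphc_scheme()] objects.
#' @param n_rep number of replicates.
#' @param level nominal interval level.
#' @param methods subset of \code{c("mle", "eci", "bayes")}.
#' @param bayes_iter,bayes_burn chain length and burn-in when
#'   \code{"bayes"} is requested.
#' @param seed optional integer seed.
#' @return an object of class \code{"mss_study"}: a per-estimand summary
#'   table plus the replicate-level estimates and the failure count.
#' @export
run_simulation_study <- function(params, s, j, strength_scheme, stress_scheme,
                                 n_rep = 500, level = 0.95,
                                 methods = c("mle", "eci"),
                                 bayes_iter = 1000, bayes_burn = 250,
                                 seed = NULL) {
  stopifnot(inherits(params, "mss_params"), n_rep >= 1)
  methods <- match.arg(methods, c("mle", "eci", "bayes"), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  R_true <- as.numeric(rsj(s, j, params$alpha, params$eta,
                           params$theta, params$beta))
  truth <- c(unlist(params[c("alpha", "eta", "theta", "beta")]), R = R_true)

  est_mle <- matrix(NA_real_, n_rep, 5,
                    dimnames = list(NULL, names(truth)))
  est_be <- est_mle
  aci_cov <- matrix(NA, n_rep, 5, dimnames = list(NULL, names(truth)))
  aci_len <- est_mle
  eci_cov <- matrix(NA, n_rep, 2, dimnames = list(NULL, c("eta", "beta")))
  eci_len <- matrix(NA_real_, n_rep, 2,
                    dimnames = list(NULL, c("eta", "beta")))
  hpd_cov <- aci_cov; hpd_len <- aci_len
  n_fail <- 0L

  for (r in seq_len(n_rep)) {
    d <- simulate_mss(params, strength_scheme, stress_scheme)
    fit <- tryCatch(mss_mle(d), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { n_fail <- n_fail + 1L; next }
    if ("mle" %in% methods) {
      Rhat <- as.numeric(rsj(s, j, fit$coefficients[1], fit$coefficients[2],
                             fit$coefficients[3], fit$coefficients[4]))
      est_mle[r, ] <- c(fit$coefficients, Rhat)
      ci <- tryCatch(confint(fit, level = level), error = function(e) NULL)
      if (!is.null(ci)) {
        aci_cov[r, 1:4] <- truth[1:4] >= ci[, 1] & truth[1:4] <= ci[, 2]
        aci_len[r, 1:4] <- ci[, 2] - ci[, 1]
      }
      ri <- tryCatch(aci_reliability(fit, s, j, level = level),
                     error = function(e) NULL)
      if (!is.null(ri)) {
        aci_cov[r, 5] <- R_true >= ri$lower & R_true <= ri$upper
        aci_len[r, 5] <- ri$upper - ri$lower
      }
    }
    if ("eci" %in% methods) {
      ee <- tryCatch(eci_eta(d, level), error = function(e) NULL)
      if (!is.null(ee)) {
        eci_cov[r, "eta"] <- params$eta >= ee$lower & params$eta <= ee$upper
        eci_len[r, "eta"] <- ee$upper - ee$lower
      }
      eb <- tryCatch(eci_beta(d, level), error = function(e) NULL)
      if (!is.null(eb)) {
        eci_cov[r, "beta"] <- params$beta >= eb$lower & params$beta <= eb$upper
        eci_len[r, "beta"] <- eb$upper - eb$lower
      }
    }
    if ("bayes" %in% methods) {
      bb <- tryCatch(
        mss_bayes(d, s = s, j = j, n_iter = bayes_iter, burn_in = bayes_burn,
                  init = fit$params,
                  proposal_sd = 2.4 * sqrt(diag(fit$vcov)[c("eta", "beta")])),
        error = function(e) NULL)
      if (!is.null(bb)) {
        est_be[r, ] <- coef(bb)
        keep <- seq.int(bb$burn_in + 1L, nrow(bb$draws))
        ch <- cbind(bb$draws[keep, , drop = FALSE],
                    R = bb$reliability[keep])
        for (k in seq_len(5)) {
          hp <- hpd_interval(ch[, k], level)
          hpd_cov[r, k] <- truth[k] >= hp$lower & truth[k] <= hp$upper
          hpd_len[r, k] <- hp$upper - hp$lower
        }
      }
    }
  }

  summarize <- function(est) {
    bias <- colMeans(est, na.rm = TRUE) - truth
    mse <- colMeans(sweep(est, 2, truth)^2, na.rm = TRUE)
    cbind(bias = bias, mse = mse)
  }
  tab <- data.frame(estimand = names(truth), truth = truth)
  if ("mle" %in% methods) {
    sm <- summarize(est_mle)
    tab$mle_bias <- sm[, "bias"]; tab$mle_mse <- sm[, "mse"]
    tab$aci_ail <- colMeans(aci_len, na.rm = TRUE)
    tab$aci_cp <- colMeans(aci_cov, na.rm = TRUE)
  }
  if ("bayes" %in% methods) {
    sb <- summarize(est_be)
    tab$be_bias <- sb[, "bias"]; tab$be_mse <- sb[, "mse"]
    tab$hpd_ail <- colMeans(hpd_len, na.rm = TRUE)
    tab$hpd_cp <- colMeans(hpd_cov, na.rm = TRUE)
  }
  if ("eci" %in% methods) {
    tab$eci_ail <- NA_real_; tab$eci_cp <- NA_real_
    tab[tab$estimand %in% c("eta", "beta"), "eci_ail"] <-
      colMeans(eci_len, na.rm = TRUE)[c("eta", "beta")]
    tab[tab$estimand %in% c("eta", "beta"), "eci_cp"] <-
      colMeans(eci_cov, na.rm = TRUE)[c("eta", "beta")]
  }
  rownames(tab) <- NULL
  structure(list(summary = tab, n_rep = n_rep, n_fail = n_fail,
                 level = level, truth = truth,
                 estimates_mle = est_mle,
                 estimates_be = if ("bayes" %in% methods) est_be else NULL),
            class = "mss_study")
}

#' @export
print.mss_study <- function(x, digits = 4, ...) {
  cat(sprintf("MSS simulation study: %d replicates (%d failed fits excluded)\n\n",
              x$n_rep, x$n_fail))
  tab <- x$summary
  tab[-1] <- lapply(tab[-1], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Real-data workflow: complete and censored analyses
#'
#' Reproduces the reservoir-storage analysis: complete-sample fits
#' (MLE with asymptotic intervals, Bayes with HPD intervals, reliability
#' of the 1-out-of-6 system), then, for each supplied censoring design,
#' an analysis of the artificially censored data.  The stress vector is
#' censored first; systems whose stress is unobserved have their whole
#' strength row dropped, and the strength scheme is then applied within
#' each remaining row.  Which surviving units are withdrawn at each
#' failure is random and seed-controlled.
#'
#' @param strengths complete strength matrix (rows = systems); defaults
#'   to the bundled reservoir data.
#' @param stresses complete stress vector in the same system order.
#' @param schemes named list of designs, each a list with elements
#'   \code{strength} and \code{stress} (both [gphc_scheme()]).
#' @param s,j system configuration (default 1-out-of-6).
#' @param level interval level.
#' @param n_iter,burn_in MCMC settings.
#' @param seed integer seed controlling the random withdrawals and MCMC.
#' @return list with elements \code{complete} (MLE/Bayes summaries) and
#'   one element per censoring design.
#' @export
analyze_real_data <- function(strengths = NULL, stresses = NULL,
                              schemes = list(), s = 1, j = 6,
                              level = 0.95, n_iter = 4000, burn_in = 1000,
                              seed = NULL) {
  if (is.null(strengths) || is.null(stresses)) {
    strengths <- as.matrix(utils::read.csv(
      system.file("extdata", "reservoir_strength.csv", package = "ssgphc")))
    dimnames(strengths) <- NULL
    stresses <- utils::read.csv(
      system.file("extdata", "reservoir_stress.csv", package = "ssgphc"))$stress
  }
  if (!is.null(seed)) set.seed(seed)

  analyse_one <- function(d) {
    fit <- mss_mle(d)
    ci <- confint(fit, level = level)
    rel <- aci_reliability(fit, s, j, level = level)
    bb <- mss_bayes(d, s = s, j = j, n_iter = n_iter, burn_in = burn_in,
                    init = fit$params)
    bs <- summary(bb, level = level)
    eci <- tryCatch(list(eta = eci_eta(d, level), beta = eci_beta(d, level)),
                    error = function(e) NULL)
    list(mle = fit, aci = ci, reliability = rel, bayes = bs, eci = eci)
  }

  out <- list(complete = analyse_one(mss_data(strengths, stresses)))

  for (nm in names(schemes)) {
    sch <- schemes[[nm]]
    cy <- progressively_censor(stresses, sch$stress)
    kept_rows <- strengths[cy$observed_idx, , drop = FALSE]
    strength_samples <- lapply(seq_len(nrow(kept_rows)), function(i)
      progressively_censor(sort(kept_rows[i, ]), sch$strength)$sample)
    d_cens <- mss_data(strength_samples, cy$sample)
    out[[nm]] <- analyse_one(d_cens)
    out[[nm]]$data <- d_cens
  }
  out
}
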