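#' Multicomponent stress-strength dataset
#'
#' Bundles the strength observations of \eqn{M^*} systems (each a GPHC
#' sample of component failure times under a common design) with the GPHC
#' sample of system stresses.  The strength side may be given as an
#' \eqn{M^* \times J^*} matrix whose rows share one censoring metadata set
#' (the model's working assumption), or as a list of [gphc_sample()]
#' objects when the realized number of failures differs between systems.
#'
#' @param strengths numeric matrix (rows = systems, columns = ordered
#'   component failure times) or list of \code{"gphc_sample"} objects.
#' @param stresses numeric vector of system stress failure times, or a
#'   \code{"gphc_sample"}.
#' @param strength_removals withdrawals at each observed component failure
#'   (length \code{ncol(strengths)}); defaults to none (complete rows).
#' @param stress_removals withdrawals at each observed stress failure.
#' @param strength_t_star realized end time of each system's strength test
#'   (scalar, shared); defaults to the largest observed time per row.
#' @param stress_b_star realized end time of the stress test.
#' @param strength_terminal,stress_terminal units removed en bloc at
#'   termination.
#' @return an object of class \code{"mss_data"} with elements
#'   \code{strength} (list of \code{"gphc_sample"}), \code{stress}
#'   (a \code{"gphc_sample"}), and \code{M_star}.
#' @examples
#' d <- reservoir_data()
#' d$M_star            # 5 systems
#' strength_matrix(d)  # 5 x 6 failure-time matrix
#' @export
mss_data <- function(strengths, stresses,
                     strength_removals = NULL, stress_removals = NULL,
                     strength_t_star = NULL, stress_b_star = NULL,
                     strength_terminal = 0L, stress_terminal = 0L) {
  if (is.matrix(strengths)) {
    if (!is.numeric(strengths) || any(!is.finite(strengths)) ||
        any(strengths <= 0))
      stop("strength times must be positive and finite")
    J <- ncol(strengths)
    if (is.null(strength_removals)) strength_removals <- rep(0L, J)
    if (all(strength_removals == 0L) && strength_terminal == 0L)
      strengths <- t(apply(strengths, 1L, sort))   # complete rows: order freely
    strength <- lapply(seq_len(nrow(strengths)), function(i) {
      row <- strengths[i, ]
      if (is.unsorted(row))
        stop("strength row ", i, " is not non-decreasing")
      gphc_sample(row, strength_removals,
                  t_star = if (is.null(strength_t_star)) max(row)
                           else strength_t_star,
                  terminal_removals = strength_terminal,
                  case = if (strength_terminal > 0) "II" else "III")
    })
  } else if (is.list(strengths) &&
             all(vapply(strengths, inherits, TRUE, "gphc_sample"))) {
    strength <- strengths
  } else stop("'strengths' must be a numeric matrix or a list of gphc_sample")

  if (inherits(stresses, "gphc_sample")) {
    stress <- stresses
  } else {
    if (!is.numeric(stresses) || any(!is.finite(stresses)) ||
        any(stresses <= 0))
      stop("stress times must be positive and finite")
    if (is.null(stress_removals)) stress_removals <- rep(0L, length(stresses))
    if (is.unsorted(stresses)) {
      if (all(stress_removals == 0L) && stress_terminal == 0L)
        stresses <- sort(stresses)
      else
        stop("censored stress sample must be given in increasing order")
    }
    stress <- gphc_sample(stresses, stress_removals,
                          t_star = if (is.null(stress_b_star)) max(stresses)
                                   else stress_b_star,
                          terminal_removals = stress_terminal,
                          case = if (stress_terminal > 0) "II" else "III")
  }
  if (length(strength) != stress$j_star)
    stop("number of strength rows (", length(strength),
         ") must equal the number of observed stresses (", stress$j_star, ")")
  structure(list(strength = strength, stress = stress,
                 M_star = length(strength)),
            class = "mss_data")
}

#' @export
print.mss_data <- function(x, ...) {
  js <- vapply(x$strength, function(s) s$j_star, 1L)
  cat(sprintf("MSS dataset: %d systems; strengths J* = %s; stress case %s (M* = %d)\n",
              x$M_star,
              if (length(unique(js)) == 1L) as.character(js[1L])
              else paste(js, collapse = ","),
              x$stress$case, x$stress$j_star))
  invisible(x)
}

#' Common strength metadata of an MSS dataset
#'
#' Returns the strength observations as a matrix when (and only when) all
#' systems share the number of observed failures, removal pattern and
#' termination metadata -- the common-design assumption under which the
#' exact pivotal intervals are derived.
#'
#' @param data an [mss_data()] object.
#' @return numeric matrix with one row per system.
#' @export
strength_matrix <- function(data) {
  stopifnot(inherits(data, "mss_data"))
  js <- vapply(data$strength, function(s) s$j_star, 1L)
  if (length(unique(js)) != 1L)
    stop("systems realized different numbers of observed failures (",
         paste(js, collapse = ","), "); no common J*")
  do.call(rbind, lapply(data$strength, function(s) s$times))
}

#' Two-stage GPHC simulation of an MSS dataset
#'
#' Reproduces the designed experiment: the stress test is run first on
#' \code{stress_scheme}, yielding \eqn{M^*} observed system stresses; a
#' strength test under \code{strength_scheme} is then run for each of the
#' \eqn{M^*} observed systems.  Each system's strength test realizes its
#' own termination case.
#'
#' @param params an [mss_params()] truth.
#' @param strength_scheme,stress_scheme [gphc_scheme()] objects.
#' @param seed optional integer seed.
#' @return an [mss_data()] object.
#' @export
simulate_mss <- function(params, strength_scheme, stress_scheme, seed = NULL) {
  stopifnot(inherits(params, "mss_params"))
  if (!is.null(seed)) set.seed(seed)
  stress <- rgphc(stress_scheme,
                  function(p) qchen(p, params$theta, params$beta))
  strength <- lapply(seq_len(stress$j_star), function(i)
    rgphc(strength_scheme,
          function(p) qgompertz(p, params$alpha, params$eta)))
  mss_data(strength, stress)
}

#' Reservoir-storage dataset (1-out-of-6 system)
#'
#' Monthly reservoir storage records analysed as a multicomponent
#' stress-strength system: for each of five years, the six January--June
#' storage values are the component strengths and the preceding August
#' value is the common stress; the system "works" (no drought) if at least
#' one month's storage exceeds the August value, i.e. s = 1, j = 6.
#' The 35 values are bundled as plain CSV under \code{inst/extdata}.
#'
#' @return a complete-sample [mss_data()] with 5 systems of 6 components.
#' @export
reservoir_data <- function() {
  xs <- as.matrix(utils::read.csv(
    system.file("extdata", "reservoir_strength.csv", package = "ssgphc"),
    header = TRUE))
  ys <- utils::read.csv(
    system.file("extdata", "reservoir_stress.csv", package = "ssgphc"),
    header = TRUE)$stress
  dimnames(xs) <- NULL
  mss_data(xs, ys)
}
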