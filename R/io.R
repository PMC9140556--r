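#' Read an MSS dataset from CSV files
#'
#' The strength file must be a rectangular numeric CSV with a header row
#' (one row per system, columns in failure order); the stress file needs
#' a single \code{stress} column.  An optional YAML scheme configuration
#' attaches censoring metadata (see [read_scheme_config()]); without it
#' the data are treated as complete samples.
#'
#' @param strength_path,stress_path CSV file paths.
#' @param scheme_path optional YAML scheme configuration path.
#' @return an [mss_data()] object.
#' @export
read_mss_dataset <- function(strength_path, stress_path, scheme_path = NULL) {
  xs <- utils::read.csv(strength_path, header = TRUE)
  bad <- which(!vapply(xs, is.numeric, TRUE))
  if (length(bad))
    stop("non-numeric strength column(s): ",
         paste(names(xs)[bad], collapse = ", "))
  xs <- as.matrix(xs)
  if (any(!is.finite(xs)))
    stop("missing or non-finite strength value at row ",
         which(!is.finite(xs), arr.ind = TRUE)[1, 1])
  dimnames(xs) <- NULL
  ys <- utils::read.csv(stress_path, header = TRUE)
  if (!"stress" %in% names(ys)) stop("stress file needs a 'stress' column")
  if (!is.numeric(ys$stress) || any(!is.finite(ys$stress)))
    stop("non-numeric or missing stress values")

  if (is.null(scheme_path)) return(mss_data(xs, ys$stress))

  cfg <- read_scheme_config(scheme_path)
  sx <- cfg$strength; sy <- cfg$stress
  mss_data(xs, ys$stress,
           strength_removals = sx$removals[seq_len(ncol(xs))],
           stress_removals = sy$removals[seq_len(length(ys$stress))],
           strength_t_star = if (is.finite(sx$t_max)) sx$t_max else NULL,
           stress_b_star = if (is.finite(sy$t_max)) sy$t_max else NULL,
           strength_terminal = sx$n - ncol(xs) -
             sum(sx$removals[seq_len(ncol(xs))]),
           stress_terminal = sy$n - length(ys$stress) -
             sum(sy$removals[seq_len(length(ys$stress))]))
}

#' Write an MSS dataset to CSV files
#'
#' Inverse of [read_mss_dataset()] for datasets with a common strength
#' design; round-trips with it.
#'
#' @param data an [mss_data()] object.
#' @param strength_path,stress_path output CSV paths.
#' @export
write_mss_dataset <- function(data, strength_path, stress_path) {
  X <- strength_matrix(data)
  colnames(X) <- paste0("t", seq_len(ncol(X)))
  utils::write.csv(X, strength_path, row.names = FALSE)
  utils::write.csv(data.frame(stress = data$stress$times), stress_path,
                   row.names = FALSE)
  invisible(data)
}

#' Read / write a censoring-scheme configuration
#'
#' YAML file with top-level \code{strength} and \code{stress} blocks,
#' each holding \code{n}, \code{m}, \code{c}, \code{t_max} (\code{.inf}
#' for no time limit) and \code{removals}.  Validation runs through
#' [gphc_scheme()], so a malformed scheme fails with the violated
#' constraint named.
#'
#' @param path YAML file path.
#' @return list with \code{strength} and \code{stress}
#'   [gphc_scheme()] objects.
#' @export
read_scheme_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (blk in c("strength", "stress"))
    if (is.null(cfg[[blk]])) stop("missing '", blk, "' block in ", path)
  parse_block <- function(b) {
    t_max <- if (is.null(b$t_max)) Inf else as.numeric(b$t_max)
    gphc_scheme(b$n, b$m, b$c, t_max, b$removals)
  }
  list(strength = parse_block(cfg$strength),
       stress = parse_block(cfg$stress))
}

#' @rdname read_scheme_config
#' @param config list with \code{strength} and \code{stress}
#'   [gphc_scheme()] objects.
#' @export
write_scheme_config <- function(config, path) {
  to_list <- function(s)
    list(n = s$n, m = s$m, c = s$c, t_max = s$t_max,
         removals = as.integer(s$removals))
  yaml::write_yaml(list(strength = to_list(config$strength),
                        stress = to_list(config$stress)), path)
  invisible(config)
}
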