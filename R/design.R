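#' Describe a validation experiment design
#'
#' A validation design records the structure of the experiment: how many
#' series (typically days) were run, how many replicates of each calibration
#' standard (CS) and validation standard (VS) were measured per series, the
#' nominal concentration levels, the tolerance-interval coverage probability
#' `beta` and the acceptance limit `lambda_pct`.
#'
#' The default values correspond to a common plasma-assay design: 3 series
#' (consecutive days), CS in triplicate and VS four times per day, beta-
#' expectation coverage 95% and acceptance limits of +/-15% of nominal.
#'
#' @param n_series Number of series/days `p` (>= 2).
#' @param n_cs_reps Replicates per CS level per series.
#' @param n_vs_reps Replicates per VS level per series `n` (>= 2).
#' @param cs_levels Nominal CS concentrations (ng/mL), strictly increasing.
#' @param vs_levels Nominal VS concentrations (ng/mL), strictly increasing.
#' @param beta Coverage probability of the tolerance interval, in (0, 1).
#' @param lambda_pct Symmetric acceptance limit as a percentage of nominal.
#' @return An object of class `validation_design`.
#' @examples
#' validation_design(cs_levels = c(5, 25, 75, 125, 175, 250),
#'                   vs_levels = c(5, 25, 75, 125, 175, 250))
#' @export
validation_design <- function(n_series = 3L, n_cs_reps = 3L, n_vs_reps = 4L,
                              cs_levels, vs_levels,
                              beta = 0.95, lambda_pct = 15) {
  n_series <- as.integer(n_series)
  n_cs_reps <- as.integer(n_cs_reps)
  n_vs_reps <- as.integer(n_vs_reps)
  if (n_series < 2L)
    stop("'n_series' must be >= 2 (between-series variance is not estimable otherwise)")
  if (n_vs_reps < 2L)
    stop("'n_vs_reps' must be >= 2 (within-series variance is not estimable otherwise)")
  if (n_cs_reps < 1L)
    stop("'n_cs_reps' must be >= 1")
  check_levels <- function(x, what) {
    if (length(x) < 1L || any(!is.finite(x)) || any(x <= 0))
      stop("'", what, "' must be positive and finite")
    if (is.unsorted(x, strictly = TRUE))
      stop("'", what, "' must be strictly increasing")
  }
  check_levels(cs_levels, "cs_levels")
  check_levels(vs_levels, "vs_levels")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1)
    stop("'beta' must be a single probability in (0, 1)")
  if (!is.numeric(lambda_pct) || length(lambda_pct) != 1L || lambda_pct <= 0)
    stop("'lambda_pct' must be a single positive percentage")
  structure(
    list(n_series = n_series, n_cs_reps = n_cs_reps, n_vs_reps = n_vs_reps,
         cs_levels = as.numeric(cs_levels), vs_levels = as.numeric(vs_levels),
         beta = beta, lambda_pct = as.numeric(lambda_pct)),
    class = "validation_design")
}

#' @export
print.validation_design <- function(x, ...) {
  cat("Validation design\n")
  cat(sprintf("  series (p): %d   CS reps/series: %d   VS reps/series (n): %d\n",
              x$n_series, x$n_cs_reps, x$n_vs_reps))
  cat("  CS levels (ng/mL):", paste(x$cs_levels, collapse = ", "), "\n")
  cat("  VS levels (ng/mL):", paste(x$vs_levels, collapse = ", "), "\n")
  cat(sprintf("  beta = %g, acceptance limits = +/-%g%%\n", x$beta, x$lambda_pct))
  invisible(x)
}
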