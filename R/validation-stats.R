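#' Balanced one-way random-effects variance components
#'
#' Decomposes the variance of back-calculated concentrations at one level
#' into a within-series (repeatability) and a between-series component,
#' from the classical balanced one-way ANOVA:
#' \deqn{MS_B = n \sum_i (\bar x_i - \bar x)^2 / (p - 1), \quad
#'       MS_W = \sum_{ij} (x_{ij} - \bar x_i)^2 / (p(n-1))}
#' with \eqn{s^2_W = MS_W} and \eqn{s^2_B = (MS_B - MS_W)/n}. The
#' between-series estimator is *not* truncated at zero: when series means
#' are more alike than the within-series scatter predicts, \eqn{s^2_B} is
#' negative and the intermediate-precision variance
#' \eqn{s^2_{IP} = s^2_W + s^2_B} drops below \eqn{s^2_W}. Keeping the
#' unconstrained estimator is what makes the reported intermediate
#' precision consistent with the tolerance-interval computation (which
#' allows a negative between/within variance ratio).
#'
#' \eqn{s^2_{IP} = ((n-1) MS_W + MS_B)/n} is a non-negative combination of
#' mean squares, so it is always >= 0 even when \eqn{s^2_B < 0}.
#'
#' @param x Numeric matrix of back-calculated concentrations, `p` rows
#'   (series) by `n` columns (replicates), balanced, no missing cells.
#' @return An object of class `variance_components`: list with
#'   `s2_within`, `s2_between`, `s2_ip`, `ms_within`, `ms_between`,
#'   `grand_mean`, `p`, `n`.
#' @examples
#' variance_components(matrix(c(1, 2, 3, 4), nrow = 2, byrow = TRUE))
#' @export
variance_components <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix (series in rows, replicates in columns)")
  if (anyNA(x))
    stop("balanced design required: missing cells are not supported")
  p <- nrow(x)
  n <- ncol(x)
  if (p < 2L || n < 2L)
    stop("design error: need p >= 2 series and n >= 2 replicates, got p = ",
         p, ", n = ", n)
  m_i <- rowMeans(x)
  m <- mean(m_i)
  ms_between <- n * sum((m_i - m)^2) / (p - 1)
  ms_within <- sum((x - m_i)^2) / (p * (n - 1))
  s2_within <- ms_within
  s2_between <- (ms_between - ms_within) / n
  structure(
    list(s2_within = s2_within, s2_between = s2_between,
         s2_ip = s2_within + s2_between,
         ms_within = ms_within, ms_between = ms_between,
         grand_mean = m, p = p, n = n),
    class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("One-way variance components (p = %d series, n = %d replicates)\n",
              x$p, x$n))
  cat(sprintf("  within-series  s2_W  = %.6g\n", x$s2_within))
  cat(sprintf("  between-series s2_B  = %.6g%s\n", x$s2_between,
              if (x$s2_between < 0) "  (negative ANOVA estimate, untruncated)" else ""))
  cat(sprintf("  intermediate   s2_IP = %.6g\n", x$s2_ip))
  invisible(x)
}

# Core beta-expectation tolerance interval on the relative-error scale.
# R is the between/within variance ratio s2_B/s2_W; may be negative, and
# may be Inf (s2_W = 0 with s2_B > 0), for which the analytic limits
# B^2 -> 1/n and nu -> p - 1 are used. Vectorised over the numeric args.
tol_core <- function(bias_pct, rsd_ip_pct, R, p, n, beta) {
  inf <- is.infinite(R)
  nR1 <- n * R + 1
  bad <- !inf & nR1 <= 0
  if (any(bad)) {
    warning("n*R + 1 <= 0 (strongly negative between/within variance ratio); ",
            "falling back to R = 0")
    R[bad] <- 0
    nR1[bad] <- 1
  }
  B2 <- ifelse(inf, 1 / n, (R + 1) / nR1)
  nu <- ifelse(inf, p - 1,
               (R + 1)^2 / ((R + 1 / n)^2 / (p - 1) + (1 - 1 / n) / (p * n)))
  nu_int <- pmax(1, floor(nu))
  k <- stats::qt((1 + beta) / 2, df = nu_int) * sqrt(1 + 1 / (p * n * B2))
  list(tol_lower_pct = bias_pct - k * rsd_ip_pct,
       tol_upper_pct = bias_pct + k * rsd_ip_pct,
       dof = nu, dof_int = as.integer(nu_int), k_tol = k, R = R)
}

#' Beta-expectation tolerance interval from summary statistics
#'
#' Computes the interval expected to contain a proportion `beta` of future
#' single measurements, on the relative-error (%) scale, from the per-level
#' summary triple (relative bias, repeatability RSD, intermediate-precision
#' RSD) and the design (`p` series, `n` replicates per series). This is the
#' entry point that reproduces a published validation table: the limits are
#' a deterministic function of the printed summaries.
#'
#' The between/within variance ratio is estimated as
#' \eqn{R = (RSD_{IP}^2 - RSD_r^2)/RSD_r^2} and deliberately *not*
#' truncated at zero (validation tables routinely print
#' \eqn{RSD_{IP} < RSD_r}, i.e. a negative ANOVA between-series estimate;
#' only the untruncated convention is consistent with such tables). Then
#' \deqn{B^2 = \frac{R+1}{nR+1}, \qquad
#'       \nu = \frac{(R+1)^2}{\frac{(R+1/n)^2}{p-1} + \frac{1-1/n}{pn}},}
#' the Satterthwaite degrees of freedom \eqn{\nu} are floored to an integer
#' (minimum 1), the coverage factor is
#' \deqn{k = t_{(1+\beta)/2,\;\lfloor\nu\rfloor}\sqrt{1 + \frac{1}{p n B^2}},}
#' and the limits are `bias_pct` \eqn{\mp} `k * rsd_ip_pct`, symmetric about
#' the bias.
#'
#' If `n*R + 1 <= 0` (possible only with strongly inconsistent rounded
#' summaries) the computation falls back to `R = 0` with a warning.
#'
#' @param bias_pct Relative bias, % of nominal.
#' @param rsd_r_pct Repeatability RSD, % of nominal; must be > 0 (use
#'   [level_statistics()] on raw data for the degenerate zero-variance case).
#' @param rsd_ip_pct Intermediate-precision RSD, % of nominal.
#' @param p Number of series (days), >= 2.
#' @param n Replicates per series, >= 2.
#' @param beta Coverage probability in (0, 1); default 0.95.
#' @return List with `tol_lower_pct`, `tol_upper_pct`, `dof` (real
#'   Satterthwaite df), `dof_int` (floored, >= 1), `k_tol`, `R`.
#' @examples
#' # limits from a printed summary row: bias -0.24%, RSDs 5.60/5.65, 3 days x 4
#' tolerance_interval(-0.24, 5.60, 5.65, p = 3, n = 4, beta = 0.95)
#' @export
tolerance_interval <- function(bias_pct, rsd_r_pct, rsd_ip_pct, p, n,
                               beta = 0.95) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1)
    stop("'beta' must be a single probability in (0, 1)")
  if (p < 2L || n < 2L)
    stop("design error: need p >= 2 and n >= 2")
  if (any(rsd_r_pct < 0) || any(rsd_ip_pct < 0))
    stop("RSDs must be non-negative")
  if (any(rsd_r_pct == 0))
    stop("rsd_r_pct = 0: the variance ratio R is undefined; ",
         "compute from raw data with level_statistics() instead")
  R <- (rsd_ip_pct^2 - rsd_r_pct^2) / rsd_r_pct^2
  tol_core(bias_pct, rsd_ip_pct, R, p, n, beta)
}

#' Per-level trueness, precision and tolerance interval from raw replicates
#'
#' Computes the full set of per-level validation statistics from a balanced
#' `p x n` matrix of back-calculated concentrations at one nominal level:
#' relative bias (trueness), repeatability and intermediate-precision RSDs
#' from the one-way variance components, and the beta-expectation tolerance
#' limits of the relative error.
#'
#' All relative quantities use the nominal concentration as denominator
#' (bias = `100 * (mean - nominal) / nominal`, RSD = `100 * SD / nominal`),
#' so bias and RSDs are on the same scale and the tolerance limits read
#' directly as relative errors.
#'
#' Degenerate inputs are handled explicitly: if the intermediate-precision
#' variance is zero (all values identical) the interval collapses to the
#' bias; if only the within-series variance is zero the analytic limit of
#' the coverage factor at infinite variance ratio is used.
#'
#' @param x Numeric `p x n` matrix of concentrations (series in rows).
#' @param nominal_conc Nominal (true) concentration, ng/mL, > 0.
#' @param beta Coverage probability; default 0.95.
#' @return An object of class `level_stats`: list with `nominal_conc`,
#'   `grand_mean`, `bias_pct`, `rsd_r_pct`, `rsd_ip_pct`,
#'   `variance_components`, `dof`, `dof_int`, `k_tol`, `tol_lower_pct`,
#'   `tol_upper_pct`.
#' @export
level_statistics <- function(x, nominal_conc, beta = 0.95) {
  if (!is.numeric(nominal_conc) || length(nominal_conc) != 1L ||
      nominal_conc <= 0)
    stop("'nominal_conc' must be a single positive concentration")
  vc <- variance_components(x)
  if (vc$s2_ip < 0)
    stop("negative intermediate-precision variance: invalid input")
  bias_pct <- 100 * (vc$grand_mean - nominal_conc) / nominal_conc
  rsd_r_pct <- 100 * sqrt(vc$s2_within) / nominal_conc
  rsd_ip_pct <- 100 * sqrt(vc$s2_ip) / nominal_conc
  if (rsd_ip_pct == 0) {
    tol <- list(tol_lower_pct = bias_pct, tol_upper_pct = bias_pct,
                dof = NA_real_, dof_int = NA_integer_, k_tol = NA_real_,
                R = NA_real_)
  } else {
    R <- if (vc$s2_within == 0) Inf else vc$s2_between / vc$s2_within
    tol <- tol_core(bias_pct, rsd_ip_pct, R, vc$p, vc$n, beta)
  }
  structure(
    list(nominal_conc = nominal_conc, grand_mean = vc$grand_mean,
         bias_pct = bias_pct, rsd_r_pct = rsd_r_pct, rsd_ip_pct = rsd_ip_pct,
         variance_components = vc, beta = beta,
         dof = tol$dof, dof_int = tol$dof_int, k_tol = tol$k_tol,
         tol_lower_pct = tol$tol_lower_pct, tol_upper_pct = tol$tol_upper_pct),
    class = "level_stats")
}

#' @export
print.level_stats <- function(x, ...) {
  cat(sprintf("Level %.4g ng/mL: bias %+.2f%%, RSD_r %.2f%%, RSD_IP %.2f%%\n",
              x$nominal_conc, x$bias_pct, x$rsd_r_pct, x$rsd_ip_pct))
  cat(sprintf("  %g%%-expectation tolerance limits: [%.2f; %.2f]%%\n",
              100 * x$beta, x$tol_lower_pct, x$tol_upper_pct))
  invisible(x)
}

#' Extraction-recovery statistics
#'
#' Per-record recovery is `100 * area_extracted / area_reference`. Records
#' are averaged per concentration level; the overall recovery is the mean
#' of the per-level means and the overall SD is the standard deviation of
#' the per-level means, so each level contributes equally regardless of its
#' replicate count.
#'
#' @param records Recovery records (see [read_recovery()]): `data.frame`
#'   with `analyte`, `level`, `series`, `area_extracted`, `area_reference`.
#' @return An object of class `recovery_stats`: list with `per_level`
#'   (`data.frame` of analyte, level, n, mean_recovery_pct) and `overall`
#'   (`data.frame` of analyte, mean_recovery_pct, sd_recovery_pct).
#' @examples
#' rec <- data.frame(analyte = "AFA", level = rep(1:2, each = 2), series = 1,
#'                   area_extracted = c(86, 86, 90, 90),
#'                   area_reference = 100)
#' recovery_statistics(rec)
#' @export
recovery_statistics <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("analyte", "level", "area_extracted", "area_reference")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    stop("recovery records missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(records$area_reference == 0))
    stop("zero reference peak area: recovery undefined")
  records$recovery_pct <-
    100 * records$area_extracted / records$area_reference
  per_level <- stats::aggregate(recovery_pct ~ analyte + level,
                                data = records, FUN = mean)
  counts <- stats::aggregate(recovery_pct ~ analyte + level,
                             data = records, FUN = length)
  per_level <- data.frame(analyte = per_level$analyte,
                          level = per_level$level,
                          n = counts$recovery_pct,
                          mean_recovery_pct = per_level$recovery_pct)
  per_level <- per_level[order(per_level$analyte, per_level$level), ]
  rownames(per_level) <- NULL
  overall <- do.call(rbind, lapply(split(per_level, per_level$analyte),
    function(d) data.frame(analyte = d$analyte[1L],
                           mean_recovery_pct = mean(d$mean_recovery_pct),
                           sd_recovery_pct = stats::sd(d$mean_recovery_pct))))
  rownames(overall) <- NULL
  structure(list(per_level = per_level, overall = overall),
            class = "recovery_stats")
}

#' @export
print.recovery_stats <- function(x, ...) {
  cat("Extraction recovery\n")
  for (i in seq_len(nrow(x$overall)))
    cat(sprintf("  %s: %.1f +/- %.1f %% (mean +/- SD of %d level means)\n",
                x$overall$analyte[i], x$overall$mean_recovery_pct[i],
                x$overall$sd_recovery_pct[i],
                sum(x$per_level$analyte == x$overall$analyte[i])))
  invisible(x)
}
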