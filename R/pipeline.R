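#' Published validation summary for two TKI plasma assays
#'
#' Per-level validation summary statistics of two UPLC plasma assays for
#' the tyrosine kinase inhibitors afatinib (AFA, 5-250 ng/mL) and
#' ibrutinib (IBR, 5-400 ng/mL), validated on a 3-day design with 4
#' validation-standard replicates per day: relative bias (% of nominal),
#' repeatability and intermediate-precision RSDs (% of nominal), and the
#' published 95%-expectation tolerance limits of the relative error. This
#' table is the worked example used throughout the package: the tolerance
#' limits are a deterministic function of the summary triples and the
#' design, so [run_summary_mode()] recomputes them from the first four
#' numeric columns.
#'
#' @param analyte `"AFA"`, `"IBR"`, or `"both"` (default).
#' @return `data.frame` with columns `analyte`, `level`, `nominal_conc`,
#'   `bias_pct`, `rsd_r_pct`, `rsd_ip_pct`, `published_tol_lower_pct`,
#'   `published_tol_upper_pct`.
#' @export
tki_plasma_summary <- function(analyte = c("both", "AFA", "IBR")) {
  analyte <- match.arg(analyte)
  path <- system.file("extdata", "tki_plasma_validation_summary.csv",
                      package = "accuprofile", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (analyte != "both") df <- df[df$analyte == analyte, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build an accuracy profile from published summary statistics
#'
#' Summary mode: validation reports usually publish only per-level triples
#' (relative bias, repeatability RSD, intermediate-precision RSD), not the
#' raw replicates. The beta-expectation tolerance limits are a
#' deterministic function of those triples and the design, so the full
#' accuracy-profile decision can be reproduced from the printed table
#' alone.
#'
#' @param summary A `data.frame` with columns `nominal_conc`, `bias_pct`,
#'   `rsd_r_pct`, `rsd_ip_pct` (one row per level, single analyte), or the
#'   path of a CSV file with those columns.
#' @param p Number of series (days).
#' @param n Replicates per series.
#' @param beta Coverage probability; default 0.95.
#' @param lambda_pct Acceptance limit, %; default 15.
#' @param analyte Optional label; taken from an `analyte` column if present.
#' @return An [accuracy_profile][build_profile].
#' @examples
#' prof <- run_summary_mode(tki_plasma_summary("AFA"), p = 3, n = 4)
#' prof
#' @export
run_summary_mode <- function(summary, p, n, beta = 0.95, lambda_pct = 15,
                             analyte = NULL) {
  if (is.character(summary) && length(summary) == 1L)
    summary <- utils::read.csv(summary, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(summary))
  if (nrow(summary) == 0L) stop("empty summary table")
  required <- c("nominal_conc", "bias_pct", "rsd_r_pct", "rsd_ip_pct")
  missing_cols <- setdiff(required, names(summary))
  if (length(missing_cols) > 0L)
    stop("summary table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if ("analyte" %in% names(summary)) {
    labs <- unique(summary$analyte)
    if (length(labs) > 1L)
      stop("summary table mixes analytes (", paste(labs, collapse = ", "),
           "); build one profile per analyte")
    if (is.null(analyte)) analyte <- labs
  }
  if (is.null(analyte)) analyte <- NA_character_
  tol <- tolerance_interval(summary$bias_pct, summary$rsd_r_pct,
                            summary$rsd_ip_pct, p = p, n = n, beta = beta)
  tab <- data.frame(nominal_conc = summary$nominal_conc,
                    bias_pct = summary$bias_pct,
                    rsd_r_pct = summary$rsd_r_pct,
                    rsd_ip_pct = summary$rsd_ip_pct,
                    dof_int = tol$dof_int, k_tol = tol$k_tol,
                    tol_lower_pct = tol$tol_lower_pct,
                    tol_upper_pct = tol$tol_upper_pct)
  if (nrow(tab) == 1L)
    stop("an accuracy profile needs at least 2 levels; ",
         "use tolerance_interval() for a single level")
  build_profile(tab, beta = beta, lambda_pct = lambda_pct,
                analyte = analyte, p = as.integer(p), n = as.integer(n))
}

# Reshape one analyte's back-calculated VS records into per-level balanced
# p x n matrices; errors if any series x level cell is ragged.
vs_level_matrices <- function(vs_records) {
  out <- list()
  for (lv in sort(unique(vs_records$level))) {
    d <- vs_records[vs_records$level == lv, , drop = FALSE]
    counts <- table(d$series)
    if (length(unique(as.integer(counts))) != 1L)
      stop("unbalanced design at level ", lv,
           ": replicate counts per series are ", paste(counts, collapse = ", "))
    series <- sort(unique(d$series))
    n <- as.integer(counts[1L])
    x <- t(vapply(series,
                  function(s) d$conc[d$series == s],
                  numeric(n)))
    out[[as.character(lv)]] <- list(x = x,
                                    nominal_conc = unique(d$nominal_conc))
  }
  out
}

#' Run the full accuracy-profile validation pipeline
#'
#' Raw-replicate mode: for each analyte, fits a calibration curve per
#' series from the CS records, back-calculates the VS records against the
#' curve of their own day, computes per-level trueness/precision/tolerance
#' statistics, assembles the accuracy profile and applies the acceptance
#' decision; extraction-recovery statistics are computed when recovery
#' records are supplied.
#'
#' @param cs CS measurement records: a `data.frame` (see
#'   [read_measurements()]) or a CSV path.
#' @param vs VS measurement records, likewise. Records that already carry
#'   back-calculated `conc` values are used as-is; `cs` may then be `NULL`.
#' @param recovery Optional recovery records (`data.frame` or CSV path).
#' @param beta Coverage probability; default 0.95.
#' @param lambda_pct Acceptance limit, %; default 15.
#' @param weighting Calibration weighting; see [fit_calibration()].
#' @param output_dir Optional directory; per-analyte profile CSVs
#'   (`profile_<analyte>.csv`) and a `summary.txt` are written there.
#' @return An object of class `validation_run`: list with `profiles`
#'   (named list of accuracy profiles), `recovery` (a
#'   [recovery_stats][recovery_statistics] or `NULL`), and `status`
#'   (`0` if every analyte validated over its whole range, `2` otherwise).
#' @export
run_validation <- function(cs, vs, recovery = NULL, beta = 0.95,
                           lambda_pct = 15,
                           weighting = c("none", "one_over_x", "one_over_x2"),
                           output_dir = NULL) {
  weighting <- match.arg(weighting)
  if (is.character(vs)) vs <- read_measurements(vs, role = "VS")
  if (is.character(cs)) cs <- read_measurements(cs, role = "CS")
  if (is.character(recovery)) recovery <- read_recovery(recovery)

  profiles <- list()
  for (a in unique(vs$analyte)) {
    vs_a <- vs[vs$analyte == a, , drop = FALSE]
    if (any(is.na(vs_a$conc))) {
      if (is.null(cs))
        stop("VS records for ", a,
             " lack back-calculated concentrations and no CS data were given")
      cs_a <- cs[cs$analyte == a, , drop = FALSE]
      if (nrow(cs_a) == 0L) stop("no CS records for analyte ", a)
      fits <- fit_calibrations(cs_a, weighting = weighting)
      vs_a <- back_calculate_dataset(vs_a, fits)
    }
    mats <- vs_level_matrices(vs_a)
    stats_list <- lapply(mats, function(m)
      level_statistics(m$x, m$nominal_conc, beta = beta))
    profiles[[a]] <- build_profile(stats_list, beta = beta,
                                   lambda_pct = lambda_pct, analyte = a,
                                   p = length(unique(vs_a$series)),
                                   n = nrow(vs_a) /
                                     (length(unique(vs_a$series)) * length(mats)))
  }
  rec_stats <- if (!is.null(recovery)) recovery_statistics(recovery) else NULL
  status <- if (all(vapply(profiles, function(p) p$validated, logical(1))))
    0L else 2L
  run <- structure(list(profiles = profiles, recovery = rec_stats,
                        status = status),
                   class = "validation_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (a in names(profiles))
      write_profile(profiles[[a]],
                    file.path(output_dir, paste0("profile_", a, ".csv")))
    summary_path <- file.path(output_dir, "summary.txt")
    con <- file(summary_path, open = "wt")
    sink(con)
    on.exit({ sink(); close(con) }, add = TRUE)
    print(run)
  }
  run
}

#' @export
print.validation_run <- function(x, ...) {
  for (p in x$profiles) { print(p); cat("\n") }
  if (!is.null(x$recovery)) print(x$recovery)
  cat(sprintf("Overall status: %s\n",
              if (x$status == 0L) "validated" else "one or more levels fail"))
  invisible(x)
}
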