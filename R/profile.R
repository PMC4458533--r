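#' Assemble an accuracy profile and apply the acceptance decision rule
#'
#' An accuracy profile plots, per concentration level, the beta-expectation
#' tolerance limits of the relative error against symmetric acceptance
#' limits `+/- lambda_pct`. A level is valid when its whole tolerance
#' interval lies inside the acceptance limits (boundary equality counts as
#' valid, matching the non-strict coverage inequality that defines the
#' criterion); the method is validated over the range where every level is
#' valid, and the lowest/highest concentrations of that range are the
#' LLOQ/ULOQ.
#'
#' @param level_stats A list of [level_stats][level_statistics] objects, or
#'   a `data.frame` with columns `nominal_conc`, `bias_pct`, `rsd_r_pct`,
#'   `rsd_ip_pct`, `tol_lower_pct`, `tol_upper_pct` (and optionally
#'   `dof_int`, `k_tol`, `grand_mean`).
#' @param beta Coverage probability used for the intervals.
#' @param lambda_pct Acceptance limit, % of nominal (symmetric).
#' @param analyte Analyte label carried into the profile.
#' @param p,n Design sizes recorded in the profile metadata.
#' @return An object of class `accuracy_profile`: list with `analyte`,
#'   `beta`, `lambda_pct`, `p`, `n`, `levels` (one row per level, sorted by
#'   ascending concentration, with a `valid` flag), `lloq`, `uloq`,
#'   `validated`.
#' @seealso [determine_limits_of_quantification()], [profile_plot_data()]
#' @export
build_profile <- function(level_stats, beta = 0.95, lambda_pct = 15,
                          analyte = NA_character_, p = NA_integer_,
                          n = NA_integer_) {
  if (is.data.frame(level_stats)) {
    tab <- level_stats
    required <- c("nominal_conc", "bias_pct", "rsd_r_pct", "rsd_ip_pct",
                  "tol_lower_pct", "tol_upper_pct")
    missing_cols <- setdiff(required, names(tab))
    if (length(missing_cols) > 0L)
      stop("level table missing column(s): ",
           paste(missing_cols, collapse = ", "))
  } else {
    stopifnot(all(vapply(level_stats, inherits, logical(1), "level_stats")))
    tab <- do.call(rbind, lapply(level_stats, function(s)
      data.frame(nominal_conc = s$nominal_conc, grand_mean = s$grand_mean,
                 bias_pct = s$bias_pct, rsd_r_pct = s$rsd_r_pct,
                 rsd_ip_pct = s$rsd_ip_pct, dof_int = s$dof_int,
                 k_tol = s$k_tol, tol_lower_pct = s$tol_lower_pct,
                 tol_upper_pct = s$tol_upper_pct)))
  }
  if (nrow(tab) < 2L)
    stop("an accuracy profile needs at least 2 concentration levels")
  if (anyDuplicated(tab$nominal_conc))
    stop("duplicate nominal concentrations in profile levels")
  tab <- tab[order(tab$nominal_conc), , drop = FALSE]
  tab$level <- seq_len(nrow(tab))
  tab$valid <- tab$tol_lower_pct >= -lambda_pct & tab$tol_upper_pct <= lambda_pct
  front <- c("level", "nominal_conc")
  tab <- tab[c(front, setdiff(names(tab), front))]
  rownames(tab) <- NULL
  profile <- structure(
    list(analyte = analyte, beta = beta, lambda_pct = lambda_pct,
         p = p, n = n, levels = tab,
         lloq = NA_real_, uloq = NA_real_, validated = all(tab$valid)),
    class = "accuracy_profile")
  loq <- determine_limits_of_quantification(profile)
  profile$lloq <- loq[["lloq"]]
  profile$uloq <- loq[["uloq"]]
  profile
}

#' Validated range of an accuracy profile
#'
#' Returns the lower and upper limits of quantification implied by the
#' accuracy-profile decision rule. If every level is valid the LLOQ/ULOQ
#' are the lowest/highest tested concentrations. If the tolerance-limit
#' curves cross the acceptance limits between adjacent levels, the crossing
#' concentration is located by linear interpolation on the concentration
#' axis, and the LLOQ is the smallest concentration at or above which both
#' curves stay within `+/- lambda_pct` (the ULOQ its upper counterpart).
#' When several disjoint valid windows exist the widest is reported (the
#' lower one on ties). Both are `NA` when no level is valid. No
#' extrapolation outside the tested range is attempted.
#'
#' @param profile An `accuracy_profile`.
#' @return Named numeric vector `c(lloq = , uloq = )`, ng/mL.
#' @export
determine_limits_of_quantification <- function(profile) {
  stopifnot(inherits(profile, "accuracy_profile"))
  tab <- profile$levels
  lam <- profile$lambda_pct
  cc <- tab$nominal_conc
  # violation margin: <= 0 iff both tolerance curves are inside +/- lambda;
  # piecewise linear in concentration between tested levels
  viol <- pmax(-lam - tab$tol_lower_pct, tab$tol_upper_pct - lam)
  if (all(viol > 0))
    return(c(lloq = NA_real_, uloq = NA_real_))
  # collect valid sub-intervals of [min(cc), max(cc)] segment by segment
  starts <- numeric(0)
  ends <- numeric(0)
  open <- NA_real_
  if (viol[1L] <= 0) open <- cc[1L]
  for (i in seq_len(length(cc) - 1L)) {
    v0 <- viol[i]; v1 <- viol[i + 1L]
    if (v0 <= 0 && v1 > 0) {            # leaves the acceptance region
      cross <- cc[i] + (cc[i + 1L] - cc[i]) * (0 - v0) / (v1 - v0)
      starts <- c(starts, open); ends <- c(ends, cross); open <- NA_real_
    } else if (v0 > 0 && v1 <= 0) {     # re-enters
      cross <- cc[i] + (cc[i + 1L] - cc[i]) * (0 - v0) / (v1 - v0)
      open <- cross
    }
  }
  if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, cc[length(cc)]) }
  widths <- ends - starts
  best <- which(widths == max(widths))[1L]
  c(lloq = starts[best], uloq = ends[best])
}

#' Plot-ready accuracy-profile table
#'
#' One row per concentration level with the quantities an accuracy-profile
#' figure needs: relative bias, lower/upper tolerance limits and the
#' constant acceptance limits. No plotting is performed.
#'
#' @param profile An `accuracy_profile`.
#' @return `data.frame` with columns `concentration`, `bias_pct`,
#'   `tol_lower_pct`, `tol_upper_pct`, `lambda_lower_pct`,
#'   `lambda_upper_pct`, ordered by ascending concentration.
#' @export
profile_plot_data <- function(profile) {
  stopifnot(inherits(profile, "accuracy_profile"))
  tab <- profile$levels
  data.frame(concentration = tab$nominal_conc,
             bias_pct = tab$bias_pct,
             tol_lower_pct = tab$tol_lower_pct,
             tol_upper_pct = tab$tol_upper_pct,
             lambda_lower_pct = -profile$lambda_pct,
             lambda_upper_pct = profile$lambda_pct)
}

#' @export
print.accuracy_profile <- function(x, digits = 2, ...) {
  cat(sprintf("Accuracy profile%s (beta = %g, acceptance limits +/-%g%%",
              if (is.na(x$analyte)) "" else paste0(" for ", x$analyte),
              x$beta, x$lambda_pct))
  if (!is.na(x$p)) cat(sprintf(", p = %d, n = %d", x$p, x$n))
  cat(")\n")
  tab <- x$levels
  out <- data.frame(conc = tab$nominal_conc,
                    bias = round(tab$bias_pct, digits),
                    rsd_r = round(tab$rsd_r_pct, digits),
                    rsd_ip = round(tab$rsd_ip_pct, digits),
                    tol_lower = round(tab$tol_lower_pct, digits),
                    tol_upper = round(tab$tol_upper_pct, digits),
                    valid = tab$valid)
  print(out, row.names = FALSE)
  if (x$validated) {
    cat(sprintf("Method validated over %.4g-%.4g ng/mL (LLOQ = %.4g ng/mL)\n",
                x$lloq, x$uloq, x$lloq))
  } else if (is.na(x$lloq)) {
    cat("No concentration level meets the acceptance limits.\n")
  } else {
    cat(sprintf("Partially valid: %.4g-%.4g ng/mL; %d level(s) fail\n",
                x$lloq, x$uloq, sum(!x$levels$valid)))
  }
  invisible(x)
}
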