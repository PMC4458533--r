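#' Fit a per-series linear calibration curve
#'
#' Fits response = intercept + slope * concentration by (optionally
#' weighted) least squares to the calibration standards of a single analyte
#' and a single series (day). The response is the internal-standard
#' normalized peak-area ratio; the concentration axis is the nominal
#' concentration in ng/mL. Calibration is deliberately per series:
#' validation standards are back-calculated against the curve of their own
#' day, which keeps day-to-day calibration drift out of the bias and makes
#' between-day effects estimable from the back-calculated concentrations.
#'
#' @param cs_records `data.frame` of CS measurement records for one analyte
#'   and one series, with `nominal_conc` and `response` columns.
#' @param weighting `"none"` (default), `"one_over_x"` (weights
#'   1/concentration) or `"one_over_x2"` (weights 1/concentration^2).
#' @return An object of class `calibration_fit` with elements `analyte`,
#'   `series`, `model`, `weighting`, `intercept`, `slope`, `residual_sd`
#'   (response units, from the residual sum of squares on
#'   `n_points - 2` degrees of freedom) and `n_points`.
#' @examples
#' cs <- data.frame(analyte = "AFA", role = "CS", series = 1,
#'                  level = 1:6, nominal_conc = c(5, 25, 75, 125, 175, 250),
#'                  response = 0.1 + 0.02 * c(5, 25, 75, 125, 175, 250))
#' fit_calibration(cs)
#' @export
fit_calibration <- function(cs_records,
                            weighting = c("none", "one_over_x", "one_over_x2")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(cs_records))
  if (!all(c("nominal_conc", "response") %in% names(cs_records)))
    stop("cs_records must have 'nominal_conc' and 'response' columns")
  if (any(is.na(cs_records$response)))
    stop("calibration records must carry a response")
  analyte <- unique(cs_records$analyte)
  series <- unique(cs_records$series)
  if (length(analyte) > 1L || length(series) > 1L)
    stop("fit_calibration() expects records from a single analyte and series; got ",
         length(analyte), " analyte(s) and ", length(series), " series")
  x <- cs_records$nominal_conc
  y <- cs_records$response
  if (length(unique(x)) < 2L)
    stop("degenerate calibration design: at least 2 distinct concentration levels required")
  w <- switch(weighting, none = rep(1, length(x)),
              one_over_x = 1 / x, one_over_x2 = 1 / x^2)
  fit <- stats::lm(y ~ x, weights = w)
  coefs <- stats::coef(fit)
  if (anyNA(coefs) || coefs[["x"]] == 0)
    stop("singular calibration fit: estimated slope is zero or undefined")
  df <- length(x) - 2L
  rss <- sum(w * stats::residuals(fit)^2)
  structure(
    list(analyte = if (length(analyte)) analyte else NA_character_,
         series = if (length(series)) series else NA_integer_,
         model = "linear", weighting = weighting,
         intercept = unname(coefs[1L]), slope = unname(coefs[["x"]]),
         residual_sd = if (df > 0L) sqrt(rss / df) else 0,
         n_points = length(x)),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Linear calibration (%s, series %s): response = %.6g + %.6g * conc\n",
              x$analyte, x$series, x$intercept, x$slope))
  cat(sprintf("  weighting: %s, n = %d, residual SD = %.4g\n",
              x$weighting, x$n_points, x$residual_sd))
  invisible(x)
}

#' Predict the instrument response for a concentration
#'
#' Forward evaluation of a fitted calibration curve.
#'
#' @param fit A `calibration_fit`.
#' @param conc Concentration(s), ng/mL.
#' @return Predicted response ratio(s).
#' @export
predict_response <- function(fit, conc) {
  stopifnot(inherits(fit, "calibration_fit"))
  fit$intercept + fit$slope * conc
}

#' Back-calculate a concentration by inverse prediction
#'
#' Returns `(response - intercept) / slope`. The result may be negative
#' (responses below the fitted intercept); negative back-calculated
#' concentrations are retained rather than clipped, since clipping biases
#' low-level trueness and precision estimates.
#'
#' @param fit A `calibration_fit`.
#' @param response Response ratio(s).
#' @return Back-calculated concentration(s), ng/mL.
#' @examples
#' fit <- structure(list(intercept = 0.1, slope = 0.02),
#'                  class = "calibration_fit")
#' back_calculate(fit, 0.6)  # 25
#' @export
back_calculate <- function(fit, response) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) stop("cannot invert a calibration with zero slope")
  (response - fit$intercept) / fit$slope
}

#' Fit calibration curves for every series of one analyte
#'
#' Convenience wrapper that splits CS records by series and fits each with
#' [fit_calibration()].
#'
#' @param cs_records CS records for a single analyte (all series).
#' @inheritParams fit_calibration
#' @return Named list of `calibration_fit` objects, keyed by series index.
#' @export
fit_calibrations <- function(cs_records,
                             weighting = c("none", "one_over_x", "one_over_x2")) {
  weighting <- match.arg(weighting)
  lapply(split(cs_records, cs_records$series), fit_calibration,
         weighting = weighting)
}

#' Back-calculate a validation dataset with day-matched calibration
#'
#' Fills the `conc` column of VS records by inverse prediction, each record
#' against the calibration fit of its own series. Records that already
#' carry a `conc` are passed through unchanged (with one warning).
#'
#' @param vs_records VS measurement records for one analyte.
#' @param fits Named list of `calibration_fit` objects keyed by series
#'   index, as returned by [fit_calibrations()].
#' @return `vs_records` with `conc` filled.
#' @export
back_calculate_dataset <- function(vs_records, fits) {
  stopifnot(is.data.frame(vs_records))
  if (!"conc" %in% names(vs_records)) vs_records$conc <- NA_real_
  preset <- !is.na(vs_records$conc)
  if (any(preset))
    warning(sum(preset), " record(s) already carry a back-calculated ",
            "concentration; passed through unchanged")
  todo <- which(!preset)
  if (length(todo) > 0L) {
    missing_fit <- setdiff(unique(vs_records$series[todo]), as.integer(names(fits)))
    if (length(missing_fit) > 0L)
      stop("no calibration fit for series: ", paste(missing_fit, collapse = ", "))
    for (s in unique(vs_records$series[todo])) {
      idx <- todo[vs_records$series[todo] == s]
      vs_records$conc[idx] <-
        back_calculate(fits[[as.character(s)]], vs_records$response[idx])
    }
  }
  vs_records
}
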