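# Run code with a private RNG stream: the global .Random.seed is saved and
# restored, so simulations never disturb (or depend on) the caller's state.
with_private_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters of a synthetic validation experiment
#'
#' Bundles the generating truth for a simulated plasma-assay validation:
#' the experimental [validation_design()], the per-level systematic bias
#' and day/within-day variability of the back-calculated concentrations, a
#' linear response model (internal-standard normalized peak-area ratio vs
#' concentration) for response-level simulation, and the extraction
#' recovery.
#'
#' Per-level vectors (`true_bias_pct`, `sigma_between_pct`,
#' `sigma_within_pct`) are recycled to the number of VS levels.
#'
#' @param design A [validation_design()].
#' @param true_bias_pct True relative bias per VS level, % of nominal.
#' @param sigma_between_pct Between-day SD per VS level, % of nominal.
#' @param sigma_within_pct Within-day SD per VS level, % of nominal;
#'   >= 0 (0 only for exactness checks — coverage simulation needs > 0).
#' @param calibration List with `intercept` (response units), `slope`
#'   (response units per ng/mL, > 0) and `response_cv` (multiplicative
#'   instrument-response noise CV) for response-level simulation. The
#'   per-level `sigma_within_pct`/`sigma_between_pct` describe the full
#'   preparation + measurement variability of back-calculated
#'   concentrations, so the default instrument noise is kept small (0.2%)
#'   rather than stacked on top of them.
#' @param recovery_mean True extraction yield as a fraction, in (0, 1.2].
#' @param recovery_cv CV of the per-batch extraction yield.
#' @param seed Integer seed; every generator call is reproducible given it.
#' @return An object of class `simulation_params`.
#' @seealso [default_simulation_params()] for packaged plasma-assay
#'   scenarios.
#' @export
simulation_params <- function(design,
                              true_bias_pct = 0,
                              sigma_between_pct = 2,
                              sigma_within_pct = 4,
                              calibration = list(intercept = 0.005,
                                                 slope = 0.004,
                                                 response_cv = 0.002),
                              recovery_mean = 0.88,
                              recovery_cv = 0.025,
                              seed = 1L) {
  stopifnot(inherits(design, "validation_design"))
  m <- length(design$vs_levels)
  true_bias_pct <- rep_len(as.numeric(true_bias_pct), m)
  sigma_between_pct <- rep_len(as.numeric(sigma_between_pct), m)
  sigma_within_pct <- rep_len(as.numeric(sigma_within_pct), m)
  if (any(sigma_within_pct < 0))
    stop("'sigma_within_pct' must be >= 0 at every level")
  if (any(sigma_between_pct < 0))
    stop("'sigma_between_pct' must be >= 0")
  if (!is.numeric(recovery_mean) || recovery_mean <= 0 || recovery_mean > 1.2)
    stop("'recovery_mean' must be a fraction in (0, 1.2]")
  if (recovery_cv < 0) stop("'recovery_cv' must be >= 0")
  stopifnot(is.list(calibration),
            all(c("intercept", "slope", "response_cv") %in% names(calibration)))
  if (calibration$slope <= 0) stop("calibration slope must be > 0")
  structure(
    list(design = design, true_bias_pct = true_bias_pct,
         sigma_between_pct = sigma_between_pct,
         sigma_within_pct = sigma_within_pct,
         calibration = calibration,
         recovery_mean = recovery_mean, recovery_cv = recovery_cv,
         seed = as.integer(seed)),
    class = "simulation_params")
}

#' Packaged plasma-assay simulation scenarios
#'
#' Returns [simulation_params()] emulating the validation of a
#' tyrosine-kinase-inhibitor plasma assay: 3 series (days), 6 concentration
#' levels, CS in triplicate and VS four times per day, beta = 0.95,
#' acceptance limits +/-15%. Per-level bias and variability are set to the
#' published per-level summary statistics of the corresponding assay
#' (see [tki_plasma_summary()]): the within-day SD equals the published
#' repeatability RSD, and the between-day SD is
#' `sqrt(max(RSD_IP^2 - RSD_r^2, 0))`. Extraction recovery defaults to the
#' published mean yield (0.88 for afatinib, 0.93 for ibrutinib) with a CV
#' matching the published spread of level means.
#'
#' @param analyte `"afatinib"` (levels 5-250 ng/mL) or `"ibrutinib"`
#'   (levels 5-400 ng/mL).
#' @param seed Integer seed.
#' @return A `simulation_params` object.
#' @export
default_simulation_params <- function(analyte = c("afatinib", "ibrutinib"),
                                      seed = 1L) {
  analyte <- match.arg(analyte)
  key <- c(afatinib = "AFA", ibrutinib = "IBR")[[analyte]]
  summ <- tki_plasma_summary(key)
  design <- validation_design(n_series = 3L, n_cs_reps = 3L, n_vs_reps = 4L,
                              cs_levels = summ$nominal_conc,
                              vs_levels = summ$nominal_conc,
                              beta = 0.95, lambda_pct = 15)
  rec <- if (key == "AFA") c(mean = 0.88, cv = 2.2 / 88) else c(mean = 0.93, cv = 9 / 93)
  simulation_params(
    design,
    true_bias_pct = summ$bias_pct,
    sigma_between_pct = sqrt(pmax(summ$rsd_ip_pct^2 - summ$rsd_r_pct^2, 0)),
    sigma_within_pct = summ$rsd_r_pct,
    recovery_mean = rec[["mean"]], recovery_cv = rec[["cv"]],
    seed = seed)
}

vs_frame <- function(design, analyte) {
  g <- expand.grid(rep = seq_len(design$n_vs_reps),
                   series = seq_len(design$n_series),
                   level = seq_along(design$vs_levels))
  data.frame(analyte = analyte, role = "VS",
             series = g$series, level = g$level)
}

#' Simulate back-calculated concentrations directly
#'
#' Concentration-level mode: skips the calibration layer and draws
#' back-calculated VS concentrations from the random-effects model the
#' validation statistics assume,
#' \deqn{x_{ij} = \mu_T (1 + \delta/100) + \tau_i + \varepsilon_{ij},}
#' with day effect \eqn{\tau_i \sim N(0, (\sigma_B\% \cdot \mu_T/100)^2)}
#' shared by all replicates of a level within a series (drawn independently
#' across levels) and residual
#' \eqn{\varepsilon_{ij} \sim N(0, (\sigma_W\% \cdot \mu_T/100)^2)}.
#'
#' @param params A [simulation_params()] object.
#' @param analyte Label stamped on the records.
#' @return An object of class `simulated_experiment`: list with
#'   `vs_records` (conc filled, no responses), `cs_records` (`NULL` in this
#'   mode), `recovery_records` (`NULL`), and `params` (the truth used).
#' @export
simulate_concentrations <- function(params, analyte = "synthetic") {
  stopifnot(inherits(params, "simulation_params"))
  d <- params$design
  vs <- with_private_seed(params$seed, {
    vs <- vs_frame(d, analyte)
    mu <- d$vs_levels[vs$level]
    tau_sd <- params$sigma_between_pct[vs$level] * mu / 100
    eps_sd <- params$sigma_within_pct[vs$level] * mu / 100
    # one day effect per series x level cell, shared by its replicates
    cell <- interaction(vs$series, vs$level, drop = TRUE)
    tau_cell <- stats::rnorm(nlevels(cell)) # standard normal, scaled per row
    tau <- tau_cell[as.integer(cell)] * tau_sd
    delta <- params$true_bias_pct[vs$level]
    vs$nominal_conc <- mu
    vs$response <- NA_real_
    vs$conc <- mu * (1 + delta / 100) + tau + stats::rnorm(nrow(vs), 0, eps_sd)
    vs
  })
  structure(list(cs_records = NULL, vs_records = vs[c(
    "analyte", "role", "series", "level", "nominal_conc", "response", "conc")],
    recovery_records = NULL, params = params),
    class = "simulated_experiment")
}

#' Simulate instrument responses through the full measurement chain
#'
#' Response-level mode: emulates internal-standard normalized peak-area
#' ratios so the whole pipeline (per-day calibration fit, back-calculation,
#' validation statistics) can run end to end. For a sample whose analyte
#' concentration at the instrument is `c`,
#' `response = intercept + slope * c * r_i * (1 + e)`, with multiplicative
#' instrument noise `e ~ N(0, response_cv)` and extraction yield
#' `r_i ~ N(recovery_mean, recovery_mean * recovery_cv)` drawn once per
#' extraction batch. CS and VS of one day are extracted together as one
#' batch, so the day's yield is common to standards and samples and
#' cancels in day-matched back-calculation — as it does in practice when
#' calibration standards are matrix-matched and extracted alongside the
#' samples.
#'
#' VS concentrations carry the per-level concentration-scale structure the
#' validation statistics estimate: `c = nominal * (1 + delta/100) + tau_i
#' + eps_ij` with day effect `tau_i` (SD `sigma_between_pct` % of nominal,
#' shared by a level's replicates within a day) and residual `eps_ij` (SD
#' `sigma_within_pct` % of nominal). CS concentrations are exact.
#'
#' Recovery records pair extracted peak areas (`slope * c * r * (1 + e)`,
#' one fresh extraction batch per series x level) with non-extracted
#' reference areas (`slope * c * (1 + e')`) at the same nominal
#' concentration.
#'
#' @inheritParams simulate_concentrations
#' @return A `simulated_experiment` with `cs_records` and `vs_records`
#'   carrying responses only, and `recovery_records`.
#' @export
simulate_responses <- function(params, analyte = "synthetic") {
  stopifnot(inherits(params, "simulation_params"))
  d <- params$design
  cal <- params$calibration
  out <- with_private_seed(params$seed, {
    rbatch <- function(k) stats::rnorm(k, params$recovery_mean,
                                       params$recovery_mean * params$recovery_cv)
    noise <- function(k) 1 + stats::rnorm(k, 0, cal$response_cv)
    # one extraction batch per day, shared by that day's CS and VS
    r_day <- rbatch(d$n_series)

    cs <- expand.grid(rep = seq_len(d$n_cs_reps),
                      series = seq_len(d$n_series),
                      level = seq_along(d$cs_levels))
    cs <- data.frame(analyte = analyte, role = "CS", series = cs$series,
                     level = cs$level, nominal_conc = d$cs_levels[cs$level])
    cs$response <- cal$intercept +
      cal$slope * cs$nominal_conc * r_day[cs$series] * noise(nrow(cs))
    cs$conc <- NA_real_

    vs <- vs_frame(d, analyte)
    mu <- d$vs_levels[vs$level]
    tau_sd <- params$sigma_between_pct[vs$level] * mu / 100
    eps_sd <- params$sigma_within_pct[vs$level] * mu / 100
    cell <- (vs$level - 1L) * d$n_series + vs$series
    tau <- stats::rnorm(d$n_series * length(d$vs_levels))[cell] * tau_sd
    c_true <- mu * (1 + params$true_bias_pct[vs$level] / 100) + tau +
      stats::rnorm(nrow(vs), 0, eps_sd)
    vs$nominal_conc <- mu
    vs$response <- cal$intercept +
      cal$slope * c_true * r_day[vs$series] * noise(nrow(vs))
    vs$conc <- NA_real_

    rec <- expand.grid(rep = seq_len(d$n_vs_reps),
                       series = seq_len(d$n_series),
                       level = seq_along(d$vs_levels))
    r_cell <- rbatch(d$n_series * length(d$vs_levels))
    cell <- (rec$level - 1L) * d$n_series + rec$series
    c_rec <- d$vs_levels[rec$level]
    rec <- data.frame(analyte = analyte, level = rec$level, series = rec$series,
                      area_extracted = cal$slope * c_rec * r_cell[cell] *
                        noise(nrow(rec)),
                      area_reference = cal$slope * c_rec * noise(nrow(rec)))
    list(cs = cs, vs = vs, rec = rec)
  })
  cols <- c("analyte", "role", "series", "level", "nominal_conc",
            "response", "conc")
  structure(list(cs_records = out$cs[cols],
                 vs_records = out$vs[cols],
                 recovery_records = out$rec, params = params),
            class = "simulated_experiment")
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat("Simulated validation experiment\n")
  cat(sprintf("  CS records: %d, VS records: %d, recovery records: %d\n",
              if (is.null(x$cs_records)) 0L else nrow(x$cs_records),
              if (is.null(x$vs_records)) 0L else nrow(x$vs_records),
              if (is.null(x$recovery_records)) 0L else nrow(x$recovery_records)))
  cat(sprintf("  seed: %d\n", x$params$seed))
  invisible(x)
}

#' Monte-Carlo coverage of the beta-expectation tolerance interval
#'
#' Estimates, by simulation, the probability that the computed tolerance
#' interval contains the relative error of one fresh future measurement
#' drawn from the same model — the defining property of a beta-expectation
#' interval, whose expected coverage should equal `beta`.
#'
#' For each of `n_experiments` replicate experiments at one concentration
#' level, a balanced `p x n` matrix of concentrations is drawn from the
#' day-effect model of [simulate_concentrations()], [level_statistics()]
#' turns it into a tolerance interval, one further observation is drawn
#' from the same model (new day effect, new residual), and the indicator of
#' its relative error falling inside the interval is recorded. The mean
#' indicator is returned.
#'
#' @param params A [simulation_params()]; the level given by `level` is
#'   simulated.
#' @param n_experiments Number of simulated experiments, >= 100.
#' @param seed Integer seed for the whole harness.
#' @param level Index of the VS level to simulate (default 1).
#' @return Mean coverage probability (scalar in \[0, 1\]), with attribute
#'   `n_experiments`.
#' @export
simulate_coverage <- function(params, n_experiments, seed, level = 1L) {
  stopifnot(inherits(params, "simulation_params"))
  if (n_experiments < 100L)
    stop("'n_experiments' must be >= 100 for a meaningful coverage estimate")
  d <- params$design
  p <- d$n_series
  n <- d$n_vs_reps
  beta <- d$beta
  mu <- d$vs_levels[level]
  delta <- params$true_bias_pct[level]
  tau_sd <- params$sigma_between_pct[level] * mu / 100
  eps_sd <- params$sigma_within_pct[level] * mu / 100
  with_private_seed(seed, {
    hits <- logical(n_experiments)
    for (b in seq_len(n_experiments)) {
      tau <- stats::rnorm(p, 0, tau_sd)
      x <- mu * (1 + delta / 100) + rep(tau, each = n) +
        stats::rnorm(p * n, 0, eps_sd)
      ls <- level_statistics(matrix(x, nrow = p, byrow = TRUE), mu, beta)
      x_new <- mu * (1 + delta / 100) + stats::rnorm(1, 0, tau_sd) +
        stats::rnorm(1, 0, eps_sd)
      rel_err <- 100 * (x_new - mu) / mu
      hits[b] <- rel_err >= ls$tol_lower_pct & rel_err <= ls$tol_upper_pct
    }
    structure(mean(hits), n_experiments = n_experiments)
  })
}
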