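#' Read replicate measurement records from a CSV file
#'
#' Reads a table of replicate observations, one row per measurement.
#' Required columns: `analyte`, `role` (`"CS"` or `"VS"`), `series`
#' (1-based series/day index), `level` (1-based level index),
#' `nominal_conc` (ng/mL), and at least one of `response` (instrument
#' response ratio, analyte area / internal-standard area) or `conc`
#' (back-calculated concentration, ng/mL). Numbers use the `.` decimal
#' separator; files are comma-separated UTF-8 with a header row.
#'
#' Row order is preserved. If the design is ragged (unequal replicate
#' counts across series x level cells within an analyte/role), the returned
#' data frame carries the attribute `ragged = TRUE` and a warning is
#' emitted; downstream variance-component statistics reject unbalanced
#' input, the reader only flags it.
#'
#' @param path Path to a CSV file.
#' @param role Optional filter, `"CS"` or `"VS"`; keeps only matching rows.
#' @return A `data.frame` of validated measurement records with attribute
#'   `ragged` (logical).
#' @export
read_measurements <- function(path, role = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("analyte", "role", "series", "level", "nominal_conc")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("measurement file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!any(c("response", "conc") %in% names(df)))
    stop("measurement file must contain a 'response' and/or 'conc' column")
  if (!"response" %in% names(df)) df$response <- NA_real_
  if (!"conc" %in% names(df)) df$conc <- NA_real_
  df$series <- as.integer(df$series)
  df$level <- as.integer(df$level)
  df$nominal_conc <- as.numeric(df$nominal_conc)
  df$response <- as.numeric(df$response)
  df$conc <- as.numeric(df$conc)

  if (!is.null(role)) {
    role <- match.arg(role, c("CS", "VS"))
    df <- df[df$role == role, , drop = FALSE]
    if (nrow(df) == 0L) stop("no rows with role '", role, "' in ", path)
    rownames(df) <- NULL
  }
  validate_measurements(df)
  attr(df, "ragged") <- is_ragged(df)
  if (attr(df, "ragged"))
    warning("ragged design in ", path,
            ": unequal replicate counts per series x level cell")
  df
}

validate_measurements <- function(df) {
  bad <- which(!is.finite(df$nominal_conc) | df$nominal_conc <= 0)
  if (length(bad) > 0L)
    stop("non-positive nominal_conc at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(!df$role %in% c("CS", "VS"))
  if (length(bad) > 0L)
    stop("role must be 'CS' or 'VS' at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(is.na(df$series) | df$series < 1L |
               is.na(df$level) | df$level < 1L)
  if (length(bad) > 0L)
    stop("series and level must be positive integers at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(is.na(df$response) & is.na(df$conc))
  if (length(bad) > 0L)
    stop("each record needs 'response' or 'conc' at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(df)
}

is_ragged <- function(df) {
  counts <- stats::aggregate(seq_len(nrow(df)),
                             by = df[c("analyte", "role", "series", "level")],
                             FUN = length)
  any(vapply(split(counts$x, paste(counts$analyte, counts$role)),
             function(k) length(unique(k)) > 1L, logical(1)))
}

#' Read extraction-recovery records from a CSV file
#'
#' One row per paired measurement: peak area of an extracted sample and the
#' peak area of a non-extracted standard solution at the same nominal
#' concentration. Required columns: `analyte`, `level`, `series`,
#' `area_extracted`, `area_reference`; both areas must be positive.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of recovery records.
#' @export
read_recovery <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("analyte", "level", "series", "area_extracted", "area_reference")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("recovery file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$area_extracted <- as.numeric(df$area_extracted)
  df$area_reference <- as.numeric(df$area_reference)
  bad <- which(!is.finite(df$area_extracted) | df$area_extracted <= 0 |
               !is.finite(df$area_reference) | df$area_reference <= 0)
  if (length(bad) > 0L)
    stop("peak areas must be positive at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  df
}

#' Write an accuracy profile to a CSV file
#'
#' Writes one data row per concentration level (level index, nominal
#' concentration, relative bias %, repeatability and intermediate-precision
#' RSD %, lower/upper beta-expectation tolerance limits %, validity flag),
#' preceded by `#`-prefixed header metadata (analyte, beta, lambda, p, n,
#' LLOQ/ULOQ, validated flag). [read_profile()] reads the format back;
#' the round trip preserves every numeric field to well below 1e-9.
#'
#' @param profile An [accuracy_profile][build_profile] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_profile()]
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "accuracy_profile"))
  if (nrow(profile$levels) == 0L)
    stop("refusing to write an empty accuracy profile")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c(analyte = profile$analyte,
            beta = format(profile$beta, digits = 17),
            lambda_pct = format(profile$lambda_pct, digits = 17),
            p = profile$p, n = profile$n,
            lloq = format(profile$lloq, digits = 17),
            uloq = format(profile$uloq, digits = 17),
            validated = profile$validated)
  writeLines(paste0("# ", names(meta), "=", unname(meta)), con)
  tab <- profile$levels
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) format(x, digits = 17))
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an accuracy profile written by [write_profile()]
#'
#' @param path Path to a profile CSV produced by [write_profile()].
#' @return An `accuracy_profile` object.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^# ", lines, value = TRUE)
  kv <- sub("^# ", "", meta_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  tab <- utils::read.csv(text = lines[!grepl("^# ", lines)],
                         stringsAsFactors = FALSE)
  tab$valid <- as.logical(tab$valid)
  structure(
    list(analyte = vals[["analyte"]],
         beta = as.numeric(vals[["beta"]]),
         lambda_pct = as.numeric(vals[["lambda_pct"]]),
         p = as.integer(vals[["p"]]),
         n = as.integer(vals[["n"]]),
         levels = tab,
         lloq = as.numeric(vals[["lloq"]]),
         uloq = as.numeric(vals[["uloq"]]),
         validated = as.logical(vals[["validated"]])),
    class = "accuracy_profile")
}

#' Write measurement or recovery records to CSV
#'
#' Plain `write.csv` wrappers that keep the on-disk schema in one place.
#'
#' @param records A `data.frame` of measurement or recovery records.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_measurements <- function(records, path) {
  cols <- c("analyte", "role", "series", "level", "nominal_conc",
            "response", "conc")
  utils::write.csv(records[intersect(cols, names(records))], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_measurements
#' @export
write_recovery <- function(records, path) {
  cols <- c("analyte", "level", "series", "area_extracted", "area_reference")
  utils::write.csv(records[intersect(cols, names(records))], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
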