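#' Length-of-stay sample container
#'
#' An ordered collection of integer durations (days, all `>= 1`) at a stated
#' aggregation level: one value per admission, or one value per patient (the
#' sum of that patient's admissions — readmissions make per-patient tails
#' heavier).
#'
#' @param values integer durations, all `>= 1`.
#' @param level `"per-admission"` or `"per-patient"`.
#' @param department department token (optional).
#' @return an object of class `"los_sample"`.
#' @export
los_sample <- function(values, level = c("per-admission", "per-patient"),
                       department = NA_character_) {
  level <- match.arg(level)
  if (length(values) == 0) stop("'values' must be non-empty", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 1) || any(values != round(values)))
    stop("'values' must be integers >= 1", call. = FALSE)
  structure(list(values = as.numeric(values), level = level,
                 department = department),
            class = "los_sample")
}

#' @export
print.los_sample <- function(x, ...) {
  cat(sprintf("LOS sample (%s%s): n = %d, mean = %.3f, median = %g, max = %g\n",
              x$level,
              if (is.na(x$department)) "" else paste0(", ", x$department),
              length(x$values), mean(x$values), stats::median(x$values),
              max(x$values)))
  invisible(x)
}

#' @export
length.los_sample <- function(x) length(x$values)

# Extract plain numeric values from an los_sample or numeric vector,
# validating the duration domain (min_value = 1 by default).
as_los_values <- function(sample, min_value = 1) {
  x <- if (inherits(sample, "los_sample")) sample$values else sample
  if (!is.numeric(x) || length(x) == 0)
    stop("sample must be a non-empty numeric vector or 'los_sample'", call. = FALSE)
  if (any(!is.finite(x))) stop("sample contains non-finite values", call. = FALSE)
  if (is.finite(min_value) && any(x < min_value))
    stop(sprintf("sample values must be >= %g", min_value), call. = FALSE)
  as.numeric(x)
}

registry_columns <- c("admission_id", "patient_id", "admission_date",
                      "discharge_date", "total_charge", "discharge_status",
                      "department")

#' Read an admission registry
#'
#' Reads a tabular registry (CSV, or XLSX first sheet when the readxl
#' package is installed) into an admission cohort. Column names can be
#' remapped through `column_map` (a named character vector,
#' `canonical = file_column`). Dates are parsed as ISO 8601 by default;
#' day/month/year strings ("13/11/2017") are accepted only under
#' `dmy = TRUE`, never auto-guessed, because of the d/m versus m/d
#' ambiguity. LOS is recomputed from the dates as
#' `max(1, discharge - admission)` (same-day discharges count as one day);
#' a stored LOS column is used for validation only and mismatches are
#' reported.
#'
#' Rows with unparseable dates or a discharge before the admission are
#' rejected, and returned in the `rejected` attribute with a per-row reason.
#'
#' @param path file path.
#' @param format `"csv"` or `"xlsx"`.
#' @param column_map named character vector remapping file columns onto the
#'   canonical schema (`admission_id`, `patient_id`, `admission_date`,
#'   `discharge_date`, `los`, `total_charge`, `discharge_status`,
#'   `department`).
#' @param dmy parse dates as day/month/year?
#' @return a data frame of class `"los_cohort"` with the canonical columns,
#'   `los` recomputed; attributes `rejected` (data frame of dropped rows
#'   with a `reason` column) and `los_mismatch` (row indices whose stored
#'   LOS disagreed with the dates).
#' @export
read_records <- function(path, format = c("csv", "xlsx"), column_map = NULL,
                         dmy = FALSE) {
  format <- match.arg(format)
  raw <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading XLSX requires the 'readxl' package", call. = FALSE)
      as.data.frame(readxl::read_excel(path, sheet = 1))
    })
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop(sprintf("mapped column '%s' not found in file", src), call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(registry_columns, names(raw))
  if (length(missing_cols) > 0)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  parse_date <- function(v) {
    if (inherits(v, "Date")) return(v)
    if (inherits(v, "POSIXt")) return(as.Date(v))
    if (dmy) as.Date(as.character(v), format = "%d/%m/%Y")
    else as.Date(as.character(v), format = "%Y-%m-%d")
  }
  adm <- parse_date(raw$admission_date)
  dis <- parse_date(raw$discharge_date)
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(adm) | is.na(dis)] <- "unparseable date"
  ok_dates <- !is.na(adm) & !is.na(dis)
  bad_order <- ok_dates & (dis < adm)
  reason[bad_order] <- "discharge before admission"
  keep <- is.na(reason)
  rejected <- cbind(raw[!keep, , drop = FALSE], reason = reason[!keep])
  rec <- raw[keep, , drop = FALSE]
  adm <- adm[keep]; dis <- dis[keep]
  los <- pmax(1, as.numeric(dis - adm))
  mism <- integer(0)
  if ("los" %in% names(rec)) {
    stored <- suppressWarnings(as.numeric(rec$los))
    mism <- which(!is.na(stored) & stored != los)
    if (length(mism) > 0)
      message(length(mism), " row(s) had a stored LOS disagreeing with the dates; dates take precedence")
  }
  out <- data.frame(admission_id = as.character(rec$admission_id),
                    patient_id = as.character(rec$patient_id),
                    admission_date = adm, discharge_date = dis,
                    los = los,
                    total_charge = as.numeric(rec$total_charge),
                    discharge_status = as.character(rec$discharge_status),
                    department = as.character(rec$department),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$admission_id))
    warning("duplicated admission_id values in cohort")
  attr(out, "rejected") <- rejected
  attr(out, "los_mismatch") <- mism
  class(out) <- c("los_cohort", "data.frame")
  out
}

#' Write an admission cohort to CSV
#'
#' Inverse of [read_records()] for the canonical schema; dates are written
#' as ISO 8601 so a round-trip reproduces the cohort exactly.
#'
#' @param cohort an admission cohort data frame.
#' @param path output CSV path.
#' @export
write_records <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$admission_date <- format(out$admission_date, "%Y-%m-%d")
  out$discharge_date <- format(out$discharge_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Per-admission and per-patient LOS samples
#'
#' `per_admission_sample` returns one duration per admission in the
#' department; `per_patient_sample` returns one duration per patient, the
#' sum of that patient's admission durations. Total LOS-days are conserved
#' between the two aggregation levels.
#'
#' @param cohort an admission cohort.
#' @param department department token.
#' @return an [los_sample()].
#' @export
per_admission_sample <- function(cohort, department) {
  rec <- cohort[cohort$department == department, , drop = FALSE]
  if (nrow(rec) == 0)
    stop(sprintf("department '%s' absent from the cohort", department), call. = FALSE)
  los_sample(rec$los, "per-admission", department)
}

#' @rdname per_admission_sample
#' @export
per_patient_sample <- function(cohort, department) {
  rec <- cohort[cohort$department == department, , drop = FALSE]
  if (nrow(rec) == 0)
    stop(sprintf("department '%s' absent from the cohort", department), call. = FALSE)
  agg <- stats::aggregate(rec$los, by = list(patient_id = rec$patient_id), FUN = sum)
  los_sample(agg$x, "per-patient", department)
}

status_positive <- c("complete recovery", "improved", "delivered", "d/c with mother")
status_negative <- c("dead", "not improved", "d/c separately")

#' Classify a discharge status label
#'
#' Case-normalized exact match against the positive outcome set ("Complete
#' recovery", "Improved", "Delivered", "D/C with mother") and the negative
#' one ("Dead", "Not improved", "D/C separately"); anything else is
#' `"unknown"`.
#'
#' @param status character vector of free-text status labels.
#' @return character vector: `"positive"`, `"negative"`, or `"unknown"`.
#' @export
classify_status <- function(status) {
  s <- tolower(trimws(as.character(status)))
  out <- rep("unknown", length(s))
  out[s %in% status_positive] <- "positive"
  out[s %in% status_negative] <- "negative"
  out
}

#' Descriptive statistics of a LOS sample
#'
#' Mean, median, variance, index of dispersion (variance over mean, 1 for a
#' Poisson law), skewness, kurtosis, and maximum. Moment estimators are the
#' biased (population) forms by default; kurtosis is Pearson (non-excess)
#' by default. Both conventions are switchable because they materially
#' affect cross-study comparisons.
#'
#' @param sample integer durations.
#' @param kurtosis `"pearson"` (non-excess) or `"excess"`.
#' @param variance `"population"` (denominator n) or `"sample"`
#'   (denominator n - 1; only the variance/dispersion entries are affected).
#' @return a list of class `"los_descriptives"` with fields `n`, `mean`,
#'   `median`, `variance`, `dispersion`, `skewness`, `kurtosis`, `max`, and
#'   the conventions used. Skewness/kurtosis are `NA` (with a warning) for a
#'   constant sample.
#' @export
descriptive_stats <- function(sample, kurtosis = c("pearson", "excess"),
                              variance = c("population", "sample")) {
  kurtosis <- match.arg(kurtosis)
  variance <- match.arg(variance)
  x <- as_los_values(sample)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  v <- if (variance == "population") m2 else m2 * n / (n - 1)
  if (m2 == 0) {
    warning("constant sample: skewness and kurtosis undefined")
    sk <- ku <- NA_real_
  } else {
    sk <- mean((x - mu)^3) / m2^1.5
    ku <- mean((x - mu)^4) / m2^2
    if (kurtosis == "excess") ku <- ku - 3
  }
  structure(list(n = n, mean = mu, median = stats::median(x), variance = v,
                 dispersion = if (mu > 0) v / mu else NA_real_,
                 skewness = sk, kurtosis = ku, max = max(x),
                 kurtosis_convention = kurtosis,
                 variance_convention = variance),
            class = "los_descriptives")
}

#' @export
print.los_descriptives <- function(x, ...) {
  cat(sprintf(paste0("n = %d  mean = %.4f  median = %g  variance = %.4f\n",
                     "dispersion = %.4f  skewness = %.4f  kurtosis = %.4f (%s)  max = %g\n"),
              x$n, x$mean, x$median, x$variance, x$dispersion,
              x$skewness, x$kurtosis, x$kurtosis_convention, x$max))
  invisible(x)
}

#' Frequency of a single LOS value, with neighbors
#'
#' Exact count and sample share at `value`, plus the counts at `value - 1`
#' and `value + 1` for context: a policy-induced spike (stays
#' administratively cut short at a round number of days) shows up as a value
#' far more frequent than both neighbors.
#'
#' @param sample integer durations.
#' @param value the LOS value of interest.
#' @return a list of class `"spike_frequency"`: `value`, `count`,
#'   `fraction`, `n`, `neighbors` (named counts at `value - 1`, `value + 1`).
#' @export
spike_frequency <- function(sample, value) {
  x <- as_los_values(sample)
  cnt <- sum(x == value)
  nb <- c(sum(x == value - 1), sum(x == value + 1))
  names(nb) <- c(value - 1, value + 1)
  structure(list(value = value, count = cnt, fraction = cnt / length(x),
                 n = length(x), neighbors = nb),
            class = "spike_frequency")
}

#' @export
print.spike_frequency <- function(x, ...) {
  cat(sprintf("LOS = %g: %d of %d admissions (%.2f%%); neighbors %s = %d, %s = %d\n",
              x$value, x$count, x$n, 100 * x$fraction,
              names(x$neighbors)[1], x$neighbors[1],
              names(x$neighbors)[2], x$neighbors[2]))
  invisible(x)
}
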