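# Hemodynamic records: one cardiac cycle of pressure and flow on a uniform,
# half-open time grid [0, T). The sample at t = T is excluded so that means
# and cycle integrals never double-count the wrap-around point.

#' Construct a hemodynamic record
#'
#' A record is a tibble with one row per time sample and columns `time_s`,
#' `pressure_mmHg` and `flow_ml_s`, covering exactly one cardiac cycle on a
#' uniform half-open grid `[0, T)`. The heart period `T` is implied by the
#' grid: `T = max(time_s) + dt`.
#'
#' @param time_s Time grid in seconds, strictly increasing and uniform.
#' @param pressure_mmHg Aortic pressure samples (mmHg).
#' @param flow_ml_s Aortic flow samples (ml/s).
#' @param subject_id Optional opaque subject label, stored as an attribute.
#'
#' @return A tibble of class `hemodynamic_record`.
#' @export
#' @examples
#' t <- seq(0, 0.99, by = 0.01)
#' rec <- hemodynamic_record(t, 100 + 20 * cos(2 * pi * t), 90 + 80 * sin(2 * pi * t))
#' record_period(rec)
hemodynamic_record <- function(time_s, pressure_mmHg, flow_ml_s, subject_id = NULL) {
  rec <- tibble(
    time_s = as.numeric(time_s),
    pressure_mmHg = as.numeric(pressure_mmHg),
    flow_ml_s = as.numeric(flow_ml_s)
  )
  validate_record(rec)
  attr(rec, "subject_id") <- subject_id
  class(rec) <- c("hemodynamic_record", class(rec))
  rec
}

validate_record <- function(rec) {
  if (nrow(rec) == 0) abort_fracwk("record is empty", "data")
  if (anyNA(rec$pressure_mmHg) || anyNA(rec$flow_ml_s) || anyNA(rec$time_s)) {
    abort_fracwk("record contains missing or non-numeric samples", "data")
  }
  check_uniform_grid(rec$time_s)
  invisible(rec)
}

#' Heart period of a record or waveform table
#'
#' The period is inferred from the uniform grid as `max(time_s) + dt`, the
#' half-open-interval convention under which the final sample sits one step
#' before the wrap-around point.
#'
#' @param data A data frame with a uniform `time_s` column.
#' @return Period in seconds.
#' @export
record_period <- function(data) {
  dt <- check_uniform_grid(data$time_s)
  data$time_s[nrow(data)] - data$time_s[1] + dt
}

#' Read a hemodynamic record from CSV
#'
#' Expects a header and at least three columns (time \[s\], pressure \[mmHg\],
#' flow \[ml/s\]); the first three columns are used positionally. The time
#' grid must be uniform; the record is taken to span exactly one cardiac
#' cycle.
#'
#' @param path Path to a CSV file.
#' @return A `hemodynamic_record` tibble.
#' @export
read_record <- function(path) {
  if (!file.exists(path)) {
    abort_fracwk(paste0("file not found: ", path), "format")
  }
  raw <- tryCatch(
    suppressWarnings(readr::read_csv(path, show_col_types = FALSE, progress = FALSE)),
    error = function(e) abort_fracwk(paste0("cannot parse CSV: ", conditionMessage(e)), "format")
  )
  if (ncol(raw) < 3) {
    abort_fracwk("CSV must have at least three columns (time, pressure, flow)", "format")
  }
  cols <- raw[, 1:3]
  if (!all(vapply(cols, is.numeric, logical(1)))) {
    abort_fracwk("first three CSV columns must be numeric", "format")
  }
  names(cols) <- c("time_s", "pressure_mmHg", "flow_ml_s")
  hemodynamic_record(cols$time_s, cols$pressure_mmHg, cols$flow_ml_s)
}

#' Write a hemodynamic record to CSV
#'
#' Emits the canonical dialect `time_s,pressure_mmHg,flow_ml_s` with a header
#' row; output is deterministic (bit-identical for identical inputs) and
#' round-trips through [read_record()] at full double precision.
#'
#' @param record A `hemodynamic_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  validate_record(record)
  out <- tibble(
    time_s = record$time_s,
    pressure_mmHg = record$pressure_mmHg,
    flow_ml_s = record$flow_ml_s
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Scalar waveform features of a record
#'
#' Computes the standard per-cycle haemodynamic summary: systolic (`sp`),
#' diastolic (`dp`) and pulse (`pp`) pressure in mmHg, mean blood pressure
#' (`mbp`, time average over the cycle), stroke volume (`sv`, the cycle
#' integral of flow by the periodic trapezoid rule, ml), heart rate
#' (`hr`, beats/min) and cardiac output (`co = sv * hr / 1000`, l/min).
#'
#' On the uniform half-open grid the periodic trapezoid rule reduces to
#' `dt * sum(flow)`, which is exact for piecewise-linear flow with breakpoints
#' on the grid.
#'
#' @param record A `hemodynamic_record`.
#' @return A one-row tibble with columns `sp`, `dp`, `pp`, `mbp`, `sv`, `hr`, `co`.
#' @export
#' @examples
#' t <- seq(0, 0.99, by = 0.01)
#' rec <- hemodynamic_record(t, 100 + 20 * cos(2 * pi * t), pmax(0, 300 * sin(2 * pi * t / 0.33)))
#' extract_features(rec)
extract_features <- function(record) {
  validate_record(record)
  dt <- check_uniform_grid(record$time_s)
  period <- record_period(record)
  sv <- dt * sum(record$flow_ml_s)
  hr <- 60 / period
  tibble(
    sp = max(record$pressure_mmHg),
    dp = min(record$pressure_mmHg),
    pp = max(record$pressure_mmHg) - min(record$pressure_mmHg),
    mbp = mean(record$pressure_mmHg),
    sv = sv,
    hr = hr,
    co = sv * hr / 1000
  )
}
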