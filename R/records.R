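#' Read and clean admission records
#'
#' Reads a CSV of de-identified admission records (one row per stay) and
#' applies the two cleaning rules used for short-stay admission-avoidance
#' units: rows with a missing (or unparseable) admission or discharge date
#' are excluded, and stays longer than 21 days are treated as recording
#' errors and excluded. Length of stay is `discharge_date - admission_date`
#' in whole days; day-case records (LOS 0) are retained.
#'
#' @param path Path to a CSV file with at least the columns `unit_id`,
#'   `admission_date`, `discharge_date` (ISO-8601 dates); `age`, `sex` and
#'   `municipality` are carried through when present.
#' @param unit_filter Optional unit id; when given, only that unit's rows are
#'   read (filtering happens before cleaning, so the cleaning log is
#'   unit-specific).
#' @param max_los Maximum credible length of stay in days (default 21).
#'
#' @return A tibble of cleaned records with a `cleaning_log` attribute, a
#'   named list with counts `missing_date`, `los_gt_max` and
#'   `negative_los`. Use [cleaning_log()] to retrieve it.
#' @seealso [clean_admission_records()] for the data-frame-in variant,
#'   [compute_daily_occupancy()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "unit_id,admission_date,discharge_date",
#'   "A,2017-01-01,2017-01-03",
#'   "A,2017-01-02,",
#'   "A,2017-01-01,2017-02-10"
#' ), path)
#' recs <- read_admission_records(path)
#' cleaning_log(recs)
read_admission_records <- function(path, unit_filter = NULL, max_los = 21) {
  if (!file.exists(path)) {
    abort(sprintf("Records file not found: '%s'", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("unit_id", "admission_date", "discharge_date")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Records file must have columns: %s (missing: %s)",
                  paste(required, collapse = ", "),
                  paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(unit_filter)) {
    raw <- dplyr::filter(raw, .data$unit_id %in% unit_filter)
  }
  clean_admission_records(raw, max_los = max_los)
}

#' Clean a data frame of admission records
#'
#' Applies the cleaning rules of [read_admission_records()] to an in-memory
#' data frame. Rules are applied in a fixed order (missing/unparseable dates
#' first, then the LOS filter) so cleaning logs are reproducible. Cleaning
#' is idempotent: re-cleaning a clean table removes nothing.
#'
#' @param records Data frame with `unit_id`, `admission_date`,
#'   `discharge_date` columns (dates as `Date` or ISO-8601 strings).
#' @inheritParams read_admission_records
#' @return A tibble with `Date` columns and a `cleaning_log` attribute.
#' @export
clean_admission_records <- function(records, max_los = 21) {
  records <- tibble::as_tibble(records)
  adm <- as_date_strict(records$admission_date)
  dis <- as_date_strict(records$discharge_date)
  missing_date <- is.na(adm) | is.na(dis)
  los <- as.numeric(dis - adm)
  negative <- !missing_date & los < 0
  too_long <- !missing_date & !negative & los > max_los
  keep <- !missing_date & !negative & !too_long

  out <- records[keep, , drop = FALSE]
  out$admission_date <- adm[keep]
  out$discharge_date <- dis[keep]
  if ("age" %in% names(out)) out$age <- as.numeric(out$age)
  log <- list(missing_date = sum(missing_date),
              los_gt_max = sum(too_long),
              negative_los = sum(negative))
  attr(out, "cleaning_log") <- log
  out
}

#' Retrieve the cleaning log of a cleaned record table
#'
#' @param records A tibble returned by [read_admission_records()] or
#'   [clean_admission_records()].
#' @return Named list of exclusion counts by reason.
#' @export
cleaning_log <- function(records) {
  attr(records, "cleaning_log") %||%
    list(missing_date = 0L, los_gt_max = 0L, negative_los = 0L)
}

#' Midnight-census occupancy series
#'
#' Computes the number of beds occupied at the midnight ending each day: a
#' patient counts on day `d` when `admission_date <= d` and
#' `discharge_date > d` (half-open convention, so a patient discharged on
#' day `d` is not counted at the midnight ending `d`). Under this convention
#' the column sum equals total patient-nights, i.e. the summed lengths of
#' stay of records falling inside the window.
#'
#' @param records Data frame of cleaned admission records.
#' @param start_date First day of the series (`Date` or ISO-8601 string).
#' @param n_days Number of consecutive days (>= 1).
#' @return A tibble with columns `date` and `occupancy` (non-negative
#'   integers), one row per day.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   unit_id = "A",
#'   admission_date = as.Date("2017-01-01"),
#'   discharge_date = as.Date("2017-01-03")
#' )
#' compute_daily_occupancy(recs, "2017-01-01", 3)
compute_daily_occupancy <- function(records, start_date, n_days) {
  n_days <- check_count(n_days, "n_days", min = 1L)
  start_date <- as_date_strict(start_date)
  if (is.na(start_date)) abort("`start_date` is not a parseable date.")
  days <- start_date + seq_len(n_days) - 1L
  adm <- as_date_strict(records$admission_date)
  dis <- as_date_strict(records$discharge_date)
  counts <- vapply(days, function(d) sum(adm <= d & dis > d, na.rm = TRUE),
                   numeric(1))
  tibble::tibble(date = days, occupancy = as.integer(counts))
}

#' Absolute mean occupancy of an occupancy series
#'
#' The study's key performance indicator: the average midnight census over
#' the covered days (conventionally 365). Annual patient days equal
#' `absolute_mean_occupancy * 365` on a 365-day series.
#'
#' @param occupancy A tibble with an `occupancy` column, as produced by
#'   [compute_daily_occupancy()].
#' @return A single number.
#' @export
absolute_mean_occupancy <- function(occupancy) {
  mean(occupancy$occupancy)
}

#' Write a result table to CSV
#'
#' Writes any result tibble (simulation summaries, Erlang results, scenario
#' rows) as plain CSV with a stable column order, one row per unit or
#' scenario in input order. Numeric fields round-trip through
#' [readr::read_csv()].
#'
#' @param summary A data frame of results.
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_summary <- function(summary, path) {
  summary <- tibble::as_tibble(summary)
  readr::write_csv(summary, path, progress = FALSE)
  invisible(summary)
}

#' Plot a midnight-census occupancy series
#'
#' @param occupancy Tibble with `date` and `occupancy` columns.
#' @param capacity Optional bed capacity drawn as a dashed reference line.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(occupancy, capacity = NULL) {
  p <- ggplot2::ggplot(occupancy, ggplot2::aes(x = .data$date,
                                               y = .data$occupancy)) +
    ggplot2::geom_step(colour = "#2c6e91") +
    ggplot2::labs(x = NULL, y = "Beds occupied at midnight") +
    ggplot2::theme_minimal()
  if (!is.null(capacity)) {
    p <- p + ggplot2::geom_hline(yintercept = capacity, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}
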