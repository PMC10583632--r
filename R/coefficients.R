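#' Admission sub-model coefficients
#'
#' Container for the linear admission sub-model: the expected number of
#' potential admissions on a day is `intercept + weekday effect + month
#' effect` (additive, in admissions/day), with Monday and January as
#' implicit reference levels (effect 0, never stored). Negative linear
#' predictions are clamped at zero downstream (see [admission_mean()]),
#' since the prediction feeds a Poisson draw.
#'
#' @param intercept Expected admissions/day on a Monday in January.
#' @param weekday_effects Named numeric vector of additive effects for
#'   `Tuesday` .. `Sunday` (missing days default to 0).
#' @param month_effects Named numeric vector of additive effects for
#'   `February` .. `December` (missing months default to 0).
#' @param std_errors Optional tibble with columns `term`, `estimate`,
#'   `std.error` (attached by [fit_admission_model()]).
#' @param fit_info Optional named list of fit diagnostics.
#' @return An object of class `admission_coeffs`.
#' @export
#' @examples
#' ac <- admission_coeffs(3, weekday_effects = c(Saturday = -0.8),
#'                        month_effects = c(July = -0.5))
#' admission_mean(ac, as.Date("2017-01-07"))  # a Saturday in January: 2.2
admission_coeffs <- function(intercept, weekday_effects = NULL,
                             month_effects = NULL, std_errors = NULL,
                             fit_info = NULL) {
  structure(
    list(intercept = as.numeric(intercept),
         weekday_effects = full_effects(weekday_effects, WEEKDAY_LEVELS),
         month_effects = full_effects(month_effects, MONTH_LEVELS),
         std_errors = std_errors,
         fit_info = fit_info),
    class = "admission_coeffs")
}

#' Discharge sub-model coefficients
#'
#' Container for the logistic discharge sub-model: the probability that an
#' inpatient is discharged during the coming day is
#' `plogis(intercept + weekday effect)`, where the weekday is that of the
#' coming day and Monday is the reference level. Effects are on the log-odds
#' scale.
#'
#' @param intercept Log-odds of next-day discharge on a Monday.
#' @param weekday_effects Named numeric vector of log-odds effects for
#'   `Tuesday` .. `Sunday` (missing days default to 0).
#' @inheritParams admission_coeffs
#' @return An object of class `discharge_coeffs`.
#' @export
#' @examples
#' dc <- discharge_coeffs(qlogis(1/3))
#' discharge_probability(dc, as.Date("2017-01-02"))  # 1/3 on a Monday
discharge_coeffs <- function(intercept, weekday_effects = NULL,
                             std_errors = NULL, fit_info = NULL) {
  structure(
    list(intercept = as.numeric(intercept),
         weekday_effects = full_effects(weekday_effects, WEEKDAY_LEVELS),
         std_errors = std_errors,
         fit_info = fit_info),
    class = "discharge_coeffs")
}

# Expand a sparse named effect vector to the full level set, reference
# included as 0. Unknown names are an error (typo guard).
full_effects <- function(effects, levels) {
  out <- setNames(numeric(length(levels)), levels)
  if (is.null(effects) || length(effects) == 0) return(out)
  if (is.null(names(effects)) || any(!nzchar(names(effects)))) {
    abort("Effect vectors must be named by level (e.g. c(Saturday = -0.8)).")
  }
  bad <- setdiff(names(effects), levels)
  if (length(bad) > 0) {
    abort(sprintf("Unknown level(s): %s", paste(bad, collapse = ", ")))
  }
  if (!all(is.finite(effects))) abort("All effects must be finite.")
  out[names(effects)] <- as.numeric(effects)
  out
}

#' Expected potential admissions on given dates
#'
#' Evaluates the linear admission sub-model `intercept + weekday effect +
#' month effect` for each date and clamps negative predictions at zero (a
#' negative value is not a valid Poisson mean; the linear fit can produce
#' one at sparse parameter combinations).
#'
#' @param coeffs An [admission_coeffs()] object.
#' @param dates Vector of dates.
#' @param warn_negative Emit a warning when clamping occurs (default FALSE).
#' @return Numeric vector of non-negative expected daily admission counts.
#' @export
admission_mean <- function(coeffs, dates, warn_negative = FALSE) {
  stopifnot(inherits(coeffs, "admission_coeffs"))
  dates <- as_date_strict(dates)
  mu <- coeffs$intercept +
    coeffs$weekday_effects[wday_index(dates)] +
    coeffs$month_effects[month_index(dates)]
  if (warn_negative && any(mu < 0)) {
    warn(sprintf("Clamped %d negative predicted admission mean(s) at 0.",
                 sum(mu < 0)))
  }
  unname(pmax(mu, 0))
}

#' Probability of discharge during the coming day
#'
#' Inverse-logit of `intercept + weekday effect`, where the weekday effect
#' is indexed by the date of the coming 24-hour period (the midnight
#' decision concerns the day that is starting).
#'
#' @param coeffs A [discharge_coeffs()] object.
#' @param dates Vector of dates (the day the discharge would fall on).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
discharge_probability <- function(coeffs, dates) {
  stopifnot(inherits(coeffs, "discharge_coeffs"))
  dates <- as_date_strict(dates)
  unname(plogis(coeffs$intercept + coeffs$weekday_effects[wday_index(dates)]))
}

sparse_effects <- function(effects, reference) {
  keep <- setdiff(names(effects), reference)
  as.list(effects[keep])
}

#' Write calibrated coefficients to a JSON file
#'
#' Stores one or more units' admission and discharge coefficient sets as
#' structured JSON. Reference levels (Monday, January) are implicitly zero
#' and never stored.
#'
#' @param coeffs Named list, one element per unit, each a list with elements
#'   `admission` ([admission_coeffs()]) and `discharge`
#'   ([discharge_coeffs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_coefficients()]
#' @export
write_coefficients <- function(coeffs, path) {
  payload <- purrr::map(coeffs, function(u) {
    list(
      admission = list(
        intercept = u$admission$intercept,
        weekday_effects = sparse_effects(u$admission$weekday_effects,
                                         "Monday"),
        month_effects = sparse_effects(u$admission$month_effects, "January")
      ),
      discharge = list(
        intercept = u$discharge$intercept,
        weekday_effects = sparse_effects(u$discharge$weekday_effects,
                                         "Monday")
      )
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read coefficients written by [write_coefficients()]
#'
#' @param path JSON file path.
#' @return Named list per unit with `admission` and `discharge` coefficient
#'   objects.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) abort(sprintf("Coefficient file not found: '%s'", path))
  payload <- jsonlite::read_json(path)
  purrr::map(payload, function(u) {
    list(
      admission = admission_coeffs(
        u$admission$intercept,
        weekday_effects = unlist(u$admission$weekday_effects),
        month_effects = unlist(u$admission$month_effects)),
      discharge = discharge_coeffs(
        u$discharge$intercept,
        weekday_effects = unlist(u$discharge$weekday_effects))
    )
  })
}

#' @export
print.admission_coeffs <- function(x, ...) {
  cat("<admission_coeffs>  expected potential admissions/day\n")
  cat(sprintf("  intercept (Mon, Jan): %.4f\n", x$intercept))
  cat("  weekday effects:",
      paste(sprintf("%s %+.3f", substr(WEEKDAY_LEVELS[-1], 1, 3),
                    x$weekday_effects[-1]), collapse = ", "), "\n")
  cat("  month effects:  ",
      paste(sprintf("%s %+.3f", substr(MONTH_LEVELS[-1], 1, 3),
                    x$month_effects[-1]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.discharge_coeffs <- function(x, ...) {
  cat("<discharge_coeffs>  log-odds of next-day discharge\n")
  cat(sprintf("  intercept (Mon): %.4f  (p = %.3f)\n", x$intercept,
              plogis(x$intercept)))
  cat("  weekday effects:",
      paste(sprintf("%s %+.3f", substr(WEEKDAY_LEVELS[-1], 1, 3),
                    x$weekday_effects[-1]), collapse = ", "), "\n")
  invisible(x)
}

coeffs_tidy <- function(x) {
  if (!is.null(x$std_errors)) return(tibble::as_tibble(x$std_errors))
  terms <- c("(Intercept)",
             paste0("weekday", names(x$weekday_effects[-1])),
             if (!is.null(x$month_effects))
               paste0("month", names(x$month_effects[-1])))
  est <- c(x$intercept, x$weekday_effects[-1],
           if (!is.null(x$month_effects)) x$month_effects[-1])
  tibble::tibble(term = terms, estimate = unname(est),
                 std.error = NA_real_)
}

#' Tidy method for admission coefficients
#' @param x An `admission_coeffs` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.admission_coeffs <- function(x, ...) coeffs_tidy(x)

#' Tidy method for discharge coefficients
#' @param x A `discharge_coeffs` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.discharge_coeffs <- function(x, ...) {
  x$month_effects <- NULL
  coeffs_tidy(x)
}

#' Glance method for admission coefficients
#' @param x An `admission_coeffs` object.
#' @param ... Unused.
#' @return One-row tibble of fit diagnostics (empty fields when the object
#'   was constructed rather than fitted).
#' @export
glance.admission_coeffs <- function(x, ...) {
  fi <- x$fit_info %||% list()
  tibble::tibble(n_days = fi$n_days %||% NA_integer_,
                 n_retained = fi$n_retained %||% NA_integer_,
                 prop_excluded = fi$prop_excluded %||% NA_real_,
                 sigma = fi$sigma %||% NA_real_,
                 r.squared = fi$r.squared %||% NA_real_)
}

#' Glance method for discharge coefficients
#' @param x A `discharge_coeffs` object.
#' @param ... Unused.
#' @return One-row tibble of fit diagnostics.
#' @export
glance.discharge_coeffs <- function(x, ...) {
  fi <- x$fit_info %||% list()
  tibble::tibble(n_patient_days = fi$n_patient_days %||% NA_integer_,
                 n_discharges = fi$n_discharges %||% NA_integer_,
                 deviance = fi$deviance %||% NA_real_,
                 separation = fi$separation %||% FALSE)
}
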