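#' Select low-occupancy calibration days
#'
#' The admission sub-model is meant to estimate *potential* (unconstrained)
#' demand, but on days when a unit is near capacity the recorded admission
#' counts are censored by bed availability. Restricting the admission
#' regression to days at or below the unit's median midnight occupancy keeps
#' only days where beds were freely available while retaining at least half
#' of the data (ties with the median are retained).
#'
#' @param occupancy Tibble with `date` and `occupancy` columns
#'   ([compute_daily_occupancy()]).
#' @return The input rows whose occupancy is at or below the median, as a
#'   tibble.
#' @export
select_low_occupancy_days <- function(occupancy) {
  if (nrow(occupancy) == 0) abort("Occupancy series is empty.")
  med <- median(occupancy$occupancy)
  dplyr::filter(occupancy, .data$occupancy <= med)
}

daily_admission_counts <- function(records, days) {
  adm <- as_date_strict(records$admission_date)
  tibble::tibble(
    date = days,
    admissions = vapply(days, function(d) sum(adm == d), numeric(1))
  )
}

#' Fit the admission sub-model
#'
#' Ordinary least-squares regression of the daily admission count on weekday
#' and month as categorical predictors (reference Monday / January), over a
#' supplied set of calibration days. Days with zero admissions enter the
#' regression as zeros: omitting them would bias the intercept upward.
#' Factor levels never observed among the calibration days are dropped with
#' a warning (their effect is not estimable and is treated as zero).
#'
#' @param records Cleaned admission records (one unit).
#' @param retained_days A `Date` vector, or a tibble with a `date` column
#'   (e.g. the output of [select_low_occupancy_days()]); admission counts
#'   are computed on exactly these days.
#' @return An [admission_coeffs()] object with standard errors (`tidy()`)
#'   and fit diagnostics (`glance()`).
#' @export
fit_admission_model <- function(records, retained_days) {
  if (is.data.frame(retained_days)) retained_days <- retained_days$date
  retained_days <- as_date_strict(retained_days)
  if (anyNA(retained_days)) abort("`retained_days` contains unparseable dates.")

  df <- daily_admission_counts(records, retained_days)
  df$wd <- weekday_factor(df$date)
  df$mo <- month_factor(df$date)

  # drop levels with no observations so lm() does not produce NA estimates
  dropped <- c(setdiff(WEEKDAY_LEVELS, unique(as.character(df$wd))),
               setdiff(MONTH_LEVELS, unique(as.character(df$mo))))
  if (length(dropped) > 0) {
    warn(sprintf("No calibration days for level(s) %s; effect(s) set to 0.",
                 paste(dropped, collapse = ", ")))
  }
  df$wd <- droplevels(df$wd)
  df$mo <- droplevels(df$mo)

  n_par <- 1L + (nlevels(df$wd) - 1L) + (nlevels(df$mo) - 1L)
  if (nrow(df) < n_par) {
    abort(sprintf(
      "Cannot fit admission model: %d retained day(s) for %d parameters (%d short).",
      nrow(df), n_par, n_par - nrow(df)))
  }

  form <- if (nlevels(df$mo) > 1 && nlevels(df$wd) > 1) {
    admissions ~ wd + mo
  } else if (nlevels(df$wd) > 1) {
    admissions ~ wd
  } else if (nlevels(df$mo) > 1) {
    admissions ~ mo
  } else {
    admissions ~ 1
  }
  fit <- lm(form, data = df)
  cf <- coef(fit)
  se_tbl <- tibble::tibble(
    term = names(cf),
    estimate = unname(cf),
    std.error = unname(sqrt(diag(vcov(fit))))
  )
  wd_eff <- extract_level_effects(cf, "wd", WEEKDAY_LEVELS)
  mo_eff <- extract_level_effects(cf, "mo", MONTH_LEVELS)
  s <- summary(fit)
  admission_coeffs(
    intercept = unname(cf["(Intercept)"]),
    weekday_effects = wd_eff,
    month_effects = mo_eff,
    std_errors = se_tbl,
    fit_info = list(n_retained = nrow(df), sigma = s$sigma,
                    r.squared = s$r.squared)
  )
}

extract_level_effects <- function(cf, prefix, levels) {
  idx <- grep(paste0("^", prefix), names(cf))
  if (length(idx) == 0) return(NULL)
  eff <- cf[idx]
  names(eff) <- sub(paste0("^", prefix), "", names(eff))
  eff
}

#' Expand stays into inpatient-day discharge outcomes
#'
#' For every midnight a patient is present, emits one row with the date of
#' the following day (the day the discharge decision concerns) and a binary
#' outcome: 1 if the patient was discharged during that day, 0 otherwise.
#' A patient admitted on day `d` and discharged on day `e` is at risk on
#' days `d + 1, ..., e`; day-case records (LOS 0) contribute no rows.
#'
#' @param records Cleaned admission records.
#' @return Tibble with columns `date`, `discharged` (0/1) and `weekday`.
#' @export
expand_inpatient_days <- function(records) {
  adm <- as_date_strict(records$admission_date)
  dis <- as_date_strict(records$discharge_date)
  los <- as.integer(dis - adm)
  keep <- which(los >= 1)
  dates <- purrr::map(keep, function(i) adm[i] + seq_len(los[i]))
  outcome <- purrr::map(keep, function(i) {
    c(rep(0L, los[i] - 1L), 1L)
  })
  dates <- as.Date(unlist(dates), origin = "1970-01-01")
  tibble::tibble(
    date = dates,
    discharged = unlist(outcome) %||% integer(0),
    weekday = weekday_factor(dates)
  )
}

#' Fit the discharge sub-model
#'
#' Maximum-likelihood logistic regression of the daily discharge indicator
#' on weekday of the coming day (sole predictor, reference Monday), over
#' all inpatient-days — no occupancy filtering is applied, because
#' discharges are not censored by bed capacity. Complete separation (a
#' weekday whose inpatient-days are all discharges or all non-discharges)
#' yields a warning; the affected effect is reported with its large
#' standard error.
#'
#' @param records Cleaned admission records (one unit).
#' @return A [discharge_coeffs()] object with standard errors and fit
#'   diagnostics.
#' @export
fit_discharge_model <- function(records) {
  df <- expand_inpatient_days(records)
  if (nrow(df) == 0) abort("No inpatient-days: cannot fit discharge model.")
  cell <- tapply(df$discharged, df$weekday, mean)
  cell <- cell[!is.na(cell)]
  separated <- any(cell == 0) || any(cell == 1)
  if (separated) {
    warn(paste("Complete separation: at least one weekday has all-0 or all-1",
               "discharge outcomes; its effect has a very large standard error."))
  }
  df$weekday <- droplevels(df$weekday)
  fit <- suppressWarnings(
    glm(discharged ~ weekday, family = binomial(), data = df)
  )
  cf <- coef(fit)
  se_tbl <- tibble::tibble(
    term = names(cf),
    estimate = unname(cf),
    std.error = unname(sqrt(diag(vcov(fit))))
  )
  wd_eff <- extract_level_effects(cf, "weekday", WEEKDAY_LEVELS)
  discharge_coeffs(
    intercept = unname(cf["(Intercept)"]),
    weekday_effects = wd_eff,
    std_errors = se_tbl,
    fit_info = list(n_patient_days = nrow(df),
                    n_discharges = sum(df$discharged),
                    deviance = fit$deviance,
                    separation = separated)
  )
}

#' Calibrate both sub-models for one or more units
#'
#' Convenience pipeline: for each unit in `records`, computes the midnight
#' census over the calibration window, optionally restricts the admission
#' regression to low-occupancy (at-or-below-median) days, and fits both
#' sub-models. The low-occupancy filter corrects for capacity censoring in
#' empirical data; disable it for data known to be unconstrained.
#'
#' @param records Cleaned admission records (possibly several units).
#' @param start_date First day of the calibration window.
#' @param n_days Window length in days (default 365).
#' @param low_occupancy_filter Restrict the admission fit to days at or
#'   below the median census (default TRUE).
#' @return Named list per unit: `admission`, `discharge`, and `diagnostics`
#'   (days retained, proportion excluded), suitable for
#'   [write_coefficients()].
#' @export
calibrate_units <- function(records, start_date, n_days = 365,
                            low_occupancy_filter = TRUE) {
  units <- unique(records$unit_id)
  out <- purrr::map(units, function(u) {
    rec_u <- dplyr::filter(records, .data$unit_id == u)
    occ <- compute_daily_occupancy(rec_u, start_date, n_days)
    days <- if (low_occupancy_filter) select_low_occupancy_days(occ) else occ
    adm <- fit_admission_model(rec_u, days)
    adm$fit_info$n_days <- nrow(occ)
    adm$fit_info$prop_excluded <- 1 - nrow(days) / nrow(occ)
    dis <- fit_discharge_model(rec_u)
    list(admission = adm, discharge = dis,
         diagnostics = list(n_days = nrow(occ), n_retained = nrow(days),
                            prop_excluded = 1 - nrow(days) / nrow(occ)))
  })
  setNames(out, units)
}
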