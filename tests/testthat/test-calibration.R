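test_that("low-occupancy day selection keeps days at or below the median", {
  occ <- tibble::tibble(date = as.Date("2017-01-01") + 0:4,
                        occupancy = 1:5)
  expect_equal(select_low_occupancy_days(occ)$occupancy, 1:3)

  flat <- tibble::tibble(date = as.Date("2017-01-01") + 0:9,
                         occupancy = rep(4L, 10))
  expect_equal(nrow(select_low_occupancy_days(flat)), 10L)

  bimodal <- tibble::tibble(date = as.Date("2017-01-01") + 0:3,
                            occupancy = c(0L, 0L, 10L, 10L))
  expect_equal(select_low_occupancy_days(bimodal)$occupancy, c(0L, 0L))

  # ties counted as retained: never fewer than half the days
  set.seed(77)
  for (i in 1:10) {
    o <- tibble::tibble(date = as.Date("2017-01-01") + 0:99,
                        occupancy = rpois(100, 5))
    expect_gte(nrow(select_low_occupancy_days(o)), 50)
  }
})

test_that("constant admissions give an exact intercept and zero effects", {
  # two admissions every day for a full year
  days <- as.Date("2017-01-01") + 0:364
  recs <- tibble::tibble(
    unit_id = "A",
    admission_date = rep(days, each = 2),
    discharge_date = rep(days, each = 2) + 1
  )
  fit <- fit_admission_model(recs, days)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(unname(fit$weekday_effects), rep(0, 7), tolerance = 1e-10)
  expect_equal(unname(fit$month_effects), rep(0, 12), tolerance = 1e-10)
  expect_false(is.null(tidy(fit)$std.error))
})

test_that("too few calibration days for the parameter count is fatal", {
  recs <- tibble::tibble(unit_id = "A",
                         admission_date = as.Date("2017-01-01"),
                         discharge_date = as.Date("2017-01-02"))
  # two days spanning a month boundary: 3 parameters, 2 observations
  deficit <- as.Date(c("2017-01-31", "2017-02-01"))
  expect_error(
    suppressWarnings(fit_admission_model(recs, deficit)),
    "retained day"
  )
})

test_that("admission mean sums effects, clamps at zero, ignores calendar year", {
  zero <- admission_coeffs(0)
  expect_equal(admission_mean(zero, as.Date("2017-06-15")), 0)

  ac <- admission_coeffs(3, weekday_effects = c(Saturday = -0.8),
                         month_effects = c(July = -0.5))
  sat_jan <- as.Date("2017-01-07")  # a Saturday in January
  expect_equal(lubridate::wday(sat_jan, week_start = 1), 6)
  expect_equal(admission_mean(ac, sat_jan), 2.2)
  sat_jul <- as.Date("2017-07-01")  # a Saturday in July
  expect_equal(admission_mean(ac, sat_jul), 3 - 0.8 - 0.5)

  low <- admission_coeffs(0.1, weekday_effects = c(Sunday = -0.5))
  expect_equal(admission_mean(low, as.Date("2017-01-01")), 0)  # a Sunday
  expect_warning(admission_mean(low, as.Date("2017-01-01"),
                                warn_negative = TRUE), "Clamped")

  # invariant to date shifts that preserve weekday and month
  mon_jan_17 <- as.Date("2017-01-02")
  mon_jan_18 <- as.Date("2018-01-01")
  expect_equal(lubridate::wday(mon_jan_18, week_start = 1), 1)
  expect_equal(admission_mean(ac, mon_jan_17), admission_mean(ac, mon_jan_18))
})

test_that("discharge probability is the inverse-logit of intercept plus weekday effect", {
  expect_equal(discharge_probability(discharge_coeffs(0),
                                     as.Date("2017-05-10")), 0.5)
  dc <- discharge_coeffs(qlogis(0.3))
  expect_equal(discharge_probability(dc, as.Date("2017-01-02")), 0.3)  # Monday
  expect_lt(discharge_probability(discharge_coeffs(-30),
                                  as.Date("2017-01-02")), 1e-10)
  fri <- discharge_coeffs(qlogis(0.3), c(Friday = 1))
  expect_equal(discharge_probability(fri, as.Date("2017-01-06")),
               plogis(qlogis(0.3) + 1))
})

test_that("inpatient-day expansion indexes outcomes by the day of the discharge decision", {
  recs <- tibble::tibble(
    unit_id = "A",
    admission_date = as.Date(c("2017-01-02", "2017-01-02")),  # Mondays
    discharge_date = as.Date(c("2017-01-05", "2017-01-02"))
  )
  days <- expand_inpatient_days(recs)
  # 3-night stay: at risk Tue, Wed, Thu; discharged on the Thursday
  expect_equal(nrow(days), 3L)
  expect_equal(as.character(days$weekday),
               c("Tuesday", "Wednesday", "Thursday"))
  expect_equal(days$discharged, c(0L, 0L, 1L))
})

test_that("the admission fit recovers known truth on unconstrained synthetic years", {
  truth_ac <- admission_coeffs(3, weekday_effects = c(Saturday = -0.8),
                               month_effects = c(July = -0.5))
  sc <- make_scenario(
    preset = "custom",
    units = unit_spec("X", 30L),
    admission_coeffs = list(X = truth_ac),
    discharge_coeffs = list(X = discharge_coeffs(qlogis(1 / 3))),
    years = 6, seed = 20260901, capacity_mode = "unconstrained"
  )
  gen <- generate_records(sc)
  fit <- fit_admission_model(gen$records, gen$occupancy$date)
  est <- tidy(fit)

  truth_by_term <- c(
    "(Intercept)" = 3, wdSaturday = -0.8, moJuly = -0.5)
  for (tm in est$term) {
    tr <- if (tm %in% names(truth_by_term)) truth_by_term[[tm]] else 0
    row <- est[est$term == tm, ]
    # named (non-zero) effects within 2 SE; the many true-zero effects at 3 SE
    k <- if (tm %in% names(truth_by_term)) 2 else 3
    expect_lt(abs(row$estimate - tr), k * row$std.error)
  }
})

test_that("the discharge fit recovers a constant rate and a boosted Friday", {
  sc <- const_scenario(mu = 3, p = 1 / 3, capacity = 30L, years = 6,
                       seed = 20260902)
  gen <- generate_records(sc)
  fit <- fit_discharge_model(gen$records)
  est <- tidy(fit)
  int <- est[est$term == "(Intercept)", ]
  expect_lt(abs(int$estimate - qlogis(1 / 3)), 2 * int$std.error)
  for (tm in est$term[-1]) {
    row <- est[est$term == tm, ]
    expect_lt(abs(row$estimate), 3 * row$std.error)
  }

  # Friday boosted to 0.6, other days 0.3
  boost <- make_scenario(
    preset = "custom",
    units = unit_spec("X", 30L),
    admission_coeffs = list(X = admission_coeffs(3)),
    discharge_coeffs = list(
      X = discharge_coeffs(qlogis(0.3),
                           c(Friday = qlogis(0.6) - qlogis(0.3)))),
    years = 6, seed = 20260903, capacity_mode = "unconstrained"
  )
  gen2 <- generate_records(boost)
  fit2 <- fit_discharge_model(gen2$records)
  p_fri <- plogis(fit2$intercept + fit2$weekday_effects[["Friday"]])
  expect_lt(abs(p_fri - 0.6), 0.04)
  expect_lt(abs(plogis(fit2$intercept) - 0.3), 0.04)
})

test_that("complete separation is warned about", {
  days <- as.Date("2017-01-01") + 0:59
  recs <- tibble::tibble(unit_id = "A", admission_date = days,
                         discharge_date = days + 1)  # every stay one night
  expect_warning(fit_discharge_model(recs), "separation")
})

test_that("coefficient files round-trip without storing reference levels", {
  coeffs <- list(
    A = list(
      admission = admission_coeffs(2.5, c(Sunday = -0.7), c(July = -0.3)),
      discharge = discharge_coeffs(qlogis(0.25), c(Friday = 0.4))
    )
  )
  path <- tempfile(fileext = ".json")
  write_coefficients(coeffs, path)
  txt <- paste(readLines(path), collapse = "")
  expect_false(grepl("Monday|January", txt))
  back <- read_coefficients(path)
  expect_equal(back$A$admission$intercept, 2.5)
  expect_equal(back$A$admission$weekday_effects, coeffs$A$admission$weekday_effects)
  expect_equal(back$A$admission$month_effects, coeffs$A$admission$month_effects)
  expect_equal(back$A$discharge$weekday_effects, coeffs$A$discharge$weekday_effects)
})

test_that("calibrate_units reports retention diagnostics per unit", {
  sc <- const_scenario(mu = 2, p = 0.5, capacity = 15L, years = 2,
                       seed = 11, capacity_mode = "constrained")
  gen <- generate_records(sc)
  cal <- calibrate_units(gen$records, sc$start_date, n_days = 730)
  expect_named(cal, "X")
  d <- cal$X$diagnostics
  expect_equal(d$n_days, 730L)
  expect_gte(d$n_retained, 365L)       # median rule keeps at least half
  expect_lt(d$prop_excluded, 0.5)
  expect_s3_class(cal$X$admission, "admission_coeffs")
  expect_s3_class(cal$X$discharge, "discharge_coeffs")
})
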