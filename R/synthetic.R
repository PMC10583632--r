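#' Build a ground-truth simulation scenario
#'
#' Defines units with known admission and discharge coefficient sets so
#' that calibration, the simulator and the experiments can be exercised —
#' and their estimates checked against truth — without any real patient
#' data. The presets are scaled to the size range of real municipal acute
#' units (6 to 72 beds, mean lengths of stay of roughly 3 to 5 days, mean
#' occupancies from about 2 to 43 beds):
#'
#' * `small` — one 6-bed unit, under 1 admission/day, mean LOS ~5 days;
#' * `medium` — one 15-bed unit, ~2.4 admissions/day, mean LOS ~3 days;
#' * `large` — one 72-bed unit, ~14 admissions/day, mean LOS ~3 days;
#' * `four_unit` — the four sizes 14, 6, 72, 15 beds together, with loads
#'   around 9.4, 2.3, 43 and 7 beds respectively.
#'
#' Every preset carries mild weekday structure (fewer weekend admissions,
#' more Friday and fewer Sunday discharges) and a summer dip in arrivals,
#' the seasonal patterns these units exhibit.
#'
#' @param preset One of `"small"`, `"medium"`, `"large"`, `"four_unit"`,
#'   or `"custom"` (supply `units`, `admission_coeffs`,
#'   `discharge_coeffs`).
#' @param years Number of simulated years of records (default 1).
#' @param seed Seed stored with the scenario (default 1).
#' @param capacity_mode `"unconstrained"` (default, so generated records
#'   reflect potential demand) or `"constrained"`.
#' @param start_date First day of the generated window.
#' @param units,admission_coeffs,discharge_coeffs Explicit specification
#'   for `preset = "custom"`; ignored otherwise.
#' @return A list of class `mau_scenario`.
#' @export
#' @examples
#' sc <- make_scenario("small", seed = 7)
#' sc$units
make_scenario <- function(preset = c("medium", "small", "large",
                                     "four_unit", "custom"),
                          years = 1, seed = 1L,
                          capacity_mode = c("unconstrained", "constrained"),
                          start_date = "2017-01-01",
                          units = NULL, admission_coeffs = NULL,
                          discharge_coeffs = NULL) {
  preset <- match.arg(preset)
  capacity_mode <- match.arg(capacity_mode)
  years <- check_count(years, "years", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)

  wd_adm <- function(base) c(Saturday = -0.25 * base, Sunday = -0.3 * base)
  mo_adm <- function(base) c(July = -0.15 * base, August = -0.1 * base)
  wd_dis <- c(Friday = 0.35, Saturday = -0.2, Sunday = -0.45)

  presets <- list(
    small = list(
      units = unit_spec("S1", 6L),
      # ~0.45 admissions/day, p ~ 0.2 -> LOS ~ 5 d, load ~ 2.3 beds
      adm = list(S1 = admission_coeffs(0.5, wd_adm(0.5), mo_adm(0.5))),
      dis = list(S1 = discharge_coeffs(qlogis(0.2), wd_dis))
    ),
    medium = list(
      units = unit_spec("M1", 15L),
      # ~2.4 admissions/day, p ~ 1/3 -> LOS ~ 3 d, load ~ 7 beds
      adm = list(M1 = admission_coeffs(2.55, wd_adm(2.55), mo_adm(2.55))),
      dis = list(M1 = discharge_coeffs(qlogis(1 / 3), wd_dis))
    ),
    large = list(
      units = unit_spec("L1", 72L),
      # ~14 admissions/day, p ~ 1/3 -> LOS ~ 3 d, load ~ 43 beds
      adm = list(L1 = admission_coeffs(15.2, wd_adm(15.2), mo_adm(15.2))),
      dis = list(L1 = discharge_coeffs(qlogis(1 / 3), wd_dis))
    )
  )
  presets$four_unit <- list(
    units = unit_spec(c("U1", "U2", "U3", "U4"), c(14L, 6L, 72L, 15L)),
    adm = list(
      U1 = admission_coeffs(3.2, wd_adm(3.2), mo_adm(3.2)),
      U2 = presets$small$adm$S1,
      U3 = presets$large$adm$L1,
      U4 = admission_coeffs(2.55, wd_adm(2.55), mo_adm(2.55))
    ),
    dis = list(
      U1 = discharge_coeffs(qlogis(0.3), wd_dis),
      U2 = presets$small$dis$S1,
      U3 = presets$large$dis$L1,
      U4 = discharge_coeffs(qlogis(1 / 3), wd_dis)
    )
  )
  if (preset == "custom") {
    if (is.null(units) || is.null(admission_coeffs) ||
        is.null(discharge_coeffs)) {
      abort("Custom scenarios need `units`, `admission_coeffs` and `discharge_coeffs`.")
    }
    missing <- setdiff(units$unit_id,
                       intersect(names(admission_coeffs),
                                 names(discharge_coeffs)))
    if (length(missing) > 0) {
      abort(sprintf("No coefficient sets for unit(s): %s",
                    paste(missing, collapse = ", ")))
    }
    spec <- list(units = units, adm = admission_coeffs,
                 dis = discharge_coeffs)
  } else {
    spec <- presets[[preset]]
  }

  # sanity: implied mean LOS must be finite and positive
  mean_p <- purrr::map_dbl(spec$dis, function(d) {
    mean(plogis(d$intercept + d$weekday_effects))
  })
  if (any(!is.finite(1 / mean_p)) || any(mean_p <= 0)) {
    abort("Scenario implies an infinite or non-positive mean length of stay.")
  }

  structure(list(
    preset = preset,
    units = spec$units,
    admission_coeffs = spec$adm,
    discharge_coeffs = spec$dis,
    years = years,
    seed = seed,
    capacity_mode = capacity_mode,
    start_date = as_date_strict(start_date)
  ), class = "mau_scenario")
}

#' @export
print.mau_scenario <- function(x, ...) {
  cat(sprintf("<mau_scenario> preset '%s': %d unit(s), %d year(s), %s, seed %d\n",
              x$preset, nrow(x$units), x$years, x$capacity_mode, x$seed))
  print(x$units)
  invisible(x)
}

# Age/sex marginals loosely matching the population these units serve
# (mostly older adults, about two-thirds female); schema completeness only,
# demographics are not predictors anywhere.
synth_demographics <- function(n) {
  list(age = pmax(18, pmin(105, round(rnorm(n, mean = 80, sd = 12)))),
       sex = sample(c("female", "male"), n, replace = TRUE,
                    prob = c(0.66, 0.34)))
}

#' Generate synthetic admission records from a scenario
#'
#' Runs the simulation engine once over `years * 365` days (after the
#' standard warm-up, with a cool-down extension so every stay has a
#' discharge date) and emits each simulated admission as one record in the
#' standard schema, together with the engine's own midnight-census trace.
#' The trace and [compute_daily_occupancy()] of the emitted records agree
#' day by day — an internal bookkeeping identity that the test-suite
#' checks.
#'
#' @param scenario A [make_scenario()] object.
#' @param demographics Add synthetic `age` and `sex` columns (default
#'   TRUE).
#' @return List with `records` (tibble in the [read_admission_records()]
#'   schema), `occupancy` (tibble of the generating midnight census over
#'   the core window) and `truth` (the scenario, for parameter-recovery
#'   checks). Any stays longer than 21 days are counted in
#'   `n_los_over_21`.
#' @export
generate_records <- function(scenario, demographics = TRUE) {
  stopifnot(inherits(scenario, "mau_scenario"))
  cfg <- sim_config(
    n_runs = 1L,
    core_days = scenario$years * 365L,
    warmup_days = 14L,
    cooldown_days = 7L,
    start_date = scenario$start_date,
    seed = scenario$seed,
    capacity_mode = scenario$capacity_mode
  )
  sim <- run_replications(scenario$units, scenario$admission_coeffs,
                          scenario$discharge_coeffs, cfg,
                          emit_records = TRUE)
  records <- sim$records
  # records begin at the warm-up start so the census recomputed from them
  # matches the engine's trace from the first core day onward
  if (demographics && nrow(records) > 0) {
    demo <- synth_demographics(nrow(records))
    records$age <- demo$age
    records$sex <- demo$sex
  }
  occupancy <- dplyr::filter(sim$census_trace, .data$window == "core")
  occupancy <- tibble::tibble(date = occupancy$date,
                              occupancy = as.integer(occupancy$mean_census))
  los <- as.integer(records$discharge_date - records$admission_date)
  list(records = records,
       occupancy = occupancy,
       truth = scenario,
       n_los_over_21 = sum(los > 21))
}
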