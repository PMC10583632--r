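#' Simulation run configuration
#'
#' Bundles the knobs of the discrete-time engine. Defaults follow the
#' standard study design: 100 replications of 365 core days, preceded by a
#' 14-day warm-up (so the census reaches steady state from an empty unit,
#' ample at a ~3-day length-of-stay scale) and followed by a 7-day
#' cool-down (simulated so stays begun near year-end complete, but excluded
#' from the census average). The 50-50 rule gives each bed freed by a
#' same-day discharge an independent 50% chance of being usable for a new
#' admission that same day.
#'
#' @param n_runs Number of replications (default 100).
#' @param core_days Days in the scoring window (default 365).
#' @param warmup_days Warm-up days excluded from scoring (default 14).
#' @param cooldown_days Cool-down days excluded from scoring (default 7).
#' @param start_date Calendar date of the first core day (default
#'   2017-01-01); warm-up days precede it.
#' @param seed Master seed; every run draws from its own substream derived
#'   from this seed, so results are bit-reproducible and runs are
#'   order-independent.
#' @param capacity_mode `"constrained"` (beds limited) or
#'   `"unconstrained"` (every potential admission admitted).
#' @param freed_bed_availability Probability that a bed freed by a same-day
#'   discharge is usable that day (default 0.5).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_runs = 100, core_days = 365, warmup_days = 14,
                       cooldown_days = 7, start_date = "2017-01-01",
                       seed = 1L,
                       capacity_mode = c("constrained", "unconstrained"),
                       freed_bed_availability = 0.5) {
  capacity_mode <- match.arg(capacity_mode)
  start_date <- as_date_strict(start_date)
  if (is.na(start_date)) abort("`start_date` is not a parseable date.")
  structure(list(
    n_runs = check_count(n_runs, "n_runs", min = 1L),
    core_days = check_count(core_days, "core_days", min = 1L),
    warmup_days = check_count(warmup_days, "warmup_days"),
    cooldown_days = check_count(cooldown_days, "cooldown_days"),
    start_date = start_date,
    seed = check_count(seed, "seed", min = 0L),
    capacity_mode = capacity_mode,
    freed_bed_availability = check_prob(freed_bed_availability,
                                        "freed_bed_availability")
  ), class = "sim_config")
}

#' Define simulated units
#'
#' @param unit_id Character vector of unit labels.
#' @param bed_capacity Integer vector of maximum bed counts (>= 1); the
#'   stated capacity is treated as fixed (no surge beds).
#' @return A tibble with one row per unit.
#' @export
unit_spec <- function(unit_id, bed_capacity) {
  if (anyDuplicated(unit_id)) abort("Duplicate unit ids.")
  if (any(bed_capacity < 1 | bed_capacity != floor(bed_capacity))) {
    abort("`bed_capacity` must be integers >= 1.")
  }
  tibble::tibble(unit_id = as.character(unit_id),
                 bed_capacity = as.integer(bed_capacity))
}

# Normalise coefficient input: either a single coeffs object (one unit) or
# a named list keyed by unit_id. Returns a list in `units` row order.
coeffs_per_unit <- function(coeffs, units, class) {
  if (inherits(coeffs, class)) {
    if (nrow(units) != 1L) {
      abort(sprintf("A single %s object was given for %d units.",
                    class, nrow(units)))
    }
    return(list(coeffs))
  }
  missing <- setdiff(units$unit_id, names(coeffs))
  if (length(missing) > 0) {
    abort(sprintf("No coefficients for unit(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- coeffs[units$unit_id]
  ok <- vapply(out, inherits, logical(1), what = class)
  if (!all(ok)) abort(sprintf("Coefficients must be %s objects.", class))
  out
}

# Per-day update, vectorised over inpatients, operating on precomputed
# mu (days x units) and p (days x units) matrices. The fixed order of RNG
# draws (discharge uniforms, per-unit Poisson counts, freed-bed binomial,
# turn-away shuffle) is part of the determinism contract.
step_day_core <- function(origin, adm_day, t, mu_row, p_row, capacity,
                          constrained, freed_prob) {
  occ_before <- length(origin)
  if (occ_before > 0) {
    disc <- runif(occ_before) < p_row[origin]
  } else {
    disc <- logical(0)
  }
  n_disc <- sum(disc)
  disc_origin <- origin[disc]
  disc_adm <- adm_day[disc]
  origin <- origin[!disc]
  adm_day <- adm_day[!disc]

  arrivals <- rpois(length(mu_row), mu_row)
  new_origin <- rep.int(seq_along(mu_row), arrivals)
  turned <- 0L
  if (constrained) {
    freed_usable <- rbinom(1L, n_disc, freed_prob)
    available <- capacity - occ_before + freed_usable
    available <- max(available, 0L)
    if (length(new_origin) > available) {
      turned <- length(new_origin) - available
      new_origin <- new_origin[sample.int(length(new_origin), available)]
    }
  }
  list(origin = c(origin, new_origin),
       adm_day = c(adm_day, rep.int(t, length(new_origin))),
       admitted = length(new_origin),
       turned_away = turned,
       discharged_origin = disc_origin,
       discharged_adm = disc_adm)
}

#' One day of the discrete-time engine
#'
#' Advances the inpatient list by a single 24-hour step, in the fixed order
#' (1) discharge each inpatient with the discharge probability of its
#' origin unit for this date, (2) draw each unit's potential admissions
#' from a Poisson distribution with that unit's regression mean, (3) count
#' available beds as free-beds-at-start plus a Binomial(discharges, 0.5)
#' number of same-day-usable freed beds (the 50-50 rule), (4) admit a
#' uniformly random subset of the pooled potential admissions if they
#' exceed availability (all of them in unconstrained mode), (5) add the
#' admitted patients to the list with their origin tags. Consumes the
#' current RNG state; seed beforehand for reproducibility.
#'
#' @param inpatients Tibble with columns `origin_unit_id`, `admission_day`
#'   (may be empty, zero rows).
#' @param date The calendar date of the day being simulated.
#' @param units A [unit_spec()] tibble; capacity is pooled across rows.
#' @param admission_coeffs,discharge_coeffs Per-unit coefficient sets: a
#'   named list keyed by `unit_id`, or a single coefficients object when
#'   there is one unit.
#' @param config A [sim_config()]; only `capacity_mode` and
#'   `freed_bed_availability` are used here.
#' @return List with elements `inpatients` (updated tibble), `admitted`,
#'   `turned_away` and `discharged` counts.
#' @export
step_day <- function(inpatients, date, units, admission_coeffs,
                     discharge_coeffs, config = sim_config()) {
  date <- as_date_strict(date)
  ac <- coeffs_per_unit(admission_coeffs, units, "admission_coeffs")
  dc <- coeffs_per_unit(discharge_coeffs, units, "discharge_coeffs")
  mu_row <- vapply(ac, admission_mean, numeric(1), dates = date)
  p_row <- vapply(dc, discharge_probability, numeric(1), dates = date)
  origin <- match(inpatients$origin_unit_id, units$unit_id)
  if (anyNA(origin)) abort("Inpatient with unknown origin unit.")
  res <- step_day_core(origin, inpatients$admission_day, 0L, mu_row, p_row,
                       capacity = sum(units$bed_capacity),
                       constrained = config$capacity_mode == "constrained",
                       freed_prob = config$freed_bed_availability)
  list(
    inpatients = tibble::tibble(
      origin_unit_id = units$unit_id[res$origin],
      admission_day = res$adm_day),
    admitted = res$admitted,
    turned_away = res$turned_away,
    discharged = length(res$discharged_origin)
  )
}

# One full replication. Returns census/admitted/turned vectors over all
# simulated days and, optionally, the emitted stay records.
simulate_run <- function(mu_mat, p_mat, capacity, constrained, freed_prob,
                         n_total, seed, emit_records = FALSE,
                         p_ext = NULL) {
  set.seed(seed)
  origin <- integer(0)
  adm_day <- integer(0)
  census <- integer(n_total)
  admitted <- integer(n_total)
  turned <- integer(n_total)
  rec_origin <- integer(0)
  rec_adm <- integer(0)
  rec_dis <- integer(0)

  for (t in seq_len(n_total)) {
    res <- step_day_core(origin, adm_day, t, mu_mat[t, ], p_mat[t, ],
                         capacity, constrained, freed_prob)
    origin <- res$origin
    adm_day <- res$adm_day
    census[t] <- length(origin)
    admitted[t] <- res$admitted
    turned[t] <- res$turned_away
    if (emit_records && length(res$discharged_origin) > 0) {
      rec_origin <- c(rec_origin, res$discharged_origin)
      rec_adm <- c(rec_adm, res$discharged_adm)
      rec_dis <- c(rec_dis, rep.int(t, length(res$discharged_origin)))
    }
  }

  if (emit_records) {
    # discharge-only extension so every emitted stay has a discharge date
    t_ext <- n_total
    while (length(origin) > 0 && t_ext < n_total + nrow(p_ext)) {
      t_ext <- t_ext + 1L
      p_row <- p_ext[t_ext - n_total, ]
      disc <- runif(length(origin)) < p_row[origin]
      if (any(disc)) {
        rec_origin <- c(rec_origin, origin[disc])
        rec_adm <- c(rec_adm, adm_day[disc])
        rec_dis <- c(rec_dis, rep.int(t_ext, sum(disc)))
        origin <- origin[!disc]
        adm_day <- adm_day[!disc]
      }
    }
    if (length(origin) > 0) {  # unreachable at realistic parameters
      rec_origin <- c(rec_origin, origin)
      rec_adm <- c(rec_adm, adm_day)
      rec_dis <- c(rec_dis, rep.int(t_ext + 1L, length(origin)))
    }
  }

  list(census = census, admitted = admitted, turned = turned,
       rec_origin = rec_origin, rec_adm = rec_adm, rec_dis = rec_dis)
}

build_rate_matrices <- function(units, ac, dc, dates) {
  mu <- vapply(ac, admission_mean, numeric(length(dates)), dates = dates)
  p <- vapply(dc, discharge_probability, numeric(length(dates)),
              dates = dates)
  mu <- matrix(mu, nrow = length(dates))
  p <- matrix(p, nrow = length(dates))
  list(mu = mu, p = p)
}

#' Run replicated occupancy simulations
#'
#' Simulates `warmup + core + cooldown` days per replication, starting each
#' replication from an empty unit, and scores the midnight census over the
#' core window only. When several units are supplied their bed capacity is
#' pooled (see [merge_units()]) while arrivals and discharges keep their
#' per-unit coefficient sets. The per-run value is the mean census over
#' core days; the summary aggregates runs with a normal-approximation 95%
#' confidence interval `mean +/- 1.96 sd / sqrt(n_runs)`.
#'
#' @inheritParams step_day
#' @param config A [sim_config()].
#' @param beds_removed Beds subtracted from the pooled capacity (default 0).
#' @param emit_records Also return each simulated stay as an admission
#'   record (single-run configurations only).
#' @return A `mau_sim` object; `glance()` gives the one-row summary,
#'   `tidy()` the per-run values, `autoplot()` plots the run distribution.
#'   Emitted records (if requested) are in `$records`.
#' @export
run_replications <- function(units, admission_coeffs, discharge_coeffs,
                             config = sim_config(), beds_removed = 0,
                             emit_records = FALSE) {
  stopifnot(is.data.frame(units))
  if (anyDuplicated(units$unit_id)) abort("Duplicate unit ids.")
  beds_removed <- check_count(beds_removed, "beds_removed")
  capacity <- sum(units$bed_capacity) - beds_removed
  if (capacity < 1) abort("`beds_removed` leaves no beds.")
  if (emit_records && config$n_runs != 1L) {
    abort("`emit_records` requires a single-run configuration.")
  }
  ac <- coeffs_per_unit(admission_coeffs, units, "admission_coeffs")
  dc <- coeffs_per_unit(discharge_coeffs, units, "discharge_coeffs")

  n_total <- config$warmup_days + config$core_days + config$cooldown_days
  day0 <- config$start_date - config$warmup_days
  dates <- day0 + seq_len(n_total) - 1L
  rates <- build_rate_matrices(units, ac, dc, dates)
  p_ext <- NULL
  if (emit_records) {
    ext_dates <- day0 + n_total + seq_len(366L) - 1L
    p_ext <- matrix(vapply(dc, discharge_probability,
                           numeric(length(ext_dates)), dates = ext_dates),
                    nrow = length(ext_dates))
  }
  constrained <- config$capacity_mode == "constrained"
  core_idx <- config$warmup_days + seq_len(config$core_days)
  run_seeds <- derive_run_seeds(config$seed, config$n_runs)

  census_sum <- numeric(n_total)
  per_run <- vector("list", config$n_runs)
  records <- NULL
  for (r in seq_len(config$n_runs)) {
    res <- simulate_run(rates$mu, rates$p, capacity, constrained,
                        config$freed_bed_availability, n_total,
                        run_seeds[r], emit_records, p_ext)
    census_sum <- census_sum + res$census
    per_run[[r]] <- tibble::tibble(
      run = r,
      mean_occupancy = mean(res$census[core_idx]),
      admitted = sum(res$admitted[core_idx]),
      turned_away = sum(res$turned[core_idx]),
      max_census = max(res$census[core_idx])
    )
    if (emit_records) {
      records <- tibble::tibble(
        unit_id = units$unit_id[res$rec_origin],
        admission_date = day0 + res$rec_adm - 1L,
        discharge_date = day0 + res$rec_dis - 1L
      )
      records <- dplyr::arrange(records, .data$admission_date, .data$unit_id)
    }
  }
  per_run <- dplyr::bind_rows(per_run)

  structure(list(
    per_run = per_run,
    census_trace = tibble::tibble(
      date = dates,
      mean_census = census_sum / config$n_runs,
      window = rep(c("warmup", "core", "cooldown"),
                   c(config$warmup_days, config$core_days,
                     config$cooldown_days))
    ),
    records = records,
    units = units,
    capacity = capacity,
    beds_removed = beds_removed,
    config = config
  ), class = "mau_sim")
}

#' Simulate merged units with pooled capacity
#'
#' Runs the engine for two or more units operating as one: bed capacities
#' are pooled (optionally minus `beds_removed`), potential admissions are
#' generated per origin unit, each inpatient keeps the discharge
#' coefficients of the unit its admission originated from, and when the
#' pooled capacity binds the turn-away is a uniformly random subset of the
#' pooled potential list, so origins are treated fairly.
#'
#' @inheritParams run_replications
#' @export
merge_units <- function(units, admission_coeffs, discharge_coeffs,
                        config = sim_config(), beds_removed = 0) {
  if (nrow(units) < 2) abort("`merge_units` needs at least two units.")
  if (anyDuplicated(units$unit_id)) abort("Duplicate unit ids.")
  if (beds_removed >= sum(units$bed_capacity)) {
    abort("`beds_removed` must be smaller than the pooled capacity.")
  }
  run_replications(units, admission_coeffs, discharge_coeffs, config,
                   beds_removed = beds_removed)
}

#' @export
print.mau_sim <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<mau_sim>  %s, %d bed(s), %d run(s) x %d core days\n",
              x$config$capacity_mode, x$capacity, x$config$n_runs,
              x$config$core_days))
  cat(sprintf("  absolute mean occupancy: %.2f (95%% CI %.2f-%.2f, sd %.2f)\n",
              g$absolute_mean_occupancy, g$ci_lo, g$ci_hi, g$sd_over_runs))
  cat(sprintf("  mean turned away per year: %.1f\n",
              g$mean_turned_away_per_year))
  invisible(x)
}

#' Per-run values of a simulation
#' @param x A `mau_sim` object.
#' @param ... Unused.
#' @return Tibble with one row per replication: core-window mean occupancy,
#'   admitted and turned-away counts, peak census.
#' @export
tidy.mau_sim <- function(x, ...) x$per_run

#' One-row summary of a simulation
#' @param x A `mau_sim` object.
#' @param ... Unused.
#' @return Tibble with the absolute mean occupancy, its spread and 95%
#'   confidence interval over runs, and mean annual turn-away count.
#' @export
glance.mau_sim <- function(x, ...) {
  v <- x$per_run$mean_occupancy
  n <- length(v)
  m <- mean(v)
  s <- if (n > 1) sd(v) else 0
  half <- 1.96 * s / sqrt(n)
  tibble::tibble(
    absolute_mean_occupancy = m,
    sd_over_runs = s,
    ci_lo = m - half,
    ci_hi = m + half,
    mean_turned_away_per_year = mean(x$per_run$turned_away),
    mean_admitted_per_year = mean(x$per_run$admitted),
    n_runs = n,
    capacity = x$capacity,
    capacity_mode = x$config$capacity_mode
  )
}

#' Plot the distribution of run-level mean occupancies
#'
#' @param object A `mau_sim` object.
#' @param ... Unused.
#' @return A ggplot object: histogram of the per-run core-window mean
#'   census, with the overall mean and 95% CI marked.
#' @export
autoplot.mau_sim <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$per_run,
                  ggplot2::aes(x = .data$mean_occupancy)) +
    ggplot2::geom_histogram(bins = 20, fill = "#2c6e91", colour = "white") +
    ggplot2::geom_vline(xintercept = g$absolute_mean_occupancy,
                        colour = "#b2432f") +
    ggplot2::geom_vline(xintercept = c(g$ci_lo, g$ci_hi),
                        colour = "#b2432f", linetype = "dashed") +
    ggplot2::labs(x = "Run mean occupancy (beds)", y = "Runs") +
    ggplot2::theme_minimal()
}
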