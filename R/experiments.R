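#' Estimate occupancy lost to the capacity constraint
#'
#' Runs the simulator twice for one unit — once with the bed capacity
#' enforced and once with the constraint removed — on independent random
#' substreams, and reports the difference in absolute mean occupancy. The
#' unconstrained value is the unit's potential occupancy (its load, in
#' queueing terms); the difference is the occupancy lost because patients
#' are turned away when the unit is full.
#'
#' @param units A one-row [unit_spec()] tibble.
#' @param admission_coeffs,discharge_coeffs Coefficient sets (see
#'   [run_replications()]).
#' @param config A [sim_config()]; its `capacity_mode` is overridden for
#'   each arm.
#' @return One-row tibble: constrained and potential (unconstrained)
#'   occupancy with 95% CIs, the loss in beds with a CI from run-level
#'   differences, and the mean annual turn-away count.
#' @export
experiment_unconstrained <- function(units, admission_coeffs,
                                     discharge_coeffs,
                                     config = sim_config()) {
  cfg_c <- config
  cfg_c$capacity_mode <- "constrained"
  cfg_u <- config
  cfg_u$capacity_mode <- "unconstrained"
  cfg_u$seed <- config$seed + 1L  # independent substream for the second arm

  con <- run_replications(units, admission_coeffs, discharge_coeffs, cfg_c)
  unc <- run_replications(units, admission_coeffs, discharge_coeffs, cfg_u)
  gc <- glance(con)
  gu <- glance(unc)
  diff <- gu$absolute_mean_occupancy - gc$absolute_mean_occupancy
  se_diff <- sqrt(gc$sd_over_runs^2 / gc$n_runs +
                  gu$sd_over_runs^2 / gu$n_runs)
  tibble::tibble(
    unit_id = paste(units$unit_id, collapse = "+"),
    bed_capacity = sum(units$bed_capacity),
    constrained_occupancy = gc$absolute_mean_occupancy,
    constrained_ci_lo = gc$ci_lo, constrained_ci_hi = gc$ci_hi,
    potential_occupancy = gu$absolute_mean_occupancy,
    potential_ci_lo = gu$ci_lo, potential_ci_hi = gu$ci_hi,
    loss = diff,
    loss_ci_lo = diff - 1.96 * se_diff,
    loss_ci_hi = diff + 1.96 * se_diff,
    turned_away_per_year = gc$mean_turned_away_per_year
  )
}

per_unit_baselines <- function(units, admission_coeffs, discharge_coeffs,
                               config) {
  purrr::map(seq_len(nrow(units)), function(i) {
    cfg <- config
    cfg$capacity_mode <- "constrained"
    cfg$seed <- config$seed + i  # independent substream per baseline unit
    run_replications(units[i, ], admission_coeffs[units$unit_id[i]],
                     discharge_coeffs[units$unit_id[i]], cfg)
  })
}

#' Estimate the occupancy gain from merging units
#'
#' Compares the absolute mean occupancy of two or more units operating as
#' one pooled-capacity unit against the sum of their individually
#' constrained baselines. Pooling reduces blocking (a patient turned away
#' from one full unit can take a bed freed elsewhere), so the increase is
#' expected to be non-negative, and largest when the member units are
#' heavily loaded.
#'
#' @inheritParams experiment_unconstrained
#' @param units A [unit_spec()] tibble with >= 2 rows.
#' @param beds_removed Beds removed from the pooled capacity (default 0).
#' @return One-row `scenario` tibble: pooled beds, the sum of individual
#'   baselines, the merged occupancy, and the occupancy increase with a
#'   95% CI combining the arms' run-level spreads.
#' @export
experiment_merge <- function(units, admission_coeffs, discharge_coeffs,
                             config = sim_config(), beds_removed = 0) {
  baselines <- per_unit_baselines(units, admission_coeffs, discharge_coeffs,
                                  config)
  gb <- purrr::map(baselines, glance)
  baseline_sum <- sum(purrr::map_dbl(gb, "absolute_mean_occupancy"))
  se_base_sq <- sum(purrr::map_dbl(gb, function(g) {
    g$sd_over_runs^2 / g$n_runs
  }))

  cfg_m <- config
  cfg_m$capacity_mode <- "constrained"
  merged <- merge_units(units, admission_coeffs, discharge_coeffs, cfg_m,
                        beds_removed = beds_removed)
  gm <- glance(merged)
  inc <- gm$absolute_mean_occupancy - baseline_sum
  se <- sqrt(se_base_sq + gm$sd_over_runs^2 / gm$n_runs)
  tibble::tibble(
    scenario_id = paste(units$unit_id, collapse = "+"),
    pooled_beds = sum(units$bed_capacity) - beds_removed,
    baseline_sum = baseline_sum,
    merged_occupancy = gm$absolute_mean_occupancy,
    merged_ci_lo = gm$ci_lo, merged_ci_hi = gm$ci_hi,
    occupancy_increase = inc,
    increase_ci_lo = inc - 1.96 * se,
    increase_ci_hi = inc + 1.96 * se,
    turned_away_per_year = gm$mean_turned_away_per_year
  )
}

#' Beds removable from a merged unit at preserved service level
#'
#' Searches for the largest number of beds that can be removed from the
#' pooled capacity of merged units while the merged absolute mean occupancy
#' stays at or above a target service level (by default the sum of the
#' individually constrained baselines). Occupancy is non-decreasing in
#' capacity, so beds are removed one at a time — with common random numbers
#' across capacity levels (the same run substreams at every k) to stabilise
#' the level at which the target is first violated — and the first failure
#' ends the search. The comparison allows one Monte-Carlo standard error of
#' slack so the answer is not seed-dependent at the margin.
#'
#' @inheritParams experiment_merge
#' @param target Target combined occupancy in beds; defaults to the sum of
#'   the units' individual constrained baselines.
#' @return One-row tibble: the target, the number of removable beds, and
#'   the merged occupancy at the reduced capacity. If the target is not met
#'   even at full pooled capacity, `removable_beds` is 0 with a warning.
#' @export
find_removable_beds <- function(units, admission_coeffs, discharge_coeffs,
                                config = sim_config(), target = NULL) {
  pooled <- sum(units$bed_capacity)
  if (is.null(target)) {
    baselines <- per_unit_baselines(units, admission_coeffs,
                                    discharge_coeffs, config)
    target <- sum(purrr::map_dbl(baselines, function(b) {
      glance(b)$absolute_mean_occupancy
    }))
  }
  if (target <= 0) abort("`target` must be positive.")
  cfg <- config
  cfg$capacity_mode <- "constrained"

  occ_at <- function(k) {
    # same cfg$seed at every k: common random numbers across the sweep
    sim <- run_replications(units, admission_coeffs, discharge_coeffs, cfg,
                            beds_removed = k)
    glance(sim)
  }

  g0 <- occ_at(0L)
  se0 <- g0$sd_over_runs / sqrt(g0$n_runs)
  if (g0$absolute_mean_occupancy < target - se0) {
    warn(sprintf(
      "Target occupancy %.3f not attained even at full pooled capacity (%.3f); no beds can be removed.",
      target, g0$absolute_mean_occupancy))
    k_best <- 0L
    g_best <- g0
  } else {
    k_best <- 0L
    g_best <- g0
    k <- 1L
    while (k <= pooled - 1L) {
      g <- occ_at(k)
      se <- g$sd_over_runs / sqrt(g$n_runs)
      if (g$absolute_mean_occupancy < target - se) break  # monotone: terminal
      k_best <- k
      g_best <- g
      k <- k + 1L
    }
  }
  tibble::tibble(
    scenario_id = paste(units$unit_id, collapse = "+"),
    pooled_beds = pooled,
    target_occupancy = target,
    removable_beds = k_best,
    remaining_beds = pooled - k_best,
    occupancy_at_reduced = g_best$absolute_mean_occupancy,
    occupancy_ci_lo = g_best$ci_lo,
    occupancy_ci_hi = g_best$ci_hi,
    turned_away_per_year = g_best$mean_turned_away_per_year
  )
}
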