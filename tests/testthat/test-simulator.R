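test_that("a single day steps in order: discharges, arrivals, 50-50 rule, admit", {
  units <- unit_spec("A", 3L)
  ac <- admission_coeffs(0)
  dc <- discharge_coeffs(qlogis(0.5))
  inp <- tibble::tibble(origin_unit_id = rep("A", 3), admission_day = 0L)
  set.seed(1)
  # zero admission mean: occupancy can only shrink, and eventually empties
  occ <- integer(0)
  for (d in 1:40) {
    res <- step_day(inp, as.Date("2017-01-01") + d, units, ac, dc)
    expect_lte(nrow(res$inpatients), nrow(inp))
    expect_equal(res$admitted, 0L)
    inp <- res$inpatients
    occ <- c(occ, nrow(inp))
  }
  expect_equal(min(occ), 0L)

  # unknown origin is an error
  bad <- tibble::tibble(origin_unit_id = "Z", admission_day = 0L)
  expect_error(step_day(bad, "2017-01-02", units, ac, dc), "unknown origin")
})

test_that("the midnight census never exceeds capacity in constrained mode", {
  units <- unit_spec("A", 1L)
  cfg <- sim_config(n_runs = 20, core_days = 120, seed = 5,
                    capacity_mode = "constrained")
  sim <- run_replications(units, admission_coeffs(50),
                          discharge_coeffs(qlogis(0.5)), cfg)
  expect_true(all(sim$per_run$max_census <= 1))
  expect_true(all(sim$census_trace$mean_census <= 1))

  units10 <- unit_spec("A", 10L)
  sim10 <- run_replications(units10, admission_coeffs(8),
                            discharge_coeffs(qlogis(0.3)), cfg)
  expect_true(all(sim10$per_run$max_census <= 10))
})

test_that("identical seeds reproduce results bit-for-bit; different seeds differ", {
  units <- unit_spec("A", 12L)
  ac <- admission_coeffs(3, c(Saturday = -1))
  dc <- discharge_coeffs(qlogis(0.4))
  cfg <- sim_config(n_runs = 10, core_days = 90, seed = 99)
  a <- run_replications(units, ac, dc, cfg)
  b <- run_replications(units, ac, dc, cfg)
  expect_identical(a$per_run, b$per_run)
  expect_identical(a$census_trace, b$census_trace)

  cfg2 <- cfg
  cfg2$seed <- 100L
  c <- run_replications(units, ac, dc, cfg2)
  expect_false(identical(a$per_run, c$per_run))
})

test_that("unconstrained occupancy settles at the arrival rate over the discharge rate", {
  units <- unit_spec("A", 100L)
  cfg <- sim_config(n_runs = 40, capacity_mode = "unconstrained", seed = 7)
  sim <- run_replications(units, admission_coeffs(2),
                          discharge_coeffs(qlogis(0.5)), cfg)
  g <- glance(sim)
  expect_lt(abs(g$absolute_mean_occupancy - 4), 3 * mc_se(sim))
  expect_equal(g$mean_turned_away_per_year, 0)
  expect_true(all(sim$per_run$turned_away == 0))
})

test_that("removing the capacity constraint cannot reduce mean occupancy", {
  units <- unit_spec("A", 6L)
  ac <- admission_coeffs(2.5)
  dc <- discharge_coeffs(qlogis(1 / 3))
  con <- run_replications(units, ac, dc,
                          sim_config(n_runs = 30, core_days = 200, seed = 21,
                                     capacity_mode = "constrained"))
  unc <- run_replications(units, ac, dc,
                          sim_config(n_runs = 30, core_days = 200, seed = 22,
                                     capacity_mode = "unconstrained"))
  se <- sqrt(mc_se(con)^2 + mc_se(unc)^2)
  expect_gte(glance(unc)$absolute_mean_occupancy,
             glance(con)$absolute_mean_occupancy - 2 * se)
})

test_that("the constrained engine matches exact enumeration of the daily chain", {
  # capacity 5, discharge probability 0.9, offered 10/day: the day update is
  # a small Markov chain whose stationary census mean is computable exactly
  C <- 5L
  p <- 0.9
  mu <- 10
  P <- matrix(0, C + 1, C + 1)
  for (N in 0:C) {
    for (D in 0:N) {
      pD <- dbinom(D, N, p)
      for (F_ in 0:D) {
        pF <- dbinom(F_, D, 0.5)
        avail <- C - N + F_
        for (a in 0:avail) {
          pa <- if (a < avail) dpois(a, mu) else 1 - ppois(avail - 1, mu)
          N2 <- N - D + a
          P[N + 1, N2 + 1] <- P[N + 1, N2 + 1] + pD * pF * pa
        }
      }
    }
  }
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  exact_mean <- sum((0:C) * stat)

  sim <- run_replications(
    unit_spec("A", C), admission_coeffs(mu), discharge_coeffs(qlogis(p)),
    sim_config(n_runs = 40, core_days = 200, seed = 31,
               capacity_mode = "constrained"))
  expect_lt(abs(glance(sim)$absolute_mean_occupancy - exact_mean),
            3 * mc_se(sim))
})

test_that("merged units pool capacity, keep origin coefficients, and gain under load", {
  units <- unit_spec(c("A", "B"), c(5L, 5L))
  ac <- list(A = admission_coeffs(0.05), B = admission_coeffs(0.05))
  dc <- list(A = discharge_coeffs(qlogis(0.5)),
             B = discharge_coeffs(qlogis(0.5)))
  cfg <- sim_config(n_runs = 20, core_days = 150, seed = 41)

  light <- merge_units(units, ac, dc, cfg)
  expect_equal(light$capacity, 10L)
  expect_equal(glance(light)$mean_turned_away_per_year, 0,
               tolerance = 0.2)

  # two identical heavily loaded units: pooling reduces blocking, so the
  # merged occupancy beats the sum of the separate constrained baselines
  ach <- list(A = admission_coeffs(3), B = admission_coeffs(3))
  dch <- list(A = discharge_coeffs(qlogis(0.5)),
              B = discharge_coeffs(qlogis(0.5)))
  one <- run_replications(units[1, ], ach["A"], dch["A"],
                          sim_config(n_runs = 30, core_days = 200, seed = 42))
  merged <- merge_units(units, ach, dch,
                        sim_config(n_runs = 30, core_days = 200, seed = 43))
  gain <- glance(merged)$absolute_mean_occupancy -
    2 * glance(one)$absolute_mean_occupancy
  expect_gt(gain, 0)
  # direction agrees with pooled-vs-separate Erlang blocking
  rho <- 6  # per-unit load mu/p
  erlang_gain <- 2 * rho * (erlang_loss(5, rho) - erlang_loss(10, 2 * rho))
  expect_gt(erlang_gain, 0)

  expect_error(merge_units(unit_spec("A", 5L), ach["A"], dch["A"], cfg),
               "at least two")
  dup <- tibble::tibble(unit_id = c("A", "A"), bed_capacity = c(5L, 5L))
  expect_error(merge_units(dup, ach, dch, cfg), "Duplicate")
  expect_error(merge_units(units, ach, dch, cfg, beds_removed = 10),
               "smaller than the pooled")
})

test_that("calendar variation in arrivals raises turn-aways above the Erlang estimate", {
  units <- unit_spec("A", 10L)
  ac <- admission_coeffs(4.4, weekday_effects = c(Saturday = -2.6,
                                                  Sunday = -2.6),
                         month_effects = c(June = -1.2, July = -1.8,
                                           August = -1.2))
  dc <- discharge_coeffs(qlogis(1 / 3))
  unc <- run_replications(units, ac, dc,
                          sim_config(n_runs = 30, seed = 51,
                                     capacity_mode = "unconstrained"))
  load <- glance(unc)$absolute_mean_occupancy
  b_erlang <- erlang_loss(10, load)

  con <- run_replications(units, ac, dc,
                          sim_config(n_runs = 30, seed = 52,
                                     capacity_mode = "constrained"))
  frac <- con$per_run$turned_away /
    (con$per_run$turned_away + con$per_run$admitted)
  se_frac <- sd(frac) / sqrt(length(frac))
  expect_gte(mean(frac), b_erlang - 2 * se_frac)
})
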