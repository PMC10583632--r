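# Shared fixture builders. Fixtures are constructed in code at test time.

write_records_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("unit_id,admission_date,discharge_date", lines), path)
  path
}

# A minimal single-unit scenario with constant rates (no weekday/month
# structure) -- handy wherever closed-form expectations exist.
const_scenario <- function(mu, p, capacity = 10L, years = 1, seed = 1L,
                           capacity_mode = "unconstrained") {
  make_scenario(
    preset = "custom",
    units = unit_spec("X", capacity),
    admission_coeffs = list(X = admission_coeffs(mu)),
    discharge_coeffs = list(X = discharge_coeffs(qlogis(p))),
    years = years, seed = seed, capacity_mode = capacity_mode
  )
}

# Direct factorial-sum form of the Erlang B formula: the small-n oracle the
# stable recurrence is checked against.
erlang_direct <- function(n, rho) {
  (rho^n / factorial(n)) / sum(rho^(0:n) / factorial(0:n))
}

# Monte-Carlo standard error of a simulation's mean occupancy
mc_se <- function(sim) {
  g <- glance(sim)
  g$sd_over_runs / sqrt(g$n_runs)
}
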