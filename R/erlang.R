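#' Erlang loss (blocking) probability
#'
#' For a loss system with `n` beds offered a load of `rho` beds (the mean
#' occupancy the unit would have with unlimited beds), the Erlang B formula
#' gives the fraction of potential admissions turned away because all beds
#' are occupied. Computed with the standard stable recurrence
#' `B_0 = 1`, `B_k = rho B_{k-1} / (k + rho B_{k-1})`, which avoids the
#' factorial overflow of the direct form at capacities like 72 beds.
#'
#' @param n Bed capacity, a non-negative integer (vectorised).
#' @param load Offered load `rho` in beds, >= 0 (vectorised).
#' @return Blocking probability in `[0, 1]`.
#' @export
#' @examples
#' erlang_loss(1, 1)   # 0.5
#' erlang_loss(2, 1)   # 0.2
erlang_loss <- function(n, load) {
  ln <- max(length(n), length(load))
  n <- rep_len(n, ln)
  load <- rep_len(load, ln)
  if (any(n < 0) || any(load < 0)) abort("`n` and `load` must be >= 0.")
  if (any(n != floor(n))) abort("`n` must be a whole number of beds.")
  vapply(seq_len(ln), function(i) {
    b <- 1
    if (n[i] >= 1) {
      for (k in seq_len(n[i])) b <- load[i] * b / (k + load[i] * b)
    }
    b
  }, numeric(1))
}

#' Occupancy of an Erlang loss system
#'
#' The expected number of occupied beds when a load of `rho` is offered to
#' `n` beds: `rho * (1 - B(n, rho))` — the offered load thinned by the
#' blocked fraction.
#'
#' @param n Bed capacity, integer >= 1.
#' @param load Offered load in beds.
#' @return Expected occupancy in beds, in `[0, min(load, n))`.
#' @export
erlang_occupancy <- function(n, load) {
  if (any(n < 1)) abort("`n` must be >= 1.")
  load * (1 - erlang_loss(n, load))
}

#' Offered load compatible with an observed occupancy
#'
#' Inverts the occupancy relation of the Erlang loss model: given a bed
#' capacity and an observed absolute mean occupancy, finds the unique load
#' `rho` whose loss-thinned occupancy matches. Because occupancy is
#' strictly increasing in the load, the root is found by growing a bracket
#' geometrically until the upper end overshoots and then bisecting;
#' iteration stops when the occupancy residual is within `tolerance`.
#'
#' @param n Bed capacity, integer >= 1.
#' @param observed_occupancy Mean beds occupied, with
#'   `0 <= observed_occupancy < n` (an n-bed loss system never averages a
#'   full house under finite load).
#' @param tolerance Occupancy residual at which bisection stops (beds,
#'   default 1e-8).
#' @return The load `rho` in beds.
#' @export
#' @examples
#' erlang_inverse_load(14, 9.42)  # about 9.98
erlang_inverse_load <- function(n, observed_occupancy, tolerance = 1e-8) {
  n <- check_count(n, "n", min = 1L)
  occ <- observed_occupancy
  if (!is.numeric(occ) || length(occ) != 1L || is.na(occ) || occ < 0) {
    abort("`observed_occupancy` must be a single number >= 0.")
  }
  if (occ >= n) {
    abort(sprintf(
      "Occupancy %.4g is not attainable with %d bed(s): the mean occupancy of an %d-bed loss system is strictly below %d.",
      occ, n, n, n))
  }
  if (occ == 0) return(0)
  lo <- occ                       # occupancy <= load, so the root is >= occ
  hi <- occ + 1
  while (erlang_occupancy(n, hi) < occ) {
    lo <- hi
    hi <- hi * 2
  }
  repeat {
    mid <- (lo + hi) / 2
    resid <- erlang_occupancy(n, mid) - occ
    if (abs(resid) <= tolerance) return(mid)
    if (resid < 0) lo <- mid else hi <- mid
    if (hi - lo < .Machine$double.eps * max(1, hi)) return(mid)
  }
}

#' Erlang loss results as a tidy table
#'
#' Evaluates the loss model for a set of units, from either known loads or
#' observed occupancies (in which case the load is recovered by
#' [erlang_inverse_load()]).
#'
#' @param units Data frame with columns `unit_id`, `bed_capacity` and one
#'   of `load` or `occupancy`.
#' @return Tibble with columns `unit_id`, `bed_capacity` (n), `load` (rho),
#'   `loss` (B) and `occupancy`, satisfying
#'   `occupancy = load * (1 - loss)`.
#' @export
erlang_table <- function(units) {
  stopifnot(is.data.frame(units))
  if ("load" %in% names(units)) {
    load <- units$load
  } else if ("occupancy" %in% names(units)) {
    load <- purrr::map2_dbl(units$bed_capacity, units$occupancy,
                            erlang_inverse_load)
  } else {
    abort("`units` needs a `load` or an `occupancy` column.")
  }
  loss <- erlang_loss(units$bed_capacity, load)
  tibble::tibble(
    unit_id = units$unit_id,
    bed_capacity = as.integer(units$bed_capacity),
    load = load,
    loss = loss,
    occupancy = load * (1 - loss)
  )
}
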