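# Locale-independent calendar helpers. Weekdays are indexed 1..7 with
# Monday = 1 (Monday is the reference level of both regression sub-models);
# months 1..12 with January = 1 (the reference month).

WEEKDAY_LEVELS <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
                    "Saturday", "Sunday")
MONTH_LEVELS <- c("January", "February", "March", "April", "May", "June",
                  "July", "August", "September", "October", "November",
                  "December")

wday_index <- function(dates) {
  lubridate::wday(dates, week_start = 1)
}

month_index <- function(dates) {
  lubridate::month(dates)
}

weekday_factor <- function(dates) {
  factor(WEEKDAY_LEVELS[wday_index(dates)], levels = WEEKDAY_LEVELS)
}

month_factor <- function(dates) {
  factor(MONTH_LEVELS[month_index(dates)], levels = MONTH_LEVELS)
}

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- suppressWarnings(lubridate::ymd(as.character(x), quiet = TRUE))
  out
}

# Independent per-run substreams: one master seed deterministically yields a
# vector of 32-bit run seeds, so runs are order-independent by contract.
derive_run_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  p
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}
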