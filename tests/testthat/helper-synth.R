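# Shared fixtures built in code: a default season and small simulated
# animals used across test files.

test_season <- season_window("2016-05-21", "2016-07-30")

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A tiny fix table on a regular 2-h schedule from explicit coordinates.
fix_table <- function(x, y, t0 = utc("2016-06-01 00:00:00"),
                      interval_hours = 2, id = "A") {
  tibble::tibble(animal_id = id,
                 t = t0 + (seq_along(x) - 1) * interval_hours * 3600,
                 x = x, y = y)
}

# Steps of given lengths on a regular 2-h schedule (straight-line track).
step_table <- function(lengths, t0 = utc("2016-06-01 00:00:00"),
                       interval_hours = 2, id = "A") {
  st <- build_steps(fix_table(cumsum(c(0, lengths)), rep(0, length(lengths) + 1),
                              t0 = t0, interval_hours = interval_hours,
                              id = id),
                    interval_hours)
  st
}

# TDAM table built directly from window starts and values (for classifier
# contract tests).
tdam_table <- function(values, t0 = utc("2016-06-01 00:00:00"),
                       interval_hours = 2, id = "A") {
  tibble::tibble(animal_id = id,
                 window_start = t0 + (seq_along(values) - 1) *
                   interval_hours * 3600,
                 tdam = values, coverage = 1)
}
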