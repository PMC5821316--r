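#' Simulate one female's GPS trajectory with known reproductive truth
#'
#' Draws step lengths from an exponential distribution whose mean follows
#' the a priori movement profile of the female's true state
#' ([mean_profile()]): constant for a non-parturient female, an abrupt
#' drop at parturition with linear recovery for a female whose calf
#' survives, and an additional abrupt return to the pre-calving mean at
#' calf mortality.  Steps are turned into planar fixes via independent
#' uniform headings (the analysis consumes only step lengths, so
#' directional realism is not modelled).  Each fix is then deleted
#' independently with probability `1 - fix_success`, and with probability
#' `outlier_prob` a step is replaced by an `outlier_scale * a` excursion,
#' emulating the capture-response/predator-avoidance bursts that the
#' top-1% rarefication targets.
#'
#' @param animal_id Identifier for the simulated female.
#' @param status `"non_parturient"`, `"parturient_survived"` or
#'   `"parturient_mortality"`.
#' @param a Pre-calving mean step length, metres.
#' @param bp,mp True parturition / mortality times (POSIXct); `bp`
#'   required unless non-parturient, `mp` required for mortality, with
#'   `bp < mp <= bp + recovery_hours`.
#' @param season Season window ([season_window()]); fixes are scheduled
#'   every `fix_interval_hours` across it.
#' @param recovery_hours Recovery duration, hours.
#' @param fix_interval_hours Nominal fix interval, hours.
#' @param fix_success Per-fix retention probability in (0, 1].
#' @param outlier_prob Per-step probability of an outlier excursion.
#' @param outlier_scale Outlier length as a multiple of `a`.
#' @param seed Optional RNG seed.
#'
#' @return List with `fixes` (fix tibble after dropout), `truth` (one-row
#'   known-status tibble: `animal_id`, `parturient`, `parturition_date`,
#'   `fate`, `mortality_date`) and `true_steps` (the complete pre-dropout
#'   step tibble, for validation).
#' @export
simulate_female <- function(animal_id, status, a, bp = NULL, mp = NULL,
                            season = season_window("2016-05-21",
                                                   "2016-07-30"),
                            recovery_hours = 672, fix_interval_hours = 2,
                            fix_success = 1, outlier_prob = 0,
                            outlier_scale = 10, seed = NULL) {
  stopifnot(a > 0, fix_success > 0, fix_success <= 1,
            outlier_prob >= 0, outlier_prob < 1)
  status <- match.arg(status, c("non_parturient", "parturient_survived",
                                "parturient_mortality"))
  if (!is.null(seed)) set.seed(seed)
  model <- switch(status, non_parturient = "M0",
                  parturient_survived = "M1", parturient_mortality = "M2")
  if (model != "M0" && (is.null(bp) || bp < season[1] || bp > season[2])) {
    stop("bp must lie inside the season window", call. = FALSE)
  }
  times <- seq(season[1], season[2], by = fix_interval_hours * 3600)
  n_steps <- length(times) - 1
  mu <- mean_profile(model, times[-length(times)], a, bp = bp, mp = mp,
                     recovery_hours = recovery_hours,
                     floor_frac = fix_interval_hours / recovery_hours)
  d <- rexp(n_steps, rate = 1 / mu)
  if (outlier_prob > 0) {
    is_out <- runif(n_steps) < outlier_prob
    d[is_out] <- outlier_scale * a
  }
  theta <- runif(n_steps, 0, 2 * pi)
  x <- c(0, cumsum(d * cos(theta)))
  y <- c(0, cumsum(d * sin(theta)))
  true_steps <- tibble::tibble(animal_id = animal_id,
                               t_start = times[-length(times)],
                               t_end = times[-1], length = d,
                               duration_h = fix_interval_hours,
                               rate = d / fix_interval_hours)
  attr(true_steps, "nominal_interval") <- fix_interval_hours
  keep <- if (fix_success < 1) runif(length(times)) < fix_success else
    rep(TRUE, length(times))
  fixes <- tibble::tibble(animal_id = animal_id, t = times, x = x,
                          y = y)[keep, , drop = FALSE]
  truth <- tibble::tibble(
    animal_id = animal_id,
    parturient = model != "M0",
    parturition_date = if (model == "M0") as.POSIXct(NA) else bp,
    fate = switch(model, M0 = NA_character_, M1 = "survived_4wk",
                  M2 = "mortality"),
    mortality_date = if (model == "M2") mp else as.POSIXct(NA)
  )
  list(fixes = fixes, truth = truth, true_steps = true_steps)
}

#' Simulate a herd with known reproductive truth
#'
#' Generates `n` females whose true states are drawn from `mix`, with
#' pre-calving scale parameters uniform on `a_range`, parturition dates
#' Normal around `mean_parturition_date`, and mortality (for the
#' calf-mortality state) uniform between `mortality_day_range` days after
#' parturition.  All randomness flows from `seed`; the same seed
#' reproduces the dataset exactly.
#'
#' The defaults emulate the telemetry the methods were designed for: 2-h
#' fixes over a 21 May - 30 Jul season, an 80% per-collar fix rate, a 1%
#' outlier process at 10x the adult scale, and scale parameters of
#' 150-350 m per 2-h step (TDAM magnitudes of tens to hundreds of m/h).
#' These are synthetic defaults, not estimates for any real herd.
#'
#' @param n Number of females.
#' @param mix Named status proportions (must sum to 1): `non_parturient`,
#'   `parturient_survived`, `parturient_mortality`.
#' @param mean_parturition_date,sd_parturition_days Parturition-date
#'   distribution (Normal, days).
#' @param a_range Range of the pre-calving mean step length, metres.
#' @param mortality_day_range Days after parturition within which a
#'   mortality occurs (uniform draw).
#' @inheritParams simulate_female
#' @param out_dir Optional directory; when given, writes `telemetry.csv`
#'   (the fix schema read by [read_gps_fixes()]) and `truth.csv`.
#' @param seed RNG seed.
#' @return List with `fixes`, `truth` (row-bound over females) and
#'   `true_steps`.
#' @export
simulate_herd <- function(n = 50,
                          mix = c(non_parturient = 0.1,
                                  parturient_survived = 0.6,
                                  parturient_mortality = 0.3),
                          mean_parturition_date = "2016-06-01",
                          sd_parturition_days = 5,
                          a_range = c(150, 350),
                          mortality_day_range = c(1, 28),
                          season = season_window("2016-05-21",
                                                 "2016-07-30"),
                          recovery_hours = 672, fix_interval_hours = 2,
                          fix_success = 0.8, outlier_prob = 0.01,
                          outlier_scale = 10, seed = NULL,
                          out_dir = NULL) {
  stopifnot(n >= 1, abs(sum(mix) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  statuses <- sample(names(mix), n, replace = TRUE, prob = mix)
  mean_pd <- as.POSIXct(mean_parturition_date, tz = "UTC")
  span <- as.numeric(difftime(season[2], season[1], units = "days"))
  bp_lo <- season[1] + min(3, span / 4) * 86400
  bp_hi <- max(bp_lo, season[2] - min(7, span / 4) * 86400)
  females <- lapply(seq_len(n), function(i) {
    id <- sprintf("F%03d", i)
    a <- runif(1, a_range[1], a_range[2])
    bp <- mp <- NULL
    if (statuses[i] != "non_parturient") {
      bp <- mean_pd + rnorm(1, 0, sd_parturition_days) * 86400
      bp <- min(max(bp, bp_lo), bp_hi)
      if (statuses[i] == "parturient_mortality") {
        mp <- bp + runif(1, mortality_day_range[1],
                         min(mortality_day_range[2],
                             recovery_hours / 24)) * 86400
      }
    }
    simulate_female(id, statuses[i], a, bp = bp, mp = mp, season = season,
                    recovery_hours = recovery_hours,
                    fix_interval_hours = fix_interval_hours,
                    fix_success = fix_success,
                    outlier_prob = outlier_prob,
                    outlier_scale = outlier_scale)
  })
  herd <- list(
    fixes = do.call(rbind, lapply(females, `[[`, "fixes")),
    truth = do.call(rbind, lapply(females, `[[`, "truth")),
    true_steps = do.call(rbind, lapply(females, `[[`, "true_steps"))
  )
  attr(herd$true_steps, "nominal_interval") <- fix_interval_hours
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gps_fixes(herd$fixes, file.path(out_dir, "telemetry.csv"))
    tr <- herd$truth
    tr$parturition_date <- format(tr$parturition_date,
                                  "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    tr$mortality_date <- format(tr$mortality_date,
                                "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    write.csv(tr, file.path(out_dir, "truth.csv"), row.names = FALSE,
              quote = FALSE)
  }
  herd
}

#' Emulate VHF calf collaring and monitoring
#'
#' Converts the truth table of a simulated herd into VHF-calf monitoring
#' records, emulating field practice: calves of parturient females are
#' captured a short lag after birth (`collar_date = parturition + lag`,
#' lag uniform on \[0, `max_capture_lag_days`\]); a collaring campaign
#' window, when given, leaves calves whose capture would fall outside it
#' unsampled (the sampling bias of collaring-date parturition proxies);
#' calves dying before their capture date are never collared; observed
#' mortality dates lag the true ones by a monitoring delay (uniform on
#' \[0, `max_detection_delay_days`\]).
#'
#' @param truth Truth tibble from [simulate_herd()].
#' @param collaring_window Optional 2-element Date/POSIXct campaign
#'   window; `NULL` (default) samples every calf.
#' @param max_capture_lag_days Maximum capture lag after birth, days
#'   (most calves are captured within a few days of birth).
#' @param max_detection_delay_days Maximum delay between death and its
#'   detection, days (monitoring is every few days).
#' @param horizon_days Monitoring horizon after collaring, days.
#' @param seed Optional RNG seed.
#' @return Tibble `calf_id`, `collar_date` (the parturition-date proxy),
#'   `last_alive_date`, `mortality_date` (NA when the calf survived the
#'   horizon).
#' @export
simulate_vhf_calves <- function(truth, collaring_window = NULL,
                                max_capture_lag_days = 3,
                                max_detection_delay_days = 3,
                                horizon_days = 28, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  part <- truth[truth$parturient %in% TRUE, , drop = FALSE]
  if (nrow(part) == 0) stop("no parturient females in truth", call. = FALSE)
  lag <- runif(nrow(part), 0, max_capture_lag_days)
  collar <- part$parturition_date + lag * 86400
  died <- part$fate == "mortality" & !is.na(part$mortality_date)
  sampled <- rep(TRUE, nrow(part))
  if (!is.null(collaring_window)) {
    cw <- as.POSIXct(collaring_window, tz = "UTC")
    sampled <- collar >= cw[1] & collar <= cw[2]
  }
  sampled <- sampled & !(died & part$mortality_date <= collar)
  delay <- runif(nrow(part), 0, max_detection_delay_days)
  horizon_end <- collar + horizon_days * 86400
  obs_mort <- as.POSIXct(ifelse(
    died & part$mortality_date <= horizon_end,
    as.numeric(part$mortality_date + delay * 86400), NA_real_),
    tz = "UTC", origin = "1970-01-01")
  last_alive <- as.POSIXct(ifelse(is.na(obs_mort),
                                  as.numeric(horizon_end),
                                  as.numeric(part$mortality_date)),
                           tz = "UTC", origin = "1970-01-01")
  out <- tibble::tibble(calf_id = paste0(part$animal_id, "-calf"),
                        collar_date = collar,
                        last_alive_date = last_alive,
                        mortality_date = obs_mort)
  out[sampled, , drop = FALSE]
}
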