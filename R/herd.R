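#' Convert predictions into 0-28 day calf survival records
#'
#' Each prediction with a parturition date yields a survival record with
#' per-subject time origin at parturition (day resolution): an observed
#' mortality within the horizon gives `(time, event = 1)`; an affirmed
#' survival (or a mortality beyond the horizon) gives
#' `(horizon, event = 0)`.  Predictions with inconclusive fate are
#' excluded (the inconclusive category carries no time stamp) and counted;
#' records with a mortality date at or before parturition are rejected
#' with a warning.
#'
#' @param predictions Tibble with `animal_id`, `status`,
#'   `parturition_date`, `mortality_date` (e.g. from [pbm_herd()],
#'   [ibm_herd()] or [combined_method()]).
#' @param horizon_days Assessment horizon, days (default 28 = 4 weeks).
#' @return Tibble `subject_id`, `time` (days, in (0, horizon\]), `event`
#'   (1 = mortality, 0 = censored), with attributes `n_excluded`
#'   (inconclusive fates) and `n_rejected` (bad dates).
#' @export
build_survival_records <- function(predictions, horizon_days = 28) {
  p <- predictions[predictions$status %in%
                     c("parturition_survived", "parturition_mortality",
                       "parturition_with_inconclusive_fate"), , drop = FALSE]
  n_excluded <- sum(p$status == "parturition_with_inconclusive_fate")
  p <- p[p$status != "parturition_with_inconclusive_fate", , drop = FALSE]
  n_rejected <- 0L
  rows <- lapply(seq_len(nrow(p)), function(i) {
    if (p$status[i] == "parturition_mortality" &&
        !is.na(p$mortality_date[i])) {
      dt <- as.numeric(as.Date(p$mortality_date[i]) -
                         as.Date(p$parturition_date[i]))
      if (dt <= 0) return(structure(list(), bad = TRUE))
      if (dt <= horizon_days) {
        return(tibble::tibble(subject_id = p$animal_id[i], time = dt,
                              event = 1L))
      }
    }
    tibble::tibble(subject_id = p$animal_id[i],
                   time = as.numeric(horizon_days), event = 0L)
  })
  bad <- vapply(rows, function(r) isTRUE(attr(r, "bad")), logical(1))
  if (any(bad)) {
    warning(sum(bad), " record(s) rejected: mortality date not after ",
            "parturition date", call. = FALSE)
    n_rejected <- sum(bad)
    rows <- rows[!bad]
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(subject_id = character(), time = double(),
                   event = integer())
  attr(out, "n_excluded") <- n_excluded
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Kaplan-Meier product-limit survival curve
#'
#' Product-limit estimator over distinct observed event times, with
#' Greenwood variance and log-transformed 95% confidence limits
#' (`S * exp(+/- z * se(log S))`, truncated to \[0, 1\]).
#'
#' @param records Survival records (`time`, `event`) from
#'   [build_survival_records()].
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `survival_curve`: tibble with `time`
#'   (including 0), `n_risk`, `n_event`, `surv`, `var_greenwood`,
#'   `lower`, `upper`.
#' @export
kaplan_meier <- function(records, conf_level = 0.95) {
  if (nrow(records) == 0) stop("no survival records", call. = FALSE)
  stopifnot(all(records$time > 0), all(records$event %in% c(0, 1)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  et <- sort(unique(records$time[records$event == 1]))
  n0 <- nrow(records)
  if (length(et) == 0) {
    out <- tibble::tibble(time = 0, n_risk = n0, n_event = 0L, surv = 1,
                          var_greenwood = 0, lower = 1, upper = 1)
    class(out) <- c("survival_curve", class(out))
    return(out)
  }
  n_risk <- vapply(et, function(t) sum(records$time >= t), double(1))
  d <- vapply(et, function(t) sum(records$time == t & records$event == 1),
              double(1))
  surv <- cumprod(1 - d / n_risk)
  gw <- cumsum(d / (n_risk * (n_risk - d)))  # var(log S)
  var_greenwood <- surv^2 * gw
  se_log <- sqrt(gw)
  lower <- ifelse(surv > 0, pmax(0, surv * exp(-z * se_log)), NA_real_)
  upper <- ifelse(surv > 0, pmin(1, surv * exp(z * se_log)), NA_real_)
  out <- tibble::tibble(
    time = c(0, et), n_risk = c(n0, n_risk), n_event = c(0L, as.integer(d)),
    surv = c(1, surv), var_greenwood = c(0, var_greenwood),
    lower = c(1, lower), upper = c(1, upper)
  )
  class(out) <- c("survival_curve", class(out))
  out
}

#' Log-rank comparison of survival curves
#'
#' Standard log-rank test over pooled risk sets: observed minus expected
#' events per group, with the hypergeometric variance-covariance matrix,
#' and a chi-square statistic on `length(groups) - 1` degrees of freedom.
#'
#' @param groups List of two or more survival-record tibbles
#'   (`time`, `event`), one per group.
#' @return List with `chi2`, `df`, `p`, `observed`, `expected`.
#' @export
log_rank <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  sizes <- vapply(groups, nrow, integer(1))
  if (any(sizes == 0)) stop("every group must be non-empty", call. = FALSE)
  k <- length(groups)
  all_t <- unlist(lapply(groups, function(g) g$time[g$event == 1]))
  et <- sort(unique(all_t))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (tj in et) {
    n_g <- vapply(groups, function(g) sum(g$time >= tj), double(1))
    d_g <- vapply(groups, function(g) sum(g$time == tj & g$event == 1),
                  double(1))
    n <- sum(n_g); d <- sum(d_g)
    if (n == 0 || d == 0) next
    O <- O + d_g
    E <- E + d * n_g / n
    if (n > 1) {
      c0 <- d * (n - d) / (n - 1)
      for (g in seq_len(k)) {
        for (h in seq_len(k)) {
          V[g, h] <- V[g, h] +
            c0 * (n_g[g] / n) * ((g == h) - n_g[h] / n)
        }
      }
    }
  }
  z <- (O - E)[-k]
  Vs <- V[-k, -k, drop = FALSE]
  chi2 <- tryCatch(as.numeric(t(z) %*% solve(Vs, z)),
                   error = function(e) 0)
  list(chi2 = chi2, df = k - 1, p = pchisq(chi2, df = k - 1,
                                           lower.tail = FALSE),
       observed = O, expected = E)
}

#' Kernel density of event dates
#'
#' Gaussian kernel density of calendar event dates (parturition or
#' mortality) on a day-of-year scale, normalized to integrate to 1 over
#' the output grid.
#'
#' @param dates Date or POSIXct vector (>= 2 values).
#' @param bandwidth_days Kernel bandwidth in days (default 2).
#' @param n_grid Grid size (default 512).
#' @return Tibble with `date` (Date), `day` (numeric day since epoch) and
#'   `density` (1/day), with attribute `bandwidth_days`.
#' @export
date_density <- function(dates, bandwidth_days = 2, n_grid = 512) {
  x <- as.numeric(as.Date(dates))
  if (length(x) < 2) stop("need at least two dates", call. = FALSE)
  stopifnot(bandwidth_days > 0)
  den <- density(x, bw = bandwidth_days, n = n_grid,
                 from = min(x) - 4 * bandwidth_days,
                 to = max(x) + 4 * bandwidth_days)
  dx <- diff(den$x)
  total <- sum((den$y[-1] + den$y[-length(den$y)]) / 2 * dx)
  out <- tibble::tibble(date = as.Date(den$x, origin = "1970-01-01"),
                        day = den$x, density = den$y / total)
  attr(out, "bandwidth_days") <- bandwidth_days
  out
}

#' Combined classifier: PBM parturition, IBM calf fate
#'
#' The population-based method is the better parturition detector and the
#' individual-based method the better mortality detector, so the combined
#' classifier takes parturition status and date from the PBM consensus and
#' then, for PBM-parturient females only, determines calf fate with the
#' IBM: mortality if and only if the calf-mortality model (M2) is selected
#' definitively; otherwise the calf is assumed to have survived.
#' Non-parturient and parturition-inconclusive females carry no fate.
#'
#' @param pbm_predictions Consensus tibble from [pbm_herd()].
#' @param steps Step tibble for the same animals.
#' @param season Season window.
#' @inheritParams ibm_classify
#' @return Tibble `animal_id`, `status`, `parturition_date`,
#'   `mortality_date`, `missing_trajectory` (flag for PBM-parturient
#'   females lacking steps; such females are excluded from survival
#'   records).
#' @export
combined_method <- function(pbm_predictions, steps, season,
                            recovery_hours = 672, delta_threshold = 2,
                            min_segment = 5, min_steps = 30,
                            floor_frac = NULL,
                            interval_hours = attr(steps, "nominal_interval")) {
  rows <- lapply(seq_len(nrow(pbm_predictions)), function(i) {
    p <- pbm_predictions[i, ]
    base <- tibble::tibble(animal_id = p$animal_id, status = p$status,
                           parturition_date = p$parturition_date,
                           mortality_date = as.POSIXct(NA),
                           missing_trajectory = FALSE)
    if (!(p$status %in% c("parturition_survived", "parturition_mortality",
                          "parturition_with_inconclusive_fate"))) {
      return(base)  # no parturition (or inconclusive): no fate assessed
    }
    st <- steps[steps$animal_id == p$animal_id, , drop = FALSE]
    if (nrow(st) == 0) {
      base$status <- "parturition_with_inconclusive_fate"
      base$missing_trajectory <- TRUE
      return(base)
    }
    attr(st, "nominal_interval") <- interval_hours
    r <- ibm_classify(st, season, recovery_hours = recovery_hours,
                      delta_threshold = delta_threshold,
                      min_segment = min_segment, min_steps = min_steps,
                      floor_frac = floor_frac,
                      interval_hours = interval_hours)
    if (r$status == "parturition_mortality") {
      base$status <- "parturition_mortality"
      base$mortality_date <- r$mortality_date
    } else {
      base$status <- "parturition_survived"
    }
    base
  })
  do.call(rbind, rows)
}
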