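#' Season window helper
#'
#' Builds the two-element POSIXct (UTC) vector used as a calving-season
#' window, e.g. `season_window("2016-05-21", "2016-07-30")`.  The end date
#' is inclusive (extended to the end of that day).
#'
#' @param start,end Dates (`Date`, character `"YYYY-MM-DD"`, or POSIXct).
#' @return POSIXct vector of length 2, UTC.
#' @export
season_window <- function(start, end) {
  s <- as.POSIXct(start, tz = "UTC")
  e <- as.POSIXct(end, tz = "UTC")
  if (inherits(end, "Date") || (is.character(end) && nchar(end) <= 10)) {
    e <- e + 86400 - 1  # inclusive calendar day
  }
  if (e <= s) stop("season end must be after season start", call. = FALSE)
  c(s, e)
}

.hours <- function(t) as.numeric(t) / 3600

#' Expected mean step length under the a priori movement models
#'
#' The three candidate models for a female over the calving season share an
#' exponential step-length distribution and differ only in how its mean
#' varies over time:
#' * `M0` (no parturition): constant mean `a`;
#' * `M1` (calf survived): mean drops abruptly at the parturition
#'   breakpoint `bp`, then recovers linearly with elapsed time, reaching
#'   `a` again after `recovery_hours` (four weeks by default, when calf
#'   mobility approaches adult rates);
#' * `M2` (calf mortality): as `M1` between `bp` and the mortality
#'   breakpoint `mp`, then an abrupt return to `a` after `mp`.
#'
#' Immediately after `bp` the linear recovery is floored at
#' `floor_frac * a` so the likelihood stays finite; the default floor is
#' one fix interval into the recovery, i.e. the first-step mean of the
#' per-step formulation.
#'
#' @param model `"M0"`, `"M1"` or `"M2"`.
#' @param t Step times (POSIXct or numeric hours), ordered.
#' @param a Pre-calving mean step length, metres (> 0).
#' @param bp,mp Breakpoint times (same representation as `t`); `bp`
#'   required for M1/M2, `mp` for M2, with `bp < mp <= bp + recovery_hours`.
#' @param recovery_hours Recovery duration, hours (default 672 = 4 weeks).
#' @param floor_frac Lower bound on the recovery ramp as a fraction of `a`.
#' @return Numeric vector of expected mean step lengths, one per time.
#' @export
mean_profile <- function(model, t, a, bp = NULL, mp = NULL,
                         recovery_hours = 672, floor_frac = 2 / 672) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0) {
    stop("a must be a positive number", call. = FALSE)
  }
  stopifnot(recovery_hours > 0, floor_frac > 0, floor_frac < 1)
  th <- if (inherits(t, "POSIXct")) .hours(t) else as.numeric(t)
  if (model == "M0") return(rep(a, length(th)))
  if (is.null(bp)) stop("bp required for ", model, call. = FALSE)
  bph <- if (inherits(bp, "POSIXct")) .hours(bp) else as.numeric(bp)
  ramp <- pmin(1, pmax(floor_frac, (th - bph) / recovery_hours))
  mu <- ifelse(th <= bph, 1, ramp)
  if (model == "M2") {
    if (is.null(mp)) stop("mp required for M2", call. = FALSE)
    mph <- if (inherits(mp, "POSIXct")) .hours(mp) else as.numeric(mp)
    if (mph <= bph || mph > bph + recovery_hours) {
      stop("require bp < mp <= bp + recovery_hours", call. = FALSE)
    }
    mu[th > mph] <- 1
  } else if (model != "M1") {
    stop("unknown model: ", model, call. = FALSE)
  }
  a * mu
}

#' Negative log-likelihood of exponential step lengths
#'
#' For step lengths `d_i` with expected means `mu_i`,
#' `nll = sum(log(mu_i) + d_i / mu_i)` (dropping no terms; the exponential
#' density is `exp(-d/mu)/mu`).
#'
#' @param lengths Observed step lengths, metres (>= 0).
#' @param means Expected means, metres (> 0), same length.
#' @return The negative log-likelihood.
#' @export
nll_exponential <- function(lengths, means) {
  if (length(lengths) != length(means)) {
    stop("lengths and means must have equal length", call. = FALSE)
  }
  if (any(means <= 0)) stop("means must be positive", call. = FALSE)
  if (any(lengths < 0)) stop("step lengths must be non-negative", call. = FALSE)
  sum(log(means) + lengths / means)
}

# Restrict a single-animal step table to the season window.
.season_steps <- function(steps, season) {
  if (length(unique(steps$animal_id)) > 1) {
    stop("fit expects steps for a single animal", call. = FALSE)
  }
  steps[steps$t_start >= season[1] & steps$t_start <= season[2], ,
        drop = FALSE]
}

#' Fit one a priori movement model by maximum likelihood
#'
#' For fixed breakpoints the mean profile has the form `mu_i = a * r_i`
#' with known relative profile `r_i`, so the conditional MLE of the scale
#' is closed-form, `a* = mean(d_i / r_i)`, and the profiled NLL reduces to
#' `sum(log r_i) + n log a* + n`.  The fit grid-searches the parturition
#' breakpoint `bp` (and for M2 the mortality breakpoint `mp`) over observed
#' step start times, subject to at least `min_segment` steps on each side
#' of each breakpoint (before `bp`, between `bp` and `mp`, and after `mp`;
#' after `bp` for M1) and `bp < mp <= bp + recovery_hours`,
#' and returns the global NLL minimum.  NLL ties are broken by earliest
#' `bp`, then earliest `mp`.
#'
#' @param steps Step tibble for one animal ([build_steps()]).
#' @param model `"M0"`, `"M1"` or `"M2"`.
#' @param season Season window ([season_window()]); only steps starting
#'   inside it are used.
#' @param recovery_hours Recovery duration, hours.
#' @param min_segment Minimum steps on each side of any breakpoint.
#' @param floor_frac Recovery-ramp floor fraction; default one nominal fix
#'   interval into the ramp (`interval_hours / recovery_hours`).
#' @param interval_hours Nominal fix interval; defaults to the
#'   `nominal_interval` attribute of `steps`.
#'
#' @return An object of class `movement_model_fit`: a list with `model`,
#'   `a`, `bp`, `mp` (POSIXct or NA), `nll`, `n_params`, `aic`, `n_steps`,
#'   `feasible` and (when infeasible) `reason`.
#' @export
fit_movement_model <- function(steps, model, season, recovery_hours = 672,
                               min_segment = 5, floor_frac = NULL,
                               interval_hours = attr(steps, "nominal_interval")) {
  ss <- .season_steps(steps, season)
  n <- nrow(ss)
  if (is.null(floor_frac)) {
    if (is.null(interval_hours)) {
      stop("interval_hours needed to set the default recovery floor",
           call. = FALSE)
    }
    floor_frac <- interval_hours / recovery_hours
  }
  infeasible <- function(reason) {
    structure(list(model = model, a = NA_real_, bp = as.POSIXct(NA),
                   mp = as.POSIXct(NA), nll = NA_real_,
                   n_params = switch(model, M0 = 1L, M1 = 2L, M2 = 3L),
                   aic = NA_real_, n_steps = n, feasible = FALSE,
                   reason = reason),
              class = "movement_model_fit")
  }
  if (n < 2 * min_segment + 1 && model != "M0") {
    return(infeasible("too few steps for breakpoint search"))
  }
  if (n < 1) return(infeasible("no steps in season"))
  d <- ss$length
  th <- .hours(ss$t_start)
  done <- function(a, nll, n_params, bp = NA, mp = NA) {
    structure(list(model = model, a = a,
                   bp = if (is.na(bp[1])) as.POSIXct(NA) else ss$t_start[bp],
                   mp = if (is.na(mp[1])) as.POSIXct(NA) else ss$t_start[mp],
                   nll = nll, n_params = n_params,
                   aic = 2 * n_params + 2 * nll, n_steps = n,
                   feasible = TRUE),
              class = "movement_model_fit")
  }
  if (model == "M0") {
    a <- mean(d)
    if (a <= 0) return(infeasible("degenerate all-zero step lengths"))
    return(done(a, n * log(a) + n, 1L))
  }
  D <- sum(d)
  b_lo <- min_segment
  best <- list(nll = Inf, b = NA, m = NA)
  if (model == "M1") {
    for (b in b_lo:(n - min_segment)) {
      post <- (b + 1):n
      g <- pmin(1, pmax(floor_frac, (th[post] - th[b]) / recovery_hours))
      S2 <- (D - sum(d[post])) + sum(d[post] / g)
      a_star <- S2 / n
      nll <- sum(log(g)) + n * log(a_star) + n
      if (nll < best$nll) best <- list(nll = nll, b = b, m = NA)
    }
    if (!is.finite(best$nll)) return(infeasible("no feasible breakpoint"))
    post <- (best$b + 1):n
    g <- pmin(1, pmax(floor_frac, (th[post] - th[best$b]) / recovery_hours))
    a <- ((D - sum(d[post])) + sum(d[post] / g)) / n
    return(done(a, best$nll, 2L, bp = best$b))
  }
  # M2: for each bp, cumulative sums over the candidate mp give all NLLs
  # in one pass
  for (b in b_lo:(n - min_segment - 1)) {
    post <- (b + 1):n
    g <- pmin(1, pmax(floor_frac, (th[post] - th[b]) / recovery_hours))
    cum_lg <- cumsum(log(g))
    cum_d <- cumsum(d[post])
    cum_dg <- cumsum(d[post] / g)
    m_all <- post  # candidate mp indices (absolute)
    # min_segment steps on each side of each breakpoint, including between
    # bp and mp: a one-step mortality window would just absorb the single
    # smallest step and is not an identifiable event
    feas <- (n - m_all) >= min_segment &
      (m_all - b) >= min_segment &
      th[m_all] <= th[b] + recovery_hours
    if (!any(feas)) next
    p <- which(feas)  # positions within post
    S2 <- D - cum_d[p] + cum_dg[p]
    a_star <- S2 / n
    nll <- cum_lg[p] + n * log(a_star) + n
    j <- which.min(nll)
    if (nll[j] < best$nll) best <- list(nll = nll[j], b = b, m = m_all[p[j]])
  }
  if (!is.finite(best$nll)) return(infeasible("no feasible breakpoint pair"))
  b <- best$b; m <- best$m
  post <- (b + 1):n
  g <- pmin(1, pmax(floor_frac, (th[post] - th[b]) / recovery_hours))
  in_rec <- post <= m
  S2 <- D - sum(d[post][in_rec]) + sum((d[post] / g)[in_rec])
  done(S2 / n, best$nll, 3L, bp = b, mp = m)
}

#' @export
print.movement_model_fit <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("<%s: infeasible (%s)>\n", x$model, x$reason))
    return(invisible(x))
  }
  cat(sprintf("<%s fit: a = %.1f m, nll = %.2f, AIC = %.2f", x$model, x$a,
              x$nll, x$aic))
  if (!is.na(x$bp)) cat(sprintf(", bp = %s", format(x$bp, "%Y-%m-%d %H:%M")))
  if (!is.na(x$mp)) cat(sprintf(", mp = %s", format(x$mp, "%Y-%m-%d %H:%M")))
  cat(">\n")
  invisible(x)
}

#' Select the reproductive state by AIC
#'
#' The best-supported model is the one with lowest AIC; the selection is
#' definitive when the runner-up trails by more than `delta_threshold` AIC
#' units.  When M1 and M2 compete within the threshold but M0 does not,
#' parturition is affirmed with the calf's fate inconclusive; when M0 is
#' among the competitors the whole selection is inconclusive.
#'
#' @param fits List of `movement_model_fit` objects (one per model).
#' @param delta_threshold Definitive-support margin in AIC units
#'   (default 2).
#' @return An object of class `ibm_result`: list with `fits`, `delta_aic`
#'   (named, NA for infeasible fits), `best_model`, `definitive`, `status`
#'   (one of `no_parturition`, `parturition_survived`,
#'   `parturition_mortality`, `parturition_with_inconclusive_fate`,
#'   `inconclusive`), `parturition_date`, `mortality_date`.
#' @export
select_model <- function(fits, delta_threshold = 2) {
  names(fits) <- vapply(fits, `[[`, character(1), "model")
  aic <- vapply(fits, function(f) if (f$feasible) f$aic else NA_real_,
                double(1))
  res <- list(fits = fits, delta_aic = aic,
              best_model = NA_character_, definitive = FALSE,
              status = "inconclusive",
              parturition_date = as.POSIXct(NA),
              mortality_date = as.POSIXct(NA))
  class(res) <- "ibm_result"
  if (all(is.na(aic))) {
    return(res)
  }
  res$delta_aic <- aic - min(aic, na.rm = TRUE)
  ord <- order(aic, na.last = TRUE)
  best <- names(aic)[ord[1]]
  res$best_model <- best
  competing <- names(aic)[!is.na(aic) & (aic - aic[ord[1]]) <= delta_threshold]
  res$definitive <- length(competing) == 1
  if (res$definitive) {
    res$status <- switch(best, M0 = "no_parturition",
                         M1 = "parturition_survived",
                         M2 = "parturition_mortality")
  } else if (!("M0" %in% competing)) {
    res$status <- "parturition_with_inconclusive_fate"
  } else {
    res$status <- "inconclusive"
  }
  if (res$status %in% c("parturition_survived", "parturition_mortality",
                        "parturition_with_inconclusive_fate") &&
      best %in% c("M1", "M2")) {
    res$parturition_date <- fits[[best]]$bp
  }
  if (res$status == "parturition_mortality") {
    res$mortality_date <- fits[["M2"]]$mp
  }
  res
}

#' @export
print.ibm_result <- function(x, ...) {
  cat("<ibm_result>\n  status:", x$status, "\n")
  da <- paste(sprintf("%s %.2f", names(x$delta_aic), x$delta_aic),
              collapse = ", ")
  cat("  delta AIC:", da, "\n")
  if (!is.na(x$parturition_date)) {
    cat("  parturition:", format(x$parturition_date, "%Y-%m-%d %H:%M"), "\n")
  }
  if (!is.na(x$mortality_date)) {
    cat("  mortality:  ", format(x$mortality_date, "%Y-%m-%d %H:%M"), "\n")
  }
  invisible(x)
}

#' Individual-based classification of one female
#'
#' Fits the three a priori models ([fit_movement_model()]) to one animal's
#' in-season steps and selects the reproductive state by AIC
#' ([select_model()]).  Trajectories with fewer than `min_steps` in-season
#' steps are returned as inconclusive without fitting.
#'
#' @inheritParams fit_movement_model
#' @inheritParams select_model
#' @param min_steps Minimum in-season steps required to attempt a fit.
#' @return An `ibm_result` (see [select_model()]).
#' @export
ibm_classify <- function(steps, season, recovery_hours = 672,
                         delta_threshold = 2, min_segment = 5,
                         min_steps = 30, floor_frac = NULL,
                         interval_hours = attr(steps, "nominal_interval")) {
  ss <- .season_steps(steps, season)
  if (nrow(ss) < min_steps) {
    res <- list(fits = list(), delta_aic = c(M0 = NA, M1 = NA, M2 = NA),
                best_model = NA_character_, definitive = FALSE,
                status = "inconclusive",
                parturition_date = as.POSIXct(NA),
                mortality_date = as.POSIXct(NA))
    class(res) <- "ibm_result"
    return(res)
  }
  fits <- lapply(c("M0", "M1", "M2"), function(m) {
    fit_movement_model(steps, m, season, recovery_hours = recovery_hours,
                       min_segment = min_segment, floor_frac = floor_frac,
                       interval_hours = interval_hours)
  })
  select_model(fits, delta_threshold = delta_threshold)
}

#' Individual-based classification of a herd
#'
#' Runs [ibm_classify()] on every animal in a multi-animal step table.
#'
#' @param steps Step tibble for one or more animals.
#' @inheritParams ibm_classify
#' @return A tibble with one row per animal: `animal_id`, `status`,
#'   `best_model`, `definitive`, `parturition_date`, `mortality_date`,
#'   `aic_m0`, `aic_m1`, `aic_m2`.
#' @export
ibm_herd <- function(steps, season, recovery_hours = 672,
                     delta_threshold = 2, min_segment = 5, min_steps = 30,
                     floor_frac = NULL,
                     interval_hours = attr(steps, "nominal_interval")) {
  ids <- unique(steps$animal_id)
  rows <- lapply(ids, function(id) {
    st <- steps[steps$animal_id == id, , drop = FALSE]
    attr(st, "nominal_interval") <- interval_hours
    r <- ibm_classify(st, season, recovery_hours = recovery_hours,
                      delta_threshold = delta_threshold,
                      min_segment = min_segment, min_steps = min_steps,
                      floor_frac = floor_frac,
                      interval_hours = interval_hours)
    aic <- function(m) {
      if (length(r$fits) && r$fits[[m]]$feasible) r$fits[[m]]$aic else NA_real_
    }
    tibble::tibble(animal_id = id, status = r$status,
                   best_model = r$best_model, definitive = r$definitive,
                   parturition_date = r$parturition_date,
                   mortality_date = r$mortality_date,
                   aic_m0 = if (length(r$fits)) aic("M0") else NA_real_,
                   aic_m1 = if (length(r$fits)) aic("M1") else NA_real_,
                   aic_m2 = if (length(r$fits)) aic("M2") else NA_real_)
  })
  do.call(rbind, rows)
}
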