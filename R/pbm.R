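#' Three-day average movement rate (TDAM) in a moving window
#'
#' Computes, for each animal, the average movement rate over a 72-hour
#' moving window slid by one nominal fix interval: the summed step length
#' in the window divided by the summed step duration (metres/hour).  Only
#' steps fully contained in a window contribute; windows whose observed
#' step time covers less than `min_coverage` of the window are reported as
#' missing (`NA`) rather than biased.
#'
#' @param steps Step tibble from [build_steps()] (one or more animals).
#' @param window_hours Window width, hours (default 72 = 3 days).
#' @param min_coverage Minimum fraction of the window that must be covered
#'   by observed steps (default 0.5).
#' @param interval_hours Window slide, hours; defaults to the step table's
#'   nominal fix interval.
#'
#' @return A tibble with `animal_id`, `window_start` (POSIXct), `tdam`
#'   (m/h or NA) and `coverage`, with attribute `window_hours`.
#' @export
tdam <- function(steps, window_hours = 72, min_coverage = 0.5,
                 interval_hours = attr(steps, "nominal_interval")) {
  if (is.null(interval_hours)) {
    stop("interval_hours required (no nominal_interval attribute)",
         call. = FALSE)
  }
  if (window_hours < 2 * interval_hours) {
    stop("window must span at least two fix intervals", call. = FALSE)
  }
  if (nrow(steps) == 0) stop("empty step table", call. = FALSE)
  parts <- split(steps, steps$animal_id)
  out <- lapply(parts, function(st) {
    st <- st[order(st$t_start), , drop = FALSE]
    ts <- as.numeric(st$t_start)
    te <- as.numeric(st$t_end)
    w <- window_hours * 3600
    if (max(te) - w < ts[1]) return(NULL)  # track shorter than one window
    starts <- seq(ts[1], max(te) - w, by = interval_hours * 3600)
    i_lo <- findInterval(starts, ts, left.open = TRUE) + 1L
    i_hi <- findInterval(starts + w, te)
    cumL <- c(0, cumsum(st$length))
    cumD <- c(0, cumsum(st$duration_h))
    empty <- i_hi < i_lo
    sumL <- ifelse(empty, 0, cumL[i_hi + 1L] - cumL[i_lo])
    sumD <- ifelse(empty, 0, cumD[i_hi + 1L] - cumD[i_lo])
    coverage <- sumD / window_hours
    tibble::tibble(
      animal_id = st$animal_id[1],
      window_start = as.POSIXct(starts, tz = "UTC",
                                origin = "1970-01-01"),
      tdam = ifelse(coverage >= min_coverage, sumL / pmax(sumD, 1e-12), NA_real_),
      coverage = coverage
    )
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  attr(res, "window_hours") <- window_hours
  res
}

# 99.9%-style quantile of a boundary-reflected Gaussian KDE.
# Reflection at zero is done by augmenting the sample with its negation and
# doubling the density on [0, inf); the CDF is a trapezoid integral on a
# regular grid and the quantile its linear-interpolation inverse.
.kde_quantile <- function(x, level, bw = NULL, n_grid = 4096) {
  stopifnot(length(x) >= 1, all(is.finite(x)), all(x >= 0))
  if (is.null(bw)) {
    bw <- if (length(x) >= 2 && stats::sd(x) > 0) bw.nrd0(x) else
      max(mean(x), 1) * 1e-6
  }
  if (!is.finite(bw) || bw <= 0) bw <- max(mean(x), 1) * 1e-6
  to <- max(x) + 4 * bw
  den <- density(c(x, -x), bw = bw, n = n_grid, from = 0, to = to)
  f <- 2 * den$y
  g <- den$x
  dx <- diff(g)
  cdf <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * dx))
  cdf <- cdf / cdf[length(cdf)]
  approx(cdf, g, xout = level, ties = "ordered")$y
}

# Eligible reference females and their period windows for one threshold.
# Period bounds are anchored at the first full calendar day after the
# parturition timestamp: day resolution lets the 72-h windows on the fix
# grid fall inside the period, and starting after the event keeps
# pre-calving movement out of the post-calving TDAM pool.
.eligible_status <- function(status, period) {
  s <- status[!is.na(status$parturient) & status$parturient, , drop = FALSE]
  if (period == "post_calving_3d") {
    # calf survived at least 1 week
    keep <- s$fate == "survived_4wk" |
      (s$fate == "mortality" & !is.na(s$mortality_date) &
         as.numeric(difftime(s$mortality_date, s$parturition_date,
                             units = "days")) >= 7)
  } else if (period == "weeks_2_to_4") {
    keep <- s$fate == "survived_4wk"
  } else {
    stop("unknown period: ", period, call. = FALSE)
  }
  s[keep & !is.na(keep), , drop = FALSE]
}

.period_bounds <- function(parturition_date, period) {
  d0 <- as.POSIXct(format(parturition_date, "%Y-%m-%d"), tz = "UTC")
  if (d0 <= parturition_date) d0 <- d0 + 86400  # first full post-calving day
  if (period == "post_calving_3d") c(d0, d0 + 3 * 86400)
  else c(d0 + 14 * 86400, d0 + 28 * 86400)
}

#' Movement-rate threshold from reference females
#'
#' Pools in-period TDAM values from reference females with known calving
#' histories, smooths them with a Gaussian kernel density estimate
#' reflected at zero, converts the KDE to a CDF by numerical integration,
#' and returns the `quantile_level` (default 99.9%) inverse-CDF value.
#'
#' Two periods are supported:
#' * `"post_calving_3d"` -- windows fully contained in the 3 days after
#'   parturition, from females whose calf survived at least 1 week; the
#'   resulting quantile is the **parturition threshold** (movement below it
#'   indicates calving);
#' * `"weeks_2_to_4"` -- windows fully contained in days 14-28 after
#'   parturition, from females whose calf survived to 4 weeks; the
#'   resulting quantile is the **calf-mortality threshold** (movement above
#'   it, after a detected parturition, indicates calf loss).
#'
#' @param tdam_tbl TDAM tibble from [tdam()].
#' @param status Known-status tibble: `animal_id`, `parturient` (logical),
#'   `parturition_date` (POSIXct), `fate`
#'   (`"survived_4wk"`, `"mortality"`, `"unknown"`), `mortality_date`.
#' @param period `"post_calving_3d"` or `"weeks_2_to_4"`.
#' @param quantile_level CDF quantile returned (default 0.999).
#' @param bw Kernel bandwidth (m/h); default Silverman's rule on the pooled
#'   sample.
#' @param window_hours TDAM window width, hours.
#' @return The threshold (m/h), with attributes `n_values`, `n_females`
#'   and `bw`.
#' @export
threshold_from_reference <- function(tdam_tbl, status,
                                     period = c("post_calving_3d",
                                                "weeks_2_to_4"),
                                     quantile_level = 0.999, bw = NULL,
                                     window_hours = attr(tdam_tbl,
                                                         "window_hours") %||% 72) {
  period <- match.arg(period)
  elig <- .eligible_status(status, period)
  if (nrow(elig) == 0) {
    stop("no eligible reference females for period ", period, call. = FALSE)
  }
  vals <- numeric(0)
  n_f <- 0L
  for (i in seq_len(nrow(elig))) {
    bounds <- .period_bounds(elig$parturition_date[i], period)
    tt <- tdam_tbl[tdam_tbl$animal_id == elig$animal_id[i], , drop = FALSE]
    inwin <- tt$window_start >= bounds[1] &
      (as.numeric(tt$window_start) + window_hours * 3600) <= as.numeric(bounds[2])
    v <- tt$tdam[inwin & !is.na(tt$tdam)]
    if (length(v) > 0) n_f <- n_f + 1L
    vals <- c(vals, v)
  }
  if (length(vals) == 0) {
    stop("no in-period TDAM values for period ", period, call. = FALSE)
  }
  thr <- .kde_quantile(vals, quantile_level, bw = bw)
  attr(thr, "n_values") <- length(vals)
  attr(thr, "n_females") <- n_f
  attr(thr, "bw") <- if (is.null(bw)) {
    if (length(vals) >= 2 && stats::sd(vals) > 0) bw.nrd0(vals) else NA_real_
  } else bw
  thr
}

#' Classify one female against a parturition/mortality threshold pair
#'
#' Moving-window analysis: parturition is called at the first in-season
#' window whose TDAM falls below the parturition threshold (the window
#' start is the parturition date, the earliest time consistent with the
#' detection); if parturition is found, calf mortality is called at the
#' first window starting within 28 days after it whose TDAM exceeds the
#' mortality threshold.  Absence of either event is a valid outcome, and
#' no mortality is assessed without a parturition call.
#'
#' @param tdam_tbl TDAM tibble for a single animal.
#' @param parturition_threshold,mortality_threshold Thresholds, m/h.
#' @param season Season window ([season_window()]).
#' @param horizon_days Mortality search horizon after parturition
#'   (default 28, inclusive).
#' @return One-row tibble: `animal_id`, `parturition` (logical),
#'   `parturition_date`, `mortality` (logical), `mortality_date`.
#' @export
classify_pbm <- function(tdam_tbl, parturition_threshold,
                         mortality_threshold, season, horizon_days = 28) {
  id <- unique(tdam_tbl$animal_id)
  if (length(id) != 1) {
    stop("classify_pbm expects a single animal", call. = FALSE)
  }
  tt <- tdam_tbl[order(tdam_tbl$window_start), , drop = FALSE]
  in_season <- tt$window_start >= season[1] & tt$window_start <= season[2]
  hit <- which(in_season & !is.na(tt$tdam) & tt$tdam < parturition_threshold)
  if (length(hit) == 0) {
    return(tibble::tibble(animal_id = id, parturition = FALSE,
                          parturition_date = as.POSIXct(NA),
                          mortality = NA, mortality_date = as.POSIXct(NA)))
  }
  pd <- tt$window_start[hit[1]]
  after <- tt$window_start > pd &
    tt$window_start <= pd + horizon_days * 86400
  mhit <- which(after & !is.na(tt$tdam) & tt$tdam > mortality_threshold)
  if (length(mhit) == 0) {
    return(tibble::tibble(animal_id = id, parturition = TRUE,
                          parturition_date = pd, mortality = FALSE,
                          mortality_date = as.POSIXct(NA)))
  }
  tibble::tibble(animal_id = id, parturition = TRUE, parturition_date = pd,
                 mortality = TRUE, mortality_date = tt$window_start[mhit[1]])
}

#' Exhaustive k-fold threshold resampling
#'
#' Enumerates every subset of the given size from the reference pool
#' (females that experienced parturition with the calf surviving to four
#' weeks, hence eligible for both threshold periods) in deterministic
#' lexicographic order, and computes the parturition and mortality
#' thresholds for each subset.  The subset count equals
#' `choose(pool, subset_size)`.
#'
#' @inheritParams threshold_from_reference
#' @param subset_size Number of reference females per subset; defaults to
#'   the whole pool (a single threshold set).
#' @param pool Optional character vector restricting the reference pool to
#'   specific animal ids (they must still be eligible).
#' @return A tibble with one row per subset: `set_id`, `ref_ids`
#'   (list-column), `parturition_threshold`, `mortality_threshold`.
#' @export
kfold_thresholds <- function(tdam_tbl, status, subset_size = NULL,
                             quantile_level = 0.999, bw = NULL,
                             window_hours = attr(tdam_tbl,
                                                 "window_hours") %||% 72,
                             pool = NULL) {
  elig <- .eligible_status(status, "weeks_2_to_4")  # survived 4 wk: both periods
  ids <- sort(elig$animal_id)
  if (!is.null(pool)) {
    missing <- setdiff(pool, ids)
    if (length(missing) > 0) {
      stop("pool ids not eligible: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    ids <- sort(pool)
  }
  if (length(ids) == 0) stop("empty reference pool", call. = FALSE)
  if (is.null(subset_size)) subset_size <- length(ids)
  if (subset_size > length(ids)) {
    stop("subset_size exceeds reference pool size (", length(ids), ")",
         call. = FALSE)
  }
  combos <- combn(ids, subset_size, simplify = FALSE)
  rows <- lapply(seq_along(combos), function(k) {
    sub <- combos[[k]]
    st <- status[status$animal_id %in% sub, , drop = FALSE]
    tt <- tdam_tbl[tdam_tbl$animal_id %in% sub, , drop = FALSE]
    attr(tt, "window_hours") <- window_hours
    tibble::tibble(
      set_id = k,
      ref_ids = list(sub),
      parturition_threshold = as.numeric(
        threshold_from_reference(tt, st, "post_calving_3d",
                                 quantile_level = quantile_level, bw = bw,
                                 window_hours = window_hours)),
      mortality_threshold = as.numeric(
        threshold_from_reference(tt, st, "weeks_2_to_4",
                                 quantile_level = quantile_level, bw = bw,
                                 window_hours = window_hours))
    )
  })
  do.call(rbind, rows)
}

#' Pool per-threshold-set predictions into consensus calls
#'
#' Combines single-set classifications ([classify_pbm()]) across threshold
#' sets into per-animal proportions.  A question's answer is conclusive
#' when its majority proportion reaches `cutoff` (default 0.8); consensus
#' event dates are the median over concurring sets.  Mortality proportions
#' are computed over the sets that predicted parturition, since no
#' mortality is assessed without one.
#'
#' Holdout is the caller's responsibility: predictions for an animal must
#' come only from threshold sets that did not include that animal (see
#' [pbm_herd()]).
#'
#' @param per_set Tibble of single-set predictions with a `set_id` column
#'   (rows = animal x set).
#' @param cutoff Conclusiveness cutoff on the pooled proportion.
#' @return A tibble with one row per animal: proportions for each outcome,
#'   conclusiveness flags, consensus `status` (`no_parturition`,
#'   `parturition_survived`, `parturition_mortality`,
#'   `parturition_with_inconclusive_fate`, `inconclusive`) and consensus
#'   dates.
#' @export
pool_predictions <- function(per_set, cutoff = 0.8) {
  if (nrow(per_set) == 0) stop("no per-set predictions", call. = FALSE)
  rows <- lapply(split(per_set, per_set$animal_id), function(p) {
    n <- nrow(p)
    prop_part <- mean(p$parturition)
    part_sets <- p[p$parturition, , drop = FALSE]
    prop_mort <- if (nrow(part_sets) > 0) mean(part_sets$mortality) else NA_real_
    part_call <- if (prop_part >= cutoff) "parturition"
      else if (1 - prop_part >= cutoff) "no_parturition" else "inconclusive"
    fate_call <- if (part_call != "parturition") NA_character_
      else if (prop_mort >= cutoff) "mortality"
      else if (1 - prop_mort >= cutoff) "survived" else "inconclusive"
    status <- if (part_call == "no_parturition") "no_parturition"
      else if (part_call == "inconclusive") "inconclusive"
      else switch(fate_call,
                  mortality = "parturition_mortality",
                  survived = "parturition_survived",
                  "parturition_with_inconclusive_fate")
    pd <- if (nrow(part_sets) > 0) {
      as.POSIXct(median(as.numeric(part_sets$parturition_date)),
                 tz = "UTC", origin = "1970-01-01")
    } else as.POSIXct(NA)
    mort_sets <- part_sets[part_sets$mortality %in% TRUE, , drop = FALSE]
    md <- if (nrow(mort_sets) > 0) {
      as.POSIXct(median(as.numeric(mort_sets$mortality_date)),
                 tz = "UTC", origin = "1970-01-01")
    } else as.POSIXct(NA)
    tibble::tibble(
      animal_id = p$animal_id[1], n_sets = n,
      prop_parturition = prop_part,
      prop_no_parturition = 1 - prop_part,
      prop_mortality = prop_mort,
      prop_survived = if (is.na(prop_mort)) NA_real_ else 1 - prop_mort,
      parturition_conclusive = max(prop_part, 1 - prop_part) >= cutoff,
      status = status,
      parturition_date = if (part_call == "parturition") pd else as.POSIXct(NA),
      mortality_date = if (identical(fate_call, "mortality")) md else as.POSIXct(NA)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population-based classification of a herd
#'
#' End-to-end PBM: computes TDAM series, builds threshold sets by
#' exhaustive resampling of the reference pool ([kfold_thresholds()]),
#' classifies every animal against every threshold set that did not
#' include it (the holdout rule), and pools the per-set predictions into
#' consensus calls ([pool_predictions()]).  Animals present in every
#' threshold set (e.g. the whole pool when `subset_size` equals the pool
#' size) have no admissible set and are omitted from the output.
#'
#' @param steps Step tibble for the herd ([build_steps()]), ideally after
#'   [rarefy_top_steps()].
#' @param status Known-status tibble for the reference females (see
#'   [threshold_from_reference()]).
#' @param season Season window ([season_window()]).
#' @inheritParams kfold_thresholds
#' @inheritParams pool_predictions
#' @param window_hours TDAM window width, hours.
#' @param min_coverage Minimum TDAM window coverage.
#' @param horizon_days Mortality search horizon, days.
#' @param interval_hours Nominal fix interval, hours.
#' @return A list with `predictions` (per-animal consensus tibble),
#'   `thresholds` (per-subset tibble) and `tdam` (the TDAM table).
#' @export
pbm_herd <- function(steps, status, season, subset_size = NULL,
                     quantile_level = 0.999, cutoff = 0.8,
                     window_hours = 72, min_coverage = 0.5,
                     horizon_days = 28, bw = NULL, pool = NULL,
                     interval_hours = attr(steps, "nominal_interval")) {
  td <- tdam(steps, window_hours = window_hours,
             min_coverage = min_coverage, interval_hours = interval_hours)
  thr <- kfold_thresholds(td, status, subset_size = subset_size,
                          quantile_level = quantile_level, bw = bw,
                          window_hours = window_hours, pool = pool)
  ids <- unique(td$animal_id)
  per_set <- vector("list", nrow(thr) * length(ids))
  k <- 0
  for (s in seq_len(nrow(thr))) {
    refs <- thr$ref_ids[[s]]
    for (id in setdiff(ids, refs)) {
      k <- k + 1
      row <- classify_pbm(td[td$animal_id == id, , drop = FALSE],
                          thr$parturition_threshold[s],
                          thr$mortality_threshold[s], season,
                          horizon_days = horizon_days)
      row$set_id <- thr$set_id[s]
      per_set[[k]] <- row
    }
  }
  per_set <- do.call(rbind, per_set[seq_len(k)])
  list(predictions = pool_predictions(per_set, cutoff = cutoff),
       thresholds = thr, tdam = td)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
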