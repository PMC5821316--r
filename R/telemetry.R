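#' Read GPS fixes from a delimited text file
#'
#' Reads a CSV/TSV of GPS relocations into the fix table used throughout the
#' package: one row per fix with columns `animal_id`, `t` (POSIXct, UTC),
#' `x` and `y` (projected coordinates, metres).  Column names in the file
#' are mapped through `schema`.  Rows are grouped by animal and sorted by
#' time; duplicated (animal, timestamp) rows are collapsed to the first
#' occurrence with a warning.
#'
#' Coordinates must already be planar metres; projecting geographic
#' coordinates is the caller's job.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named list or character vector mapping the canonical names
#'   `animal_id`, `t`, `x`, `y` to the column names used in the file.
#' @param sep Field separator (default `","`).
#' @param tz Timezone used to parse timestamps (default `"UTC"`).
#'
#' @return A tibble with columns `animal_id` (character), `t` (POSIXct),
#'   `x`, `y` (double), sorted by animal then time.
#' @export
read_gps_fixes <- function(path,
                           schema = c(animal_id = "animal_id", t = "t",
                                      x = "x", y = "y"),
                           sep = ",", tz = "UTC") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  schema <- unlist(schema)
  needed <- c("animal_id", "t", "x", "y")
  if (!all(needed %in% names(schema))) {
    stop("schema must map all of: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  missing_cols <- setdiff(unname(schema[needed]), names(raw))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tt <- as.POSIXct(raw[[schema[["t"]]]], tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  bad <- which(is.na(tt) & !is.na(raw[[schema[["t"]]]]))
  if (length(bad) > 0) {
    stop("unparseable timestamp at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  fixes <- tibble::tibble(
    animal_id = as.character(raw[[schema[["animal_id"]]]]),
    t = tt,
    x = as.numeric(raw[[schema[["x"]]]]),
    y = as.numeric(raw[[schema[["y"]]]])
  )
  if (any(!is.finite(fixes$x)) || any(!is.finite(fixes$y))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  fixes <- fixes[order(fixes$animal_id, fixes$t), , drop = FALSE]
  dup <- duplicated(fixes[, c("animal_id", "t")])
  if (any(dup)) {
    warning(sum(dup), " duplicated (animal, timestamp) row(s) dropped",
            call. = FALSE)
    fixes <- fixes[!dup, , drop = FALSE]
  }
  fixes
}

#' Write a fix table back to CSV
#'
#' Companion to [read_gps_fixes()]; timestamps are written as ISO 8601 UTC.
#'
#' @param fixes Fix table (`animal_id`, `t`, `x`, `y`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gps_fixes <- function(fixes, path) {
  out <- data.frame(
    animal_id = fixes$animal_id,
    t = format(fixes$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    x = fixes$x,
    y = fixes$y
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Screen fixes for unrealistic movement
#'
#' Two-rule screen for erroneous relocations.  Rule 1 removes "spikes":
#' interior fixes whose inbound and outbound speeds both exceed
#' `spike_speed` and whose turning angle (change of heading) is at least
#' `spike_angle` degrees -- the out-and-back signature of a bad fix.
#' Rule 2 then removes any fix reached from its retained predecessor at a
#' speed above `max_speed`.  Animals with fewer than 3 fixes are passed
#' through unscreened with a warning.
#'
#' @param fixes Fix table (`animal_id`, `t`, `x`, `y`).
#' @param max_speed Hard speed ceiling, metres/hour.
#' @param spike_speed Speed both legs of a spike must exceed, metres/hour.
#' @param spike_angle Minimum turning angle of a spike, degrees (<= 180).
#'
#' @return A list with `fixes` (the retained rows, a subsequence of the
#'   input), `removed` (per-animal tibble of counts and fractions) and
#'   `removed_fraction` (global fraction removed).
#' @export
screen_fixes <- function(fixes, max_speed = 15000, spike_speed = 10000,
                         spike_angle = 166) {
  stopifnot(max_speed > 0, spike_speed > 0,
            spike_angle > 0, spike_angle <= 180)
  parts <- split(fixes, fixes$animal_id)
  kept <- vector("list", length(parts))
  report <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    f <- parts[[k]]
    n <- nrow(f)
    if (n < 3) {
      warning("animal ", names(parts)[k],
              " has < 3 fixes; passed through unscreened", call. = FALSE)
      kept[[k]] <- f
      report[[k]] <- tibble::tibble(animal_id = names(parts)[k],
                                    n_in = n, n_removed = 0L,
                                    fraction_removed = 0)
      next
    }
    drop <- .find_spikes(f, spike_speed, spike_angle)
    f2 <- f[!drop, , drop = FALSE]
    drop2 <- .find_speeders(f2, max_speed)
    out <- f2[!drop2, , drop = FALSE]
    n_rm <- n - nrow(out)
    kept[[k]] <- out
    report[[k]] <- tibble::tibble(animal_id = names(parts)[k],
                                  n_in = n, n_removed = n_rm,
                                  fraction_removed = n_rm / n)
  }
  removed <- do.call(rbind, report)
  list(fixes = do.call(rbind, kept),
       removed = removed,
       removed_fraction = sum(removed$n_removed) / sum(removed$n_in))
}

# spike = interior fix with both legs fast and a near-reversal of heading
.find_spikes <- function(f, spike_speed, spike_angle) {
  n <- nrow(f)
  dx <- diff(f$x); dy <- diff(f$y)
  dt <- as.numeric(difftime(f$t[-1], f$t[-n], units = "hours"))
  speed <- sqrt(dx^2 + dy^2) / dt
  # turning angle at fix i: angle between headings of legs (i-1,i) and (i,i+1)
  h <- atan2(dy, dx)
  turn <- abs(diff(h))
  turn <- pmin(turn, 2 * pi - turn) * 180 / pi
  drop <- rep(FALSE, n)
  drop[2:(n - 1)] <- speed[1:(n - 2)] > spike_speed &
    speed[2:(n - 1)] > spike_speed & turn >= spike_angle
  drop
}

# sequential scan: drop a fix if the speed from the last retained fix exceeds
# the ceiling
.find_speeders <- function(f, max_speed) {
  n <- nrow(f)
  drop <- rep(FALSE, n)
  if (n < 2) return(drop)
  last <- 1L
  for (i in 2:n) {
    dt <- as.numeric(difftime(f$t[i], f$t[last], units = "hours"))
    sp <- sqrt((f$x[i] - f$x[last])^2 + (f$y[i] - f$y[last])^2) / dt
    if (is.finite(sp) && sp > max_speed) {
      drop[i] <- TRUE
    } else {
      last <- i
    }
  }
  drop
}

#' Build step lengths from successive scheduled fixes
#'
#' Converts time-sorted fixes into movement steps.  A step is emitted only
#' when the time gap between consecutive fixes lies within
#' `interval_hours * (1 +/- tolerance)`: longer gaps (missed fixes) produce
#' no step, never a summed multi-interval step, so fix failures are not
#' bridged.
#'
#' @param fixes Fix table for one or more animals.
#' @param interval_hours Nominal fix interval, hours.
#' @param tolerance Allowed fractional jitter around the nominal interval
#'   (default 0.25).
#'
#' @return A tibble of steps: `animal_id`, `t_start`, `t_end`, `length`
#'   (metres), `duration_h` (hours), `rate` (metres/hour), with attribute
#'   `nominal_interval` (hours).  Animals with zero usable steps simply
#'   contribute no rows.
#' @export
build_steps <- function(fixes, interval_hours, tolerance = 0.25) {
  stopifnot(interval_hours > 0, tolerance >= 0)
  parts <- split(fixes, fixes$animal_id)
  out <- lapply(parts, function(f) {
    f <- f[order(f$t), , drop = FALSE]
    n <- nrow(f)
    if (n < 2) return(NULL)
    dt <- as.numeric(difftime(f$t[-1], f$t[-n], units = "hours"))
    ok <- dt >= interval_hours * (1 - tolerance) &
      dt <= interval_hours * (1 + tolerance)
    if (!any(ok)) return(NULL)
    i <- which(ok)
    len <- sqrt((f$x[i + 1] - f$x[i])^2 + (f$y[i + 1] - f$y[i])^2)
    tibble::tibble(animal_id = f$animal_id[i], t_start = f$t[i],
                   t_end = f$t[i + 1], length = len, duration_h = dt[i],
                   rate = len / dt[i])
  })
  steps <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(steps)) {
    steps <- tibble::tibble(animal_id = character(),
                            t_start = as.POSIXct(character(), tz = "UTC"),
                            t_end = as.POSIXct(character(), tz = "UTC"),
                            length = double(), duration_h = double(),
                            rate = double())
  }
  attr(steps, "nominal_interval") <- interval_hours
  steps
}

#' Remove the top fraction of step lengths per animal
#'
#' Rarefies each animal's steps by dropping those with length strictly
#' greater than the per-animal `1 - fraction` empirical quantile
#' (linear-interpolation definition, `stats::quantile` type 7).  These
#' extreme steps are typically associated with capture events or predator
#' avoidance rather than routine movement.
#'
#' @param steps Step tibble from [build_steps()].
#' @param fraction Fraction to remove from the top (default 0.01); must lie
#'   in (0, 0.5).
#'
#' @return The rarefied step tibble, with attribute `n_removed` and the
#'   input's `nominal_interval` attribute preserved.
#' @export
rarefy_top_steps <- function(steps, fraction = 0.01) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 0.5) {
    stop("fraction must lie in (0, 0.5)", call. = FALSE)
  }
  if (nrow(steps) == 0) stop("no steps to rarefy", call. = FALSE)
  keep <- unlist(lapply(split(seq_len(nrow(steps)), steps$animal_id),
                        function(i) {
    len <- steps$length[i]
    q <- quantile(len, probs = 1 - fraction, type = 7, names = FALSE)
    tol <- 1e-8 * max(q, 1)
    tied <- abs(len - q) <= tol
    drop <- len > q + tol
    # Ties at the cutoff (e.g. repeated near-identical excursions) would
    # otherwise shield each other: when the quantile lands on a tie group
    # that is itself extreme relative to the remaining steps, remove the
    # whole group.  A sample of all-equal lengths removes nothing.
    if (any(tied)) {
      rest <- len[len < q - tol]
      if (length(rest) > 0 &&
          q > quantile(rest, probs = 1 - fraction, type = 7, names = FALSE)) {
        drop <- drop | tied
      }
    }
    i[!drop]
  }), use.names = FALSE)
  out <- steps[sort(keep), , drop = FALSE]
  attr(out, "nominal_interval") <- attr(steps, "nominal_interval")
  attr(out, "n_removed") <- nrow(steps) - nrow(out)
  out
}

#' Per-collar fix success rate
#'
#' Fraction of scheduled fix attempts that produced a fix.  Offspring
#' survival inferred from collars with fix rates below 90% is known to be
#' unreliable, so a warning is attached below that level.
#'
#' @param fixes Fix table for a single animal.
#' @param schedule POSIXct vector of attempted fix times.
#' @return Fraction in \[0, 1\].
#' @export
fix_rate <- function(fixes, schedule) {
  if (length(schedule) == 0) stop("empty fix schedule", call. = FALSE)
  got <- sum(round(as.numeric(schedule)) %in% round(as.numeric(fixes$t)))
  rate <- got / length(schedule)
  if (rate < 0.90) {
    warning(sprintf("fix rate %.2f < 0.90: survival inference may be unreliable",
                    rate), call. = FALSE)
  }
  rate
}

#' Thin fixes to a coarser schedule
#'
#' Keeps every `factor`-th scheduled fix time, anchored at each animal's
#' first fix, e.g. `factor = 2` turns a 2-hour series into a 4-hour series.
#'
#' @param fixes Fix table.
#' @param factor Integer >= 2; the schedule-coarsening factor.
#' @param interval_hours Nominal fix interval of the input schedule, hours.
#' @return The thinned fix table.
#' @export
thin_to_interval <- function(fixes, factor, interval_hours) {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 2 ||
      factor != round(factor)) {
    stop("factor must be an integer >= 2", call. = FALSE)
  }
  parts <- split(fixes, fixes$animal_id)
  out <- lapply(parts, function(f) {
    f <- f[order(f$t), , drop = FALSE]
    slot <- round(as.numeric(difftime(f$t, f$t[1], units = "hours")) /
                    interval_hours)
    f[slot %% factor == 0, , drop = FALSE]
  })
  do.call(rbind, out)
}
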