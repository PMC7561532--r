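# Implied speed (km/h) between consecutive observed fixes of one animal.
consecutive_speeds <- function(time, x, y) {
  dt_h <- as.numeric(diff(time), units = "hours")
  dist_km <- sqrt(diff(x)^2 + diff(y)^2) / 1000
  dist_km / pmax(dt_h, 1e-9)
}

#' Screen fixes for impossible and improbable movement speeds
#'
#' Iteratively removes fixes that imply impossible movement speeds
#' (> `remove_threshold` to or from a neighbor): while any consecutive
#' implied speed exceeds the threshold, the fix with the largest summed
#' implied speed to its neighbors is dropped and speeds recomputed.
#' Fixes implying speeds in (`flag_threshold`, `remove_threshold`] are
#' retained but flagged for review in a `speed_flag` column (an
#' automated, reproducible proxy for manual inspection of improbable
#' movements).
#'
#' @param fixes fix data.frame (`id, time, x, y, ...`), one or more animals.
#' @param flag_threshold review-flag speed (km/h), default 10.
#' @param remove_threshold removal speed (km/h), default 50.
#' @return list with `fixes` (retained, with `speed_flag`) and `removed`
#'   (dropped rows). Animals with a single fix are passed through with a
#'   warning.
#' @export
filter_speed <- function(fixes, flag_threshold = 10, remove_threshold = 50) {
  fixes <- fixes[order(fixes$id, fixes$time), , drop = FALSE]
  removed <- fixes[0, , drop = FALSE]
  out <- list()
  for (animal in unique(fixes$id)) {
    f <- fixes[fixes$id == animal, , drop = FALSE]
    obs <- f[!(f$missing %||% FALSE) & !is.na(f$x), , drop = FALSE]
    if (nrow(obs) < 2) {
      warning("animal ", animal, " has fewer than 2 observed fixes; ",
              "speed screening skipped")
      f$speed_flag <- FALSE
      out[[animal]] <- f
      next
    }
    repeat {
      v <- consecutive_speeds(obs$time, obs$x, obs$y)
      if (!any(v > remove_threshold)) break
      # score each fix by the sum of its adjacent implied speeds: the
      # erroneous fix is implicated on both sides, its neighbors on one
      score <- c(0, v) + c(v, 0)
      drop_i <- which.max(score)
      removed <- rbind(removed, obs[drop_i, intersect(names(obs), names(removed)),
                                    drop = FALSE])
      obs <- obs[-drop_i, , drop = FALSE]
      if (nrow(obs) < 2) break
    }
    v <- if (nrow(obs) >= 2) consecutive_speeds(obs$time, obs$x, obs$y) else numeric()
    flag <- pmax(c(0, v), c(v, 0)) > flag_threshold
    obs$speed_flag <- flag
    keep_missing <- f[(f$missing %||% FALSE) | is.na(f$x), , drop = FALSE]
    if (nrow(keep_missing)) {
      keep_missing$speed_flag <- FALSE
      obs <- rbind(obs, keep_missing)
      obs <- obs[order(obs$time), , drop = FALSE]
    }
    out[[animal]] <- obs
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  rownames(removed) <- NULL
  list(fixes = res, removed = removed)
}

#' Rarefy a fix series to a target interval
#'
#' Greedy forward selection from the first fix of each animal: the next
#' fix whose gap from the last retained fix rounds (at the given grain)
#' to the target interval is retained. When a gap passes the target
#' without a match (a hole in the data), the first fix beyond the window
#' restarts the sequence, so data after holes are preserved and the hole
#' shows up as a long gap.
#'
#' @param fixes fix data.frame.
#' @param target_interval_h target interval in hours (e.g. 2 or 7).
#' @param rounding_grain_min rounding grain in minutes (default 15).
#' @return the rarefied fix data.frame.
#' @export
rarefy <- function(fixes, target_interval_h, rounding_grain_min = 15) {
  # unobserved placeholder rows (NA coordinates) are not anchors
  fixes <- fixes[!is.na(fixes$x) & !is.na(fixes$y), , drop = FALSE]
  if (nrow(fixes) == 0) return(fixes)
  tol_h <- rounding_grain_min / 60 / 2
  keep_all <- logical(nrow(fixes))
  for (animal in unique(fixes$id)) {
    idx <- which(fixes$id == animal)
    f <- fixes[idx, , drop = FALSE]
    o <- order(f$time)
    idx <- idx[o]; f <- f[o, , drop = FALSE]
    keep <- logical(nrow(f))
    keep[1] <- TRUE
    last <- 1
    i <- 2
    while (i <= nrow(f)) {
      gap <- as.numeric(difftime(f$time[i], f$time[last], units = "hours"))
      if (abs(gap - target_interval_h) <= tol_h) {
        keep[i] <- TRUE; last <- i; i <- i + 1
      } else if (gap > target_interval_h + tol_h) {
        keep[i] <- TRUE; last <- i; i <- i + 1  # hole: restart the chain
      } else {
        i <- i + 1  # too soon: thin it out
      }
    }
    keep_all[idx] <- keep
  }
  fixes[keep_all, , drop = FALSE]
}

#' Extract regular analysis bursts from rarefied fixes
#'
#' Assigns each fix of each animal to a nominal slot on a regular
#' `interval_h` grid (slot increments are rounded gap multiples), splits
#' the series wherever more than `max_missing` consecutive slots are
#' empty, and keeps segments spanning at least `min_days` days. Empty
#' slots within a kept segment are materialized as missing rows so the
#' burst is a complete regular series with a missingness annotation.
#'
#' @param fixes fix data.frame, nominally at `interval_h` spacing.
#' @param interval_h nominal slot interval (hours), default 2.
#' @param min_days minimum burst span in days, default 8.
#' @param max_missing maximum tolerated run of missing slots, default 4.
#' @return list of `burst` objects: data.frames with columns
#'   `slot, time, x, y, observed, source` and attributes `id`,
#'   `interval_h`.
#' @export
extract_bursts <- function(fixes, interval_h = 2, min_days = 8,
                           max_missing = 4) {
  bursts <- list()
  for (animal in unique(fixes$id)) {
    f <- fixes[fixes$id == animal, , drop = FALSE]
    f <- f[order(f$time), , drop = FALSE]
    obs <- f[!(f$missing %||% FALSE) & !is.na(f$x), , drop = FALSE]
    if (nrow(obs) == 0) next
    gaps <- as.numeric(diff(obs$time), units = "hours")
    inc <- pmax(1, round(gaps / interval_h))
    slot <- cumsum(c(0, inc))
    seg_break <- c(FALSE, (inc - 1) > max_missing)
    seg_id <- cumsum(seg_break)
    for (s in unique(seg_id)) {
      sel <- seg_id == s
      ss <- slot[sel] - slot[sel][1]
      span_days <- ss[length(ss)] * interval_h / 24
      if (span_days < min_days) next
      n_slots <- ss[length(ss)] + 1
      t0 <- obs$time[sel][1]
      b <- data.frame(
        slot = 0:(n_slots - 1),
        time = t0 + (0:(n_slots - 1)) * interval_h * 3600,
        x = NA_real_, y = NA_real_,
        observed = FALSE, source = "missing",
        stringsAsFactors = FALSE)
      b$x[ss + 1] <- obs$x[sel]
      b$y[ss + 1] <- obs$y[sel]
      b$time[ss + 1] <- obs$time[sel]
      b$observed[ss + 1] <- TRUE
      b$source[ss + 1] <- "observed"
      attr(b, "id") <- animal
      attr(b, "interval_h") <- interval_h
      class(b) <- c("burst", "data.frame")
      bursts[[length(bursts) + 1]] <- b
    }
  }
  bursts
}

#' Step series of a burst
#'
#' Computes the bivariate step series (lengths and turning angles) of a
#' regular burst. Bearings use the mathematical convention
#' (counterclockwise from east, `atan2(dy, dx)`), so a left turn is a
#' positive turning angle; turning angles are successive bearing differences
#' wrapped to `(-pi, pi]`. A step is `NA`-length if either endpoint slot
#' is missing; turning angles are undefined for the first step, after an
#' undefined or zero-length step (the bearing does not exist), and
#' around missing slots. Steps touching imputed fixes carry an
#' `imputed` flag.
#'
#' @param burst a `burst` from [extract_bursts()] (possibly imputed by
#'   [impute_missing()]).
#' @return data.frame with columns `slot, time, x0, y0, x1, y1, length,
#'   bearing, turn, imputed`.
#' @export
steps_from_burst <- function(burst) {
  n <- nrow(burst)
  if (n < 2) {
    return(data.frame(slot = integer(), time = burst$time[0],
                      x0 = numeric(), y0 = numeric(), x1 = numeric(),
                      y1 = numeric(), length = numeric(), bearing = numeric(),
                      turn = numeric(), imputed = logical()))
  }
  i0 <- 1:(n - 1); i1 <- 2:n
  dx <- burst$x[i1] - burst$x[i0]
  dy <- burst$y[i1] - burst$y[i0]
  len <- sqrt(dx^2 + dy^2)
  bearing <- ifelse(!is.na(len) & len > 0, atan2(dy, dx), NA_real_)
  turn <- wrap_angle(bearing - c(NA_real_, bearing[-length(bearing)]))
  src <- burst$source
  data.frame(
    slot = burst$slot[i0],
    time = burst$time[i0],
    x0 = burst$x[i0], y0 = burst$y[i0],
    x1 = burst$x[i1], y1 = burst$y[i1],
    length = len, bearing = bearing, turn = turn,
    imputed = (src[i0] == "imputed") | (src[i1] == "imputed"),
    stringsAsFactors = FALSE)
}

#' Net squared displacement
#'
#' Squared Euclidean distance of each fix from the animal's first fix;
#' used to screen residency versus transience.
#'
#' @param fixes fix data.frame for one animal, time-ordered.
#' @return data.frame with columns `time` and `nsd` (square meters).
#' @export
net_squared_displacement <- function(fixes) {
  if (nrow(fixes) == 0) stop("need at least one fix", call. = FALSE)
  f <- fixes[order(fixes$time), , drop = FALSE]
  data.frame(time = f$time,
             nsd = (f$x - f$x[1])^2 + (f$y - f$y[1])^2)
}
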