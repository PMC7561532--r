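round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

#' Behavior proportions from location counts
#'
#' `p_b = n_b / sum(n)` within one temporal period, reported at full
#' precision and rounded (half-up) to 2 decimals for display.
#'
#' @param counts named or unnamed vector of per-behavior location counts.
#' @return data.frame `behavior, n, proportion, proportion_2dp`.
#' @export
proportions_from_counts <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  behaviors <- names(counts) %||% paste0("behavior", seq_along(counts))
  p <- as.numeric(counts) / sum(counts)
  data.frame(behavior = behaviors, n = as.integer(counts),
             proportion = p, proportion_2dp = round_half_up(p, 2),
             row.names = NULL)
}

#' Hours per day spent in a behavior
#'
#' Proportion of a light period's locations times the mean daily
#' duration of that period.
#'
#' @param proportion behavior proportion(s) within the period.
#' @param period_hours mean duration of the light period (h/day).
#' @return hours per day.
#' @export
hours_per_day <- function(proportion, period_hours) proportion * period_hours

#' Seasonal behavior proportions pooled over light periods
#'
#' Pools counts across the light periods within a season before
#' normalizing, giving the per-behavior share of the whole season.
#'
#' @param counts matrix or data.frame of counts with light periods in
#'   rows and behaviors in columns.
#' @return named vector of per-behavior seasonal proportions.
#' @export
season_totals <- function(counts) {
  m <- as.matrix(counts)
  tot <- colSums(m)
  tot / sum(tot)
}

#' Behavior time budget by season and light condition
#'
#' The machine twin of a behavior time-budget table: per
#' (season, light) cell the per-behavior location counts, proportions
#' (full precision and 2 dp), and estimated hours per day, using the
#' season-specific mean daily duration of each light period.
#'
#' @param records data.frame with columns `time, season, light,
#'   behavior` (one row per decoded location/step).
#' @param lat,lon study reference coordinates for solar durations.
#' @return data.frame `season, light, behavior, n, proportion,
#'   proportion_2dp, hours_per_day`.
#' @export
time_budget <- function(records, lat = 46.7, lon = -60.6) {
  r <- records[!is.na(records$season) & !is.na(records$light) &
                 !is.na(records$behavior), , drop = FALSE]
  out <- list()
  for (se in unique(r$season)) {
    rs <- r[r$season == se, , drop = FALSE]
    dates <- unique(as.Date(rs$time, tz = "UTC"))
    dur <- light_period_durations(dates, lat, lon)
    mean_dur <- c(diurnal = mean(dur$diurnal),
                  crepuscular = mean(dur$crepuscular),
                  nocturnal = mean(dur$nocturnal))
    for (li in intersect(c("diurnal", "crepuscular", "nocturnal"),
                         unique(rs$light))) {
      rl <- rs[rs$light == li, , drop = FALSE]
      counts <- table(factor(rl$behavior))
      pr <- proportions_from_counts(as.vector(counts))
      pr$behavior <- names(counts)
      out[[length(out) + 1]] <- data.frame(
        season = se, light = li, pr[, c("behavior", "n", "proportion",
                                        "proportion_2dp")],
        hours_per_day = hours_per_day(pr$proportion, mean_dur[[li]]),
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}
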