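#' Default snow-season calendar windows
#'
#' Snow cover windows by elevation regime: December 10 to April 15 below
#' the plateau threshold and November 20 to May 1 at or above it;
#' windows are inclusive and wrap the year end.
#'
#' @return list with `low`, `high` (each `c(start, end)` as `"mm-dd"`)
#'   and `elev` (threshold in m).
#' @export
season_thresholds <- function() {
  list(low = c("12-10", "04-15"), high = c("11-20", "05-01"), elev = 300)
}

mmdd <- function(time) as.integer(format(time, "%m")) * 100L +
  as.integer(format(time, "%d"))

in_window <- function(md, start, end) {
  s <- as.integer(sub("-", "", start)); e <- as.integer(sub("-", "", end))
  if (s <= e) md >= s & md <= e else md >= s | md <= e
}

#' Climatic season of a fix
#'
#' Snow season iff the date falls in the calendar window for the fix's
#' elevation regime (low: below the elevation threshold; high: at or
#' above it); snow-free otherwise.
#'
#' @param time POSIXct fix time(s) (UTC).
#' @param elevation_m elevation (m) at the fix location(s); `NA` is an
#'   error naming the fix.
#' @param thresholds window definition, see [season_thresholds()].
#' @return character vector, `"snow"` or `"snow_free"`.
#' @export
season <- function(time, elevation_m, thresholds = season_thresholds()) {
  if (any(is.na(elevation_m))) {
    i <- which(is.na(elevation_m))[1]
    stop(sprintf("missing DEM elevation for fix %d (%s)", i,
                 format(time[i])), call. = FALSE)
  }
  md <- mmdd(time)
  high <- elevation_m >= thresholds$elev
  snow <- ifelse(high,
                 in_window(md, thresholds$high[1], thresholds$high[2]),
                 in_window(md, thresholds$low[1], thresholds$low[2]))
  ifelse(snow, "snow", "snow_free")
}

#' Sunrise and sunset (UTC) for a date and location
#'
#' NOAA solar-position equations (Meeus-based, as in the NOAA solar
#' calculator): Julian-century solar geometry, equation of time, solar
#' declination, and the hour angle for the standard -0.833 degree solar
#' altitude (refraction plus solar radius).
#'
#' @param lat,lon latitude/longitude in decimal degrees (east positive);
#'   `|lat|` must be below the polar circle.
#' @param date a `Date` (or POSIXct, whose UTC date is used).
#' @return list with POSIXct UTC `sunrise` and `sunset`. Sunset may fall
#'   on the next UTC calendar day at western longitudes.
#' @export
solar_events <- function(lat, lon, date) {
  if (abs(lat) >= 66.5) {
    stop("unsupported latitude: polar day/night not handled", call. = FALSE)
  }
  date <- as.Date(date)
  jd <- as.numeric(date) + 2440587.5 + 0.5  # Julian day at 12:00 UTC
  jc <- (jd - 2451545) / 36525

  gmls <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  seqc <- sin(gmas * pi / 180) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmas * pi / 180) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmas * pi / 180) * 0.000289
  stl <- gmls + seqc
  sal <- stl - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * pi / 180)
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos((125.04 - 1934.136 * jc) * pi / 180)
  decl <- asin(sin(oc * pi / 180) * sin(sal * pi / 180)) * 180 / pi
  vary <- tan(oc / 2 * pi / 180)^2
  eqtime <- 4 * (vary * sin(2 * gmls * pi / 180) -
    2 * eeo * sin(gmas * pi / 180) +
    4 * eeo * vary * sin(gmas * pi / 180) * cos(2 * gmls * pi / 180) -
    0.5 * vary^2 * sin(4 * gmls * pi / 180) -
    1.25 * eeo^2 * sin(2 * gmas * pi / 180)) * 180 / pi

  cos_ha <- cos(90.833 * pi / 180) / (cos(lat * pi / 180) * cos(decl * pi / 180)) -
    tan(lat * pi / 180) * tan(decl * pi / 180)
  if (cos_ha < -1 || cos_ha > 1) {
    stop("sun does not rise/set on this date at this latitude", call. = FALSE)
  }
  ha <- acos(cos_ha) * 180 / pi

  noon_min <- 720 - 4 * lon - eqtime          # minutes after UTC midnight
  rise_min <- noon_min - 4 * ha
  set_min <- noon_min + 4 * ha
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  list(sunrise = midnight + rise_min * 60, sunset = midnight + set_min * 60)
}

#' Light condition at given instants
#'
#' Classifies times into diurnal / crepuscular / nocturnal using the
#' two-hour rule: crepuscular is the closed window within 2 h of sunrise
#' or sunset; diurnal is from 2 h after sunrise to 2 h before sunset;
#' nocturnal is from 2 h after sunset to 2 h before sunrise. Solar
#' events are evaluated for the day before, of, and after each time so
#' the classification is correct across UTC midnights.
#'
#' @param time POSIXct time(s), UTC.
#' @param lat,lon location in decimal degrees.
#' @param window_h half-width of the crepuscular window (hours).
#' @return character vector: `"diurnal"`, `"crepuscular"`, `"nocturnal"`.
#' @export
light_condition <- function(time, lat, lon, window_h = 2) {
  dates <- sort(unique(as.Date(time, tz = "UTC") + rep(c(-1, 0, 1),
                                                       each = length(time))))
  ev <- lapply(dates, function(d) solar_events(lat, lon, d))
  rises <- as.numeric(do.call(c, lapply(ev, `[[`, "sunrise")))
  sets <- as.numeric(do.call(c, lapply(ev, `[[`, "sunset")))
  w <- window_h * 3600
  tt <- as.numeric(time)
  out <- character(length(tt))
  for (i in seq_along(tt)) {
    near_event <- min(abs(tt[i] - rises), abs(tt[i] - sets))
    if (near_event <= w) {
      out[i] <- "crepuscular"
    } else {
      # daytime iff between the latest sunrise before t and the first
      # sunset after that sunrise
      last_rise <- suppressWarnings(max(rises[rises <= tt[i]]))
      next_set <- suppressWarnings(min(sets[sets >= last_rise]))
      out[i] <- if (is.finite(last_rise) && is.finite(next_set) &&
                    tt[i] < next_set) "diurnal" else "nocturnal"
    }
  }
  out
}

#' Mean daily durations of the three light periods
#'
#' For each date, daylight `D` is sunset minus sunrise; the diurnal
#' period lasts `max(D - 2*window, 0)` hours, the nocturnal period
#' `max(24 - D - 2*window, 0)` and the crepuscular period the remainder
#' (8 h unless a period would be negative-length, in which case the
#' clamping is flagged with a warning).
#'
#' @param dates vector of `Date`s.
#' @param lat,lon location in decimal degrees.
#' @param window_h half-width of the crepuscular window (hours).
#' @return data.frame with columns `date, diurnal, crepuscular,
#'   nocturnal` (hours); the three columns sum to 24.
#' @export
light_period_durations <- function(dates, lat, lon, window_h = 2) {
  dates <- as.Date(dates)
  rows <- lapply(dates, function(d) {
    ev <- solar_events(lat, lon, d)
    D <- as.numeric(difftime(ev$sunset, ev$sunrise, units = "hours"))
    day <- max(D - 2 * window_h, 0)
    night <- max(24 - D - 2 * window_h, 0)
    crep <- 24 - day - night
    if (day == 0 || night == 0) {
      warning("degenerate light period on ", format(d),
              ": day length ", round(D, 2), " h; period clamped to zero")
    }
    data.frame(date = d, diurnal = day, crepuscular = crep, nocturnal = night)
  })
  do.call(rbind, rows)
}

#' Assign season and light condition to fixes
#'
#' Samples elevation at each fix from the DEM, applies the seasonal
#' calendar/elevation rule and the solar light rule at the study
#' reference coordinates, and appends `season` and `light` columns.
#'
#' @param fixes fix data.frame (`id, time, x, y`).
#' @param stack a `landscape_stack` (for the DEM).
#' @param ref_latlon study reference `c(lat, lon)` in decimal degrees
#'   used for solar position (tracks are in projected meters; across a
#'   study-area-sized window the solar-event error is under a minute).
#' @param thresholds see [season_thresholds()].
#' @return `fixes` with `season` and `light` columns.
#' @export
assign_temporal <- function(fixes, stack, ref_latlon = c(46.7, -60.6),
                            thresholds = season_thresholds()) {
  ok <- !is.na(fixes$x)
  elev <- rep(NA_real_, nrow(fixes))
  # points marginally outside the DEM (e.g. smoother draws near the
  # boundary) sample the nearest edge cell
  e <- raster_extent(stack$dem)
  xs <- pmin(pmax(fixes$x[ok], e["xmin"]), e["xmax"])
  ys <- pmin(pmax(fixes$y[ok], e["ymin"]), e["ymax"])
  elev[ok] <- raster_extract(stack$dem, xs, ys)
  fixes$season <- NA_character_
  fixes$season[ok] <- season(fixes$time[ok], elev[ok], thresholds)
  fixes$light <- light_condition(fixes$time, ref_latlon[1], ref_latlon[2])
  fixes
}
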