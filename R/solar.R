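#' Construct a solar day record
#'
#' Low-level constructor for one or more solar days: a date and location with
#' sunrise and sunset expressed in local decimal hours. \code{\link{sun_times}}
#' builds these from the solar-position equations; this constructor also lets
#' callers supply sunrise/sunset directly (e.g. from an almanac).
#'
#' @param date \code{Date} (or coercible).
#' @param latitude,longitude decimal degrees.
#' @param utc_offset hours ahead of UTC of the local civil clock.
#' @param sunrise,sunset local decimal hours in \eqn{[0, 24)}.
#' @return a data.frame of class \code{"solar_day"} with columns \code{date},
#'   \code{latitude}, \code{longitude}, \code{utc_offset}, \code{sunrise},
#'   \code{sunset}.
#' @export
solar_day <- function(date, latitude, longitude, utc_offset, sunrise, sunset) {
  date <- as.Date(date)
  stopifnot(all(latitude >= -90 & latitude <= 90),
            all(longitude >= -180 & longitude <= 180),
            all(sunrise >= 0 & sunrise < 24),
            all(sunset >= 0 & sunset < 24),
            all(sunrise < sunset))
  out <- data.frame(date = date, latitude = latitude, longitude = longitude,
                    utc_offset = utc_offset, sunrise = sunrise, sunset = sunset)
  class(out) <- c("solar_day", "data.frame")
  out
}

#' @export
print.solar_day <- function(x, ...) {
  cat("<solar_day> ", nrow(x), " day(s)\n", sep = "")
  df <- as.data.frame(x)
  df$sunrise <- format_hm(df$sunrise)
  df$sunset <- format_hm(df$sunset)
  print(df, ...)
  invisible(x)
}

format_hm <- function(h) {
  h <- h %% 24
  sprintf("%02d:%02d", floor(h), round((h - floor(h)) * 60) %% 60)
}

# Equation of time (minutes) and solar declination (radians) at a Julian
# century t, per the NOAA general solar-position equations.
solar_params <- function(t) {
  deg2rad <- pi / 180
  l0 <- (280.46646 + t * (36000.76983 + t * 0.0003032)) %% 360
  m  <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ec <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  mr <- m * deg2rad
  ctr <- sin(mr) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * mr) * (0.019993 - 0.000101 * t) +
    sin(3 * mr) * 0.000289
  true_long <- l0 + ctr
  omega <- (125.04 - 1934.136 * t) * deg2rad
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega)
  e0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  obliq <- (e0 + 0.00256 * cos(omega)) * deg2rad
  decl <- asin(sin(obliq) * sin(app_long * deg2rad))
  y <- tan(obliq / 2)^2
  l0r <- l0 * deg2rad
  eqtime <- 4 / deg2rad *
    (y * sin(2 * l0r) - 2 * ec * sin(mr) + 4 * ec * y * sin(mr) * cos(2 * l0r) -
       0.5 * y^2 * sin(4 * l0r) - 1.25 * ec^2 * sin(2 * mr))
  list(eqtime = eqtime, decl = decl)
}

# Julian century for a UTC instant given as Date + minutes past 00:00 UTC.
julian_century <- function(date, utc_minutes) {
  jd <- as.numeric(as.Date(date)) + 2440587.5 + utc_minutes / 1440
  (jd - 2451545) / 36525
}

#' Sunrise and sunset from the NOAA solar-position equations
#'
#' Computes local sunrise and sunset (solar zenith 90.833 degrees, i.e.
#' including standard refraction and the solar disc radius) for mid-latitude
#' locations. Accuracy is within about 2 minutes of the NOAA reference
#' calculation, far below the 1-h resolution of the downstream analysis.
#'
#' @param date vector of dates (\code{Date} or coercible).
#' @param latitude,longitude decimal degrees; \code{abs(latitude)} must be
#'   below 66.5 (polar day/night is not handled).
#' @param utc_offset hours ahead of UTC of the local civil clock (the analysis
#'   treats camera timestamps as fixed-offset local civil time).
#' @return a \code{\link{solar_day}} data.frame, one row per input date.
#' @examples
#' sun_times(as.Date("2015-06-21"), 54.6, -5.9, 0)
#' @export
sun_times <- function(date, latitude, longitude, utc_offset = 0) {
  date <- as.Date(date)
  n <- max(length(date), length(latitude), length(longitude), length(utc_offset))
  date <- rep_len(date, n); latitude <- rep_len(latitude, n)
  longitude <- rep_len(longitude, n); utc_offset <- rep_len(utc_offset, n)
  if (any(abs(latitude) >= 66.5))
    stop("polar latitudes (|latitude| >= 66.5) are not supported")
  stopifnot(all(abs(longitude) <= 180))
  deg2rad <- pi / 180
  zen <- 90.833 * deg2rad
  event_minutes <- function(utc_guess, which) {
    # one refinement pass: re-evaluate declination/eqtime at the event time
    p <- solar_params(julian_century(date, utc_guess))
    cos_ha <- cos(zen) / (cos(latitude * deg2rad) * cos(p$decl)) -
      tan(latitude * deg2rad) * tan(p$decl)
    if (any(abs(cos_ha) > 1))
      stop("sun does not rise or set on the given date/latitude")
    ha <- acos(cos_ha) / deg2rad
    noon <- 720 - 4 * longitude - p$eqtime
    if (which == "rise") noon - 4 * ha else noon + 4 * ha
  }
  rise <- event_minutes(rep(720, n), "rise")
  rise <- event_minutes(rise, "rise")
  set <- event_minutes(rep(720, n), "set")
  set <- event_minutes(set, "set")
  solar_day(date, latitude, longitude, utc_offset,
            sunrise = (rise / 60 + utc_offset) %% 24,
            sunset = (set / 60 + utc_offset) %% 24)
}

# Decimal hour of day from a timestamp (POSIXct clock fields) or numeric hours.
clock_hours <- function(timestamp) {
  if (inherits(timestamp, "POSIXct") || inherits(timestamp, "POSIXlt")) {
    lt <- as.POSIXlt(timestamp)
    lt$hour + lt$min / 60 + lt$sec / 3600
  } else {
    as.numeric(timestamp)
  }
}

check_dates_match <- function(timestamp, sd) {
  if (inherits(timestamp, "POSIXct") || inherits(timestamp, "POSIXlt")) {
    d <- as.Date(as.POSIXlt(timestamp))
    if (!all(d == rep_len(sd$date, length(d))))
      stop("timestamp date does not match solar_day date")
  }
  invisible(NULL)
}

#' Signed offset of a detection from its solar anchor
#'
#' Detections with clock time in [00:00, 12:00) are offset relative to
#' sunrise; detections in [12:00, 24:00) relative to sunset. The magnitude is
#' the time from the anchor; the sign is positive for daylight detections
#' (between sunrise and sunset) and negative otherwise. E.g. a detection at
#' 22:10 with sunset at 20:00 has offset -2 h 10 min (nocturnal activity).
#'
#' @param timestamp POSIXct vector (local civil time; date must match
#'   \code{solar_day}) or numeric decimal hours.
#' @param solar_day a \code{\link{solar_day}} (1 row, or one row per
#'   timestamp).
#' @return data.frame with columns \code{value} (signed decimal hours, minute
#'   precision preserved) and \code{anchor} (\code{"sunrise"} or
#'   \code{"sunset"}).
#' @export
offset_from_sun <- function(timestamp, solar_day) {
  check_dates_match(timestamp, solar_day)
  h <- clock_hours(timestamp)
  n <- length(h)
  sr <- rep_len(solar_day$sunrise, n)
  ss <- rep_len(solar_day$sunset, n)
  anchor <- ifelse(h < 12, "sunrise", "sunset")
  # t - sunrise (morning) / sunset - t (afternoon): positive iff in daylight
  value <- ifelse(h < 12, h - sr, ss - h)
  data.frame(value = value, anchor = anchor)
}

#' Diel period of a detection
#'
#' Partitions the 24-h circle into dawn \eqn{[sunrise-1, sunrise+1)}, day
#' \eqn{[sunrise+1, sunset-1)}, dusk \eqn{[sunset-1, sunset+1)} and night
#' \eqn{[sunset+1, sunrise-1)} (wrapping midnight). Intervals are half-open
#' (closed at the start) so the four periods tile the circle exactly.
#'
#' @inheritParams offset_from_sun
#' @return factor with levels \code{dawn, day, dusk, night}.
#' @export
diel_period <- function(timestamp, solar_day) {
  check_dates_match(timestamp, solar_day)
  h <- clock_hours(timestamp) %% 24
  n <- length(h)
  sr <- rep_len(solar_day$sunrise, n)
  ss <- rep_len(solar_day$sunset, n)
  in_arc <- function(x, from, to) {
    # membership in the half-open clockwise arc [from, to) on the 24-h circle
    ((x - from) %% 24) < ((to - from) %% 24)
  }
  out <- rep("night", n)
  out[in_arc(h, sr - 1, sr + 1)] <- "dawn"
  out[in_arc(h, sr + 1, ss - 1)] <- "day"
  out[in_arc(h, ss - 1, ss + 1)] <- "dusk"
  factor(out, levels = c("dawn", "day", "dusk", "night"))
}

#' Durations of the four diel periods
#'
#' @param solar_day a \code{\link{solar_day}}.
#' @return data.frame with columns \code{dawn}, \code{day}, \code{dusk},
#'   \code{night} (hours; rows sum to 24).
#' @export
diel_durations <- function(solar_day) {
  daylen <- solar_day$sunset - solar_day$sunrise
  data.frame(dawn = 2, day = daylen - 2, dusk = 2, night = 24 - daylen - 2)
}

#' Meteorological season of a date
#'
#' Spring is March--May, summer June--August, autumn September--November and
#' winter December--February.
#'
#' @param date vector of dates (\code{Date} or coercible).
#' @return factor with levels \code{spring, summer, autumn, winter}.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
  factor(s, levels = c("spring", "summer", "autumn", "winter"))
}
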