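#' Annotate detections with solar context
#'
#' Joins detections to the site table, computes sunrise/sunset for each
#' (date, site), and adds the derived columns used throughout the analysis:
#' the signed sunrise/sunset offset, its anchor, the diel period and the
#' season.
#'
#' @param records detection data.frame.
#' @param sites site table (see \code{\link{read_sites}}).
#' @return the records with added columns \code{sunrise}, \code{sunset}
#'   (decimal hours), \code{offset} (signed decimal hours), \code{anchor},
#'   \code{period}, \code{season}.
#' @export
annotate_solar <- function(records, sites) {
  miss <- setdiff(unique(records$site_id), sites$site_id)
  if (length(miss)) stop("sites missing from site table: ",
                         paste(miss, collapse = ", "))
  i <- match(records$site_id, sites$site_id)
  date <- as.Date(as.POSIXlt(records$timestamp))
  key <- paste(records$site_id, date)
  uk <- !duplicated(key)
  sd <- sun_times(date[uk], sites$latitude[i][uk], sites$longitude[i][uk],
                  sites$utc_offset[i][uk])
  j <- match(key, key[uk])
  records$sunrise <- sd$sunrise[j]
  records$sunset <- sd$sunset[j]
  sday <- solar_day(date, sites$latitude[i], sites$longitude[i],
                    sites$utc_offset[i], records$sunrise, records$sunset)
  off <- offset_from_sun(records$timestamp, sday)
  records$offset <- off$value
  records$anchor <- off$anchor
  records$period <- diel_period(records$timestamp, sday)
  records$season <- season_of(date)
  records
}

#' Hourly diel activity profile
#'
#' Bins independent detections of one species into 24 one-hour intervals
#' beginning at the hour mark (e.g. 11:00--11:59), optionally restricted to
#' one season, and attaches the min--max normalised frequencies and the
#' detection clock times mapped to radians.
#'
#' @param events detection data.frame (independence-filtered); a
#'   \code{season} column is required when \code{season != "all"}.
#' @param species species label to profile; \code{NULL} uses all rows.
#' @param season one of \code{"all"}, \code{"spring"}, \code{"summer"},
#'   \code{"autumn"}, \code{"winter"}.
#' @return an \code{activity_profile}: list with \code{species},
#'   \code{season}, \code{counts} (24 integers, bin i = [i-1, i) h),
#'   \code{z} (normalised), \code{n_events} and \code{times_radians}.
#' @export
bin_hourly <- function(events, species = NULL, season = "all") {
  if (!is.null(species)) events <- events[events$species == species, , drop = FALSE]
  if (season != "all") {
    if (is.null(events$season)) stop("no season column; run annotate_solar() first")
    events <- events[events$season == season, , drop = FALSE]
  }
  h <- clock_hours(events$timestamp)
  if (length(h) == 0) warning("no events for ", species %||% "input",
                              " in season ", season)
  counts <- tabulate(floor(h %% 24) + 1L, nbins = 24L)
  structure(list(species = species %||% "all", season = season,
                 counts = counts, z = normalise_counts(counts),
                 n_events = length(h), times_radians = hours_to_radians(h)),
            class = "activity_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.activity_profile <- function(x, ...) {
  cat("<activity_profile> ", x$species, " / ", x$season, ": ", x$n_events,
      " events\n", sep = "")
  print(stats::setNames(x$counts, sprintf("%02d", 0:23)))
  invisible(x)
}

#' Min--max normalise hourly detection frequencies
#'
#' \eqn{z_i = (x_i - x_{min}) / (x_max - x_min)}. A constant profile (no
#' range) maps to all zeros by convention.
#'
#' @param counts numeric vector of 24 hourly counts.
#' @return numeric vector of 24 values in \eqn{[0, 1]}.
#' @export
normalise_counts <- function(counts) {
  stopifnot(length(counts) == 24)
  rng <- max(counts) - min(counts)
  if (rng == 0) return(rep(0, 24))
  (counts - min(counts)) / rng
}

#' Fit a circular (von Mises) kernel density to detection times
#'
#' Kernel density on the 24-h circle with a von Mises kernel whose
#' concentration is chosen by the von Mises plug-in rule (the convention of
#' the activity-overlap estimator literature), scaled by a multiplicative
#' adjustment \code{adjust}. The density is evaluated on \code{m} equally
#' spaced grid points and renormalised so its trapezoidal integral over the
#' circle is exactly 1.
#'
#' @param times_radians detection times as angles in \eqn{[0, 2\pi)};
#'   must be non-empty.
#' @param m grid size (default 128).
#' @param adjust multiplicative bandwidth adjustment c (default 1; 0.8 is a
#'   common alternative for the grid overlap estimator).
#' @param kappa optional fixed kernel concentration, bypassing the plug-in.
#' @return a \code{circular_density}: list with \code{kappa}, \code{grid},
#'   \code{density}, \code{n}, \code{data}.
#' @export
fit_circular_density <- function(times_radians, m = 128, adjust = 1,
                                 kappa = NULL) {
  n <- length(times_radians)
  if (n < 1) stop("at least one detection time is required")
  if (is.null(kappa)) kappa <- taylor_bandwidth(times_radians, adjust = adjust)
  grid <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  dens <- vm_kde(grid, times_radians, kappa)
  # renormalise on the grid (equally spaced circular grid: trapezoid = mean)
  dens <- dens / (mean(dens) * 2 * pi)
  structure(list(kappa = kappa, grid = grid, density = dens, n = n,
                 data = times_radians),
            class = "circular_density")
}

#' @export
print.circular_density <- function(x, ...) {
  cat("<circular_density> n = ", x$n, ", kernel concentration = ",
      signif(x$kappa, 4), ", grid = ", length(x$grid), " points\n", sep = "")
  invisible(x)
}

#' Evaluate a fitted circular density at arbitrary angles
#'
#' @param fit a \code{circular_density}.
#' @param theta angles in radians.
#' @return density values.
#' @export
density_at <- function(fit, theta) {
  vm_kde(theta, fit$data, fit$kappa)
}

#' Classify a species' diel activity pattern
#'
#' Tallies independent detections into night, day and crepuscular (dawn and
#' dusk pooled) periods, converts the tallies to duration-normalised rates
#' (events per hour of period, using the mean period durations over the solar
#' days represented in the data), and labels the species by the period with
#' the highest rate. When the top rate does not exceed the runner-up by the
#' dominance factor the species is called cathemeral.
#'
#' @param events annotated detections of one species (columns \code{period},
#'   \code{sunrise}, \code{sunset}; see \code{\link{annotate_solar}});
#'   must be non-empty.
#' @param dominance factor by which the top rate must exceed the second for a
#'   non-cathemeral call (default 1.25).
#' @return character label in \code{nocturnal, diurnal, crepuscular,
#'   cathemeral}, with attribute \code{rates} (events/hour per period).
#' @export
classify_diel <- function(events, dominance = 1.25) {
  if (nrow(events) == 0) stop("cannot classify an empty event set")
  if (is.null(events$period)) stop("no period column; run annotate_solar() first")
  pooled <- c(dawn = "crepuscular", dusk = "crepuscular",
              day = "diurnal", night = "nocturnal")[as.character(events$period)]
  counts <- c(nocturnal = sum(pooled == "nocturnal"),
              diurnal = sum(pooled == "diurnal"),
              crepuscular = sum(pooled == "crepuscular"))
  uk <- !duplicated(data.frame(as.Date(as.POSIXlt(events$timestamp)),
                               events$site_id, events$sunrise))
  daylen <- events$sunset[uk] - events$sunrise[uk]
  dur <- c(nocturnal = mean(24 - daylen - 2), diurnal = mean(daylen - 2),
           crepuscular = 4)
  rates <- counts / dur
  ord <- order(rates, decreasing = TRUE)
  label <- if (rates[ord[1]] < dominance * rates[ord[2]]) "cathemeral"
           else names(rates)[ord[1]]
  structure(label, rates = rates)
}

#' Export activity profiles as a tidy table
#'
#' @param profiles list of \code{activity_profile} objects.
#' @return data.frame with columns \code{species, season, hour, count, z}.
#' @export
profile_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(species = p$species, season = p$season, hour = 0:23,
               count = p$counts, z = p$z)))
}
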