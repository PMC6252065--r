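#' Species activity template
#'
#' Describes a species' true diel activity as a von Mises mixture on the 24-h
#' circle whose components are anchored to solar events, so that the clock
#' density drifts through the year exactly as sunrise and sunset do. Anchors:
#' \code{sunrise}, \code{sunset}, \code{noon} (midpoint of daylight),
#' \code{midnight} (midpoint of night) or \code{clock} (fixed clock hour,
#' given by \code{shift}).
#'
#' @param name species label.
#' @param guild one of \code{nocturnal, diurnal, crepuscular, cathemeral}.
#' @param components data.frame with columns \code{anchor}, \code{shift}
#'   (hours relative to the anchor; absolute hour for \code{clock}),
#'   \code{kappa} (> 0 concentration, or 0 for a uniform component) and
#'   \code{weight} (summing to 1).
#' @param daily_rate expected independent detections per camera-day; a single
#'   number, or a vector named by season.
#' @return a \code{species_template}.
#' @export
species_template <- function(name, guild, components, daily_rate) {
  guild <- match.arg(guild, c("nocturnal", "diurnal", "crepuscular", "cathemeral"))
  stopifnot(is.data.frame(components),
            all(c("anchor", "shift", "kappa", "weight") %in% names(components)),
            all(components$anchor %in% c("sunrise", "sunset", "noon",
                                         "midnight", "clock")),
            all(components$kappa >= 0), all(components$weight > 0),
            all(daily_rate >= 0))
  if (abs(sum(components$weight) - 1) > 1e-8)
    stop("mixture weights must sum to 1")
  structure(list(name = name, guild = guild, components = components,
                 daily_rate = daily_rate),
            class = "species_template")
}

#' @export
print.species_template <- function(x, ...) {
  cat("<species_template> ", x$name, " (", x$guild, "), ",
      nrow(x$components), " component(s), daily rate ",
      paste(signif(x$daily_rate, 3), collapse = "/"), "\n", sep = "")
  invisible(x)
}

anchor_hour <- function(anchor, shift, solar_day) {
  sr <- solar_day$sunrise; ss <- solar_day$sunset
  base <- switch(anchor,
                 sunrise = sr, sunset = ss,
                 noon = (sr + ss) / 2,
                 midnight = (sr + ss) / 2 + 12,
                 clock = 0)
  (base + shift) %% 24
}

#' Analytic clock-time density of a template on a given solar day
#'
#' @param template a \code{\link{species_template}}.
#' @param solar_day a one-row \code{\link{solar_day}} giving the anchors.
#' @param theta angles in radians at which to evaluate.
#' @return density values on the 24-h circle (radian scale, integrates to 1).
#' @export
template_density <- function(template, solar_day, theta) {
  cmp <- template$components
  dens <- rep(0, length(theta))
  for (k in seq_len(nrow(cmp))) {
    mu <- hours_to_radians(anchor_hour(cmp$anchor[k], cmp$shift[k], solar_day))
    dens <- dens + cmp$weight[k] * dvonmises(theta, mu, cmp$kappa[k])
  }
  dens
}

rate_for_season <- function(daily_rate, season) {
  if (length(daily_rate) == 1 && is.null(names(daily_rate))) return(daily_rate)
  r <- daily_rate[as.character(season)]
  ifelse(is.na(r), 0, unname(r))
}

#' Default species templates
#'
#' Ten mid-latitude mammal species in three diel guilds (four nocturnal, four
#' diurnal--counting both squirrel species and deer--and hares/rabbit as
#' crepuscular), with daily detection rates ranked like a multi-survey
#' camera-trap collation (squirrels most detected, hares least).
#'
#' @return named list of \code{\link{species_template}} objects.
#' @export
default_templates <- function() {
  vm <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(anchor = c("sunrise", "sunset", "noon", "midnight",
                          "clock")[m[, 1]],
               shift = 0, kappa = m[, 2], weight = m[, 3])
  }
  # anchor codes: 1 sunrise, 2 sunset, 3 noon, 4 midnight, 5 clock
  tpl <- list(
    species_template("badger", "nocturnal", vm(4, 2.5, 1), 0.32),
    species_template("fox", "nocturnal",
                     vm(4, 1.2, 0.8, 1, 4.0, 0.1, 2, 4.0, 0.1), 0.22),
    species_template("pine_marten", "nocturnal", vm(4, 1.5, 1), 0.33),
    species_template("wood_mouse", "nocturnal", vm(4, 2.0, 1), 0.28),
    species_template("irish_hare", "crepuscular",
                     vm(1, 6, 0.5, 2, 6, 0.5), 0.15),
    species_template("european_hare", "crepuscular",
                     vm(1, 6, 0.5, 2, 6, 0.5), 0.11),
    species_template("rabbit", "crepuscular",
                     vm(1, 6, 0.55, 2, 6, 0.45), 0.40),
    species_template("grey_squirrel", "diurnal", vm(3, 2.5, 1), 0.45),
    species_template("red_squirrel", "diurnal", vm(3, 2.5, 1), 0.30),
    species_template("fallow_deer", "diurnal", vm(3, 1.2, 1), 0.20)
  )
  stats::setNames(tpl, vapply(tpl, `[[`, "", "name"))
}

#' Default deployment plan
#'
#' Four study sites at 54--55 deg N, five cameras per site (20 cameras), and
#' four 14-day deployment windows, one per season.
#'
#' @param cameras_per_site cameras at each site (default 5).
#' @return a list with \code{sites} (site table) and \code{windows}
#'   (data.frame: season, start, end) of class \code{deployment_plan}.
#' @export
default_deployment_plan <- function(cameras_per_site = 5) {
  sites <- data.frame(
    site_id = c("glen", "lough", "forest", "moor"),
    latitude = c(54.8, 54.4, 55.0, 54.6),
    longitude = c(-6.1, -5.9, -7.3, -6.8),
    utc_offset = 0
  )
  windows <- data.frame(
    season = c("spring", "summer", "autumn", "winter"),
    start = as.Date(c("2015-04-01", "2015-07-01", "2015-10-01", "2016-01-05")),
    end = as.Date(c("2015-04-14", "2015-07-14", "2015-10-14", "2016-01-18"))
  )
  structure(list(sites = sites, windows = windows,
                 cameras_per_site = cameras_per_site),
            class = "deployment_plan")
}

#' Simulate a camera-trap detection dataset with known ground truth
#'
#' For every camera-day in the plan, draws a Poisson number of detections per
#' species (at the template's daily rate) and detection clock times from the
#' template's von Mises mixture anchored to that date's computed sunrise and
#' sunset, rounded to the minute. Ground truth (analytic densities per
#' species and season, true pairwise overlap by quadrature, and the true
#' rotation lag between requested pairs) is returned alongside.
#'
#' @param templates list of \code{\link{species_template}}s.
#' @param plan a \code{\link{default_deployment_plan}}-style plan.
#' @param seed integer seed; the full detection stream is a deterministic
#'   function of it.
#' @param pairs optional list of 2-vectors of species names for which true
#'   overlap and true peak lag are recorded.
#' @return list with \code{detections} (canonical detection data.frame),
#'   \code{sites}, and \code{truth} (list: \code{reference_days},
#'   \code{delta}, \code{lags}, \code{templates}).
#' @export
simulate_detections <- function(templates = default_templates(),
                                plan = default_deployment_plan(),
                                seed = 1, pairs = NULL) {
  set.seed(seed)
  sites <- plan$sites
  rows <- vector("list", 0)
  for (w in seq_len(nrow(plan$windows))) {
    dates <- seq(plan$windows$start[w], plan$windows$end[w], by = "day")
    season <- plan$windows$season[w]
    for (s in seq_len(nrow(sites))) {
      sd_all <- sun_times(dates, sites$latitude[s], sites$longitude[s],
                          sites$utc_offset[s])
      for (cam in seq_len(plan$cameras_per_site)) {
        cam_id <- sprintf("%s_cam%02d", sites$site_id[s], cam)
        for (d in seq_along(dates)) {
          sd1 <- sd_all[d, ]
          for (tpl in templates) {
            rate <- rate_for_season(tpl$daily_rate, season)
            n <- stats::rpois(1, rate)
            if (n == 0) next
            cmp <- tpl$components
            pick <- sample.int(nrow(cmp), n, replace = TRUE,
                               prob = cmp$weight)
            hrs <- vapply(pick, function(k) {
              mu <- hours_to_radians(anchor_hour(cmp$anchor[k], cmp$shift[k], sd1))
              radians_to_hours(rvonmises(1, mu, cmp$kappa[k]))
            }, numeric(1))
            hrs <- floor(hrs * 60) / 60  # minute resolution
            rows[[length(rows) + 1]] <- data.frame(
              species = tpl$name, site_id = sites$site_id[s],
              camera_id = cam_id,
              timestamp = as.POSIXct(dates[d], tz = "UTC") + hrs * 3600,
              latitude = sites$latitude[s], longitude = sites$longitude[s],
              group_size = 1L)
          }
        }
      }
    }
  }
  det <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), site_id = character(),
               camera_id = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"),
               latitude = numeric(), longitude = numeric(),
               group_size = integer())
  det <- det[order(det$species, det$camera_id, det$timestamp), , drop = FALSE]
  # burst semantics: same species/camera/minute is a single event
  det <- det[!duplicated(data.frame(det$species, det$camera_id,
                                    det$timestamp)), , drop = FALSE]
  rownames(det) <- NULL
  truth <- ground_truth(templates, plan, pairs)
  list(detections = det, sites = sites, truth = truth)
}

# Mid-window reference solar day per season (central site), used to evaluate
# the analytic densities and true overlaps.
reference_days <- function(plan) {
  mid <- plan$windows$start + floor(as.numeric(plan$windows$end -
                                                 plan$windows$start) / 2)
  lat <- mean(plan$sites$latitude); lon <- mean(plan$sites$longitude)
  sd <- sun_times(mid, lat, lon, plan$sites$utc_offset[1])
  rownames(sd) <- plan$windows$season
  sd
}

ground_truth <- function(templates, plan, pairs = NULL) {
  refs <- reference_days(plan)
  annual <- refs[which.min(abs(diel_durations(refs)$day - 12)), ]
  delta <- NULL; lags <- NULL
  if (!is.null(pairs)) {
    delta <- do.call(rbind, lapply(pairs, function(pr) {
      data.frame(species_a = pr[1], species_b = pr[2],
                 delta_true = true_overlap(templates[[pr[1]]],
                                           templates[[pr[2]]], annual))
    }))
    lags <- do.call(rbind, lapply(pairs, function(pr) {
      data.frame(species_a = pr[1], species_b = pr[2],
                 lag_true = true_peak_lag(templates[[pr[1]]],
                                          templates[[pr[2]]], annual))
    }))
  }
  list(reference_days = refs, annual_reference = annual,
       delta = delta, lags = lags, templates = templates)
}

#' Draw detection clock times directly from a template
#'
#' Samples n clock times (in radians) from the template's von Mises mixture
#' anchored to a fixed solar day, bypassing the camera/deployment machinery.
#' Useful for ground-truth recovery experiments.
#'
#' @param template a \code{\link{species_template}}.
#' @param solar_day a one-row \code{\link{solar_day}}.
#' @param n number of detection times.
#' @return numeric vector of angles in \eqn{[0, 2\pi)}.
#' @export
sample_template <- function(template, solar_day, n) {
  cmp <- template$components
  pick <- sample.int(nrow(cmp), n, replace = TRUE, prob = cmp$weight)
  out <- numeric(n)
  for (k in unique(pick)) {
    mu <- hours_to_radians(anchor_hour(cmp$anchor[k], cmp$shift[k], solar_day))
    sel <- pick == k
    out[sel] <- rvonmises(sum(sel), mu, cmp$kappa[k])
  }
  out
}

#' True overlap of two templates by quadrature
#'
#' \eqn{\int \min(f_a, f_b)} of the analytic mixture densities on a fine
#' equally spaced grid (4,096 points by default), by the trapezoid rule (on a
#' periodic equally spaced grid this is the rectangle/mean rule) or composite
#' Simpson's rule.
#'
#' @param template_a,template_b \code{\link{species_template}}s.
#' @param solar_day reference \code{\link{solar_day}} fixing the anchors.
#' @param n_grid number of grid points (>= 4096 recommended).
#' @param method \code{"trapezoid"} or \code{"simpson"}.
#' @return the true overlap coefficient in \eqn{[0, 1]}.
#' @export
true_overlap <- function(template_a, template_b, solar_day, n_grid = 4096,
                         method = c("trapezoid", "simpson")) {
  method <- match.arg(method)
  if (method == "simpson" && n_grid %% 2 != 0) n_grid <- n_grid + 1
  theta <- seq(0, 2 * pi, length.out = n_grid + 1)
  g <- pmin(template_density(template_a, solar_day, theta),
            template_density(template_b, solar_day, theta))
  h <- 2 * pi / n_grid
  val <- if (method == "trapezoid") {
    h * (sum(g) - (g[1] + g[n_grid + 1]) / 2)
  } else {
    w <- c(1, rep(c(4, 2), length.out = n_grid - 1), 1)
    h / 3 * sum(w * g)
  }
  min(max(val, 0), 1)
}

#' True peak lag between two templates
#'
#' Hour lag maximising |r| of the circular cross-correlation between the two
#' analytic densities evaluated at the 24 hourly bin centres.
#'
#' @inheritParams true_overlap
#' @return integer lag in hours (-12..11).
#' @export
true_peak_lag <- function(template_a, template_b, solar_day) {
  theta <- hours_to_radians(0:23 + 0.5)
  fa <- template_density(template_a, solar_day, theta)
  fb <- template_density(template_b, solar_day, theta)
  r <- circular_ccf(fa, fb)
  as.integer(names(r)[which.max(abs(r))])
}

#' Write a simulated scene to disk
#'
#' Writes the detection and site CSVs in the dialect read by
#' \code{\link{read_detections}}/\code{\link{read_sites}}, and the ground
#' truth as a YAML sidecar (template parameters, reference days and true
#' pairwise overlaps).
#'
#' @param scene result of \code{\link{simulate_detections}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_detections(scene$detections, file.path(dir, "detections.csv"))
  utils::write.csv(scene$sites, file.path(dir, "sites.csv"), row.names = FALSE,
                   quote = FALSE)
  tr <- scene$truth
  yaml::write_yaml(list(
    reference_days = lapply(as.data.frame(tr$reference_days), as.character),
    delta = if (!is.null(tr$delta)) as.list(tr$delta),
    lags = if (!is.null(tr$lags)) as.list(tr$lags),
    templates = lapply(tr$templates, function(t)
      list(name = t$name, guild = t$guild, daily_rate = as.list(t$daily_rate),
           components = as.list(t$components)))
  ), file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
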