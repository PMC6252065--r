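test_that("hourly bins begin at the hour mark", {
  rec <- make_records(c("2015-07-01 11:00", "2015-07-01 11:59",
                        "2015-07-01 12:00"))
  p <- bin_hourly(rec)
  expect_equal(p$counts[12], 2)  # bin 12 = [11:00, 12:00)
  expect_equal(p$counts[13], 1)
  expect_equal(p$n_events, 3)
  expect_equal(sum(p$counts), p$n_events)
})

test_that("one event per hour yields a uniform profile", {
  rec <- make_records(sprintf("2015-07-01 %02d:30", 0:23))
  p <- bin_hourly(rec)
  expect_equal(p$counts, rep(1, 24))
  expect_equal(p$z, rep(0, 24))  # constant profile normalises to zeros
})

test_that("binning matches a histogram oracle on random events", {
  set.seed(12)
  h <- runif(500, 0, 24)
  rec <- make_records(format(as.POSIXct("2015-07-01", tz = "UTC") +
                               floor(h * 3600), "%Y-%m-%d %H:%M:%S"))
  p <- bin_hourly(rec)
  want <- as.vector(table(cut(h, 0:24, right = FALSE)))
  expect_equal(p$counts, want)
  # radian times preserve the clock positions
  expect_equal(sort(radians_to_hours(p$times_radians)),
               sort(floor(h * 3600) / 3600), tolerance = 1e-9)
})

test_that("annual counts equal the sum of seasonal counts", {
  sc <- simulate_detections(plan = default_deployment_plan(cameras_per_site = 1),
                            seed = 5)
  ev <- annotate_solar(sc$detections, sc$sites)
  annual <- bin_hourly(ev, species = "badger")
  seasonal <- lapply(c("spring", "summer", "autumn", "winter"),
                     function(s) bin_hourly(ev, species = "badger", season = s))
  expect_equal(annual$counts, Reduce(`+`, lapply(seasonal, `[[`, "counts")))
})

test_that("min-max normalisation matches the formula", {
  x <- c(2, 4, 6, rep(2, 21))
  z <- normalise_counts(x)
  expect_equal(min(z), 0)
  expect_equal(max(z), 1)
  expect_equal(z[2], 0.5)
  set.seed(8)
  for (rep in 1:10) {
    x <- rpois(24, 5)
    if (max(x) == min(x)) next
    expect_equal(normalise_counts(x), (x - min(x)) / (max(x) - min(x)),
                 tolerance = 1e-12)
  }
  expect_equal(normalise_counts(rep(3, 24)), rep(0, 24))
})

test_that("circular density integrates to one and tracks its sample", {
  # point-mass limit: sharply peaked at the common angle
  tight <- fit_circular_density(rep(pi / 3, 50))
  expect_equal(mean(tight$density) * 2 * pi, 1, tolerance = 1e-6)
  expect_equal(tight$grid[which.max(tight$density)], pi / 3, tolerance = 0.05)
  expect_gt(max(tight$density), 20 * min(tight$density))
  # flat limit: uniform circular sample
  set.seed(4)
  flat <- fit_circular_density(runif(4000, 0, 2 * pi))
  expect_lt(max(flat$density) / min(flat$density), 1.35)
  expect_equal(mean(flat$density) * 2 * pi, 1, tolerance = 1e-6)
  expect_error(fit_circular_density(numeric(0)), "at least one")
})

test_that("fitted density approaches the analytic von Mises in L1", {
  set.seed(21)
  x <- rvonmises(4000, 1, 2)
  fit <- fit_circular_density(x, m = 512)
  l1 <- mean(abs(fit$density - dvonmises(fit$grid, 1, 2))) * 2 * pi
  expect_lt(l1, 0.08)
})

test_that("diel classification is driven by duration-normalised rates", {
  sites <- make_sites()
  # all events deep in the night period -> nocturnal
  night <- annotate_solar(make_records(sprintf("2015-07-01 0%d:0%d", rep(0:2, 4),
                                               rep(c(1, 3, 5, 7), each = 3)),
                                       camera = paste0("c", 1:12)), sites)
  expect_equal(as.character(classify_diel(night)), "nocturnal")
  expect_error(classify_diel(night[0, ]), "empty")
})

test_that("rate-balanced activity is called cathemeral", {
  sd <- sun_times(as.Date("2015-07-01"), 54.6, -5.9, 0)
  dur <- diel_durations(sd)
  # build counts proportional to period durations -> equal rates -> tie
  n_night <- 40
  per_hour <- n_night / dur$night
  mk <- function(hours) format(as.POSIXct("2015-07-01", tz = "UTC") +
                                 hours * 3600, "%Y-%m-%d %H:%M:%S")
  hours_night <- seq(sd$sunset + 1.05, sd$sunset + 1 + dur$night - 0.1,
                     length.out = n_night) %% 24
  hours_day <- seq(sd$sunrise + 1.05, sd$sunset - 1.05,
                   length.out = round(per_hour * dur$day))
  hours_crep <- seq(sd$sunrise - 0.95, sd$sunrise + 0.95,
                    length.out = round(per_hour * 4))
  rec <- make_records(mk(c(hours_night, hours_day, hours_crep)),
                      camera = paste0("c", seq_along(c(hours_night, hours_day,
                                                       hours_crep))))
  ev <- annotate_solar(rec, make_sites())
  expect_equal(as.character(classify_diel(ev)), "cathemeral")
})

test_that("synthetic guilds are recovered from 200-event samples", {
  sites <- make_sites(lat = 54.7, lon = -6.5)
  sd <- sun_times(as.Date("2015-04-07"), 54.7, -6.5, 0)
  tpl <- default_templates()
  set.seed(99)
  for (sp in c("badger", "grey_squirrel", "irish_hare")) {
    hits <- replicate(20, {
      th <- sample_template(tpl[[sp]], sd, 200)
      rec <- make_records(format(as.POSIXct("2015-04-07", tz = "UTC") +
                                   floor(radians_to_hours(th) * 3600),
                                 "%Y-%m-%d %H:%M:%S"),
                          camera = paste0("c", 1:200),
                          lat = 54.7, lon = -6.5)
      ev <- annotate_solar(rec, sites)
      as.character(classify_diel(ev)) == tpl[[sp]]$guild
    })
    expect_gte(mean(hits), 0.95)
  }
})
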