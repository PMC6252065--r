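small_plan <- function() {
  p <- default_deployment_plan(cameras_per_site = 2)
  p$sites <- p$sites[1:2, ]
  p$windows <- p$windows[c(1, 3), ]
  p
}

test_that("a zero rate yields an empty dataset", {
  tpl <- default_templates()["badger"]
  tpl$badger$daily_rate <- 0
  sc <- simulate_detections(tpl, small_plan(), seed = 1)
  expect_equal(nrow(sc$detections), 0)
})

test_that("the same seed reproduces the scene byte for byte", {
  tpl <- default_templates()[c("fox", "irish_hare")]
  sc1 <- simulate_detections(tpl, small_plan(), seed = 9)
  sc2 <- simulate_detections(tpl, small_plan(), seed = 9)
  expect_identical(sc1$detections, sc2$detections)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_detections(sc1$detections, f1)
  write_detections(sc2$detections, f2)
  expect_identical(readLines(f1), readLines(f2))
  sc3 <- simulate_detections(tpl, small_plan(), seed = 10)
  expect_false(identical(sc1$detections, sc3$detections))
})

test_that("invalid mixtures are rejected", {
  expect_error(species_template("x", "nocturnal",
                                data.frame(anchor = "midnight", shift = 0,
                                           kappa = 2, weight = 0.7), 1),
               "sum to 1")
  expect_error(species_template("x", "weird",
                                data.frame(anchor = "midnight", shift = 0,
                                           kappa = 2, weight = 1), 1))
})

test_that("a nocturnal template concentrates detections in the night period", {
  tpl <- default_templates()["wood_mouse"]
  tpl$wood_mouse$daily_rate <- 3
  plan <- small_plan()
  sc <- simulate_detections(tpl, plan, seed = 33)
  ev <- annotate_solar(sc$detections, sc$sites)
  expect_gt(nrow(ev), 250)
  # analytic night-interval mass of the template on the reference day
  sd <- sc$truth$annual_reference
  th <- seq(0, 2 * pi, length.out = 8193)[-8193]
  dens <- template_density(tpl$wood_mouse, sd, th)
  h <- radians_to_hours(th)
  night <- ((h - (sd$sunset + 1)) %% 24) < ((sd$sunrise - 1 - (sd$sunset + 1)) %% 24)
  mass <- mean(dens * night) * 2 * pi
  frac_night <- mean(ev$period == "night")
  expect_gte(frac_night, 0.8)
  expect_lt(abs(frac_night - mass), 0.1)
})

test_that("template densities integrate to one", {
  sd <- sun_times(as.Date("2015-04-07"), 54.7, -6.5, 0)
  th <- seq(0, 2 * pi, length.out = 4097)[-4097]
  for (tpl in default_templates()) {
    dens <- template_density(tpl, sd, th)
    expect_equal(mean(dens) * 2 * pi, 1, tolerance = 1e-8)
  }
})

test_that("true overlap quadrature is consistent across rules", {
  sd <- sun_times(as.Date("2015-04-07"), 54.7, -6.5, 0)
  tpl <- default_templates()
  expect_equal(true_overlap(tpl$badger, tpl$badger, sd), 1, tolerance = 1e-6)
  sep <- list(
    species_template("a", "nocturnal",
                     data.frame(anchor = "clock", shift = 0, kappa = 8,
                                weight = 1), 1),
    species_template("b", "diurnal",
                     data.frame(anchor = "clock", shift = 12, kappa = 8,
                                weight = 1), 1))
  expect_lt(true_overlap(sep[[1]], sep[[2]], sd), 0.05)
  for (pair in list(c("fox", "irish_hare"), c("pine_marten", "grey_squirrel"))) {
    tr <- true_overlap(tpl[[pair[1]]], tpl[[pair[2]]], sd, method = "trapezoid")
    si <- true_overlap(tpl[[pair[1]]], tpl[[pair[2]]], sd, method = "simpson")
    expect_equal(tr, si, tolerance = 1e-4)
  }
})

test_that("estimated overlap recovers the generating truth at n = 1000", {
  sd <- sun_times(as.Date("2015-04-07"), 54.7, -6.5, 0)
  tpl <- default_templates()
  truth <- true_overlap(tpl$fox, tpl$rabbit, sd)
  set.seed(61)
  hits <- replicate(15, {
    a <- sample_template(tpl$fox, sd, 1000)
    b <- sample_template(tpl$rabbit, sd, 1000)
    abs(overlap_delta(a, b) - truth) <= 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("write_scene emits the CSV dialects and a truth sidecar", {
  dir <- withr::local_tempdir()
  tpl <- default_templates()[c("fox", "rabbit")]
  sc <- simulate_detections(tpl, small_plan(), seed = 3,
                            pairs = list(c("fox", "rabbit")))
  write_scene(sc, dir)
  expect_true(file.exists(file.path(dir, "detections.csv")))
  back <- read_detections(file.path(dir, "detections.csv"))
  expect_equal(nrow(back), nrow(sc$detections))
  sites <- read_sites(file.path(dir, "sites.csv"))
  expect_equal(sites$site_id, sc$sites$site_id)
  truth <- yaml::read_yaml(file.path(dir, "ground_truth.yaml"))
  expect_equal(unlist(truth$delta$delta_true),
               sc$truth$delta$delta_true, tolerance = 1e-6)
})
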