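test_that("a well-formed CSV reads back in timestamp order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,site_id,camera_id,timestamp,latitude,longitude,group_size",
               "fox,A,A_cam1,2015-07-01 10:30,54.6,-5.9,1",
               "fox,A,A_cam1,2015-07-01 08:00,54.6,-5.9,1",
               "hare,A,A_cam1,01/07/2015 09:15,54.6,-5.9,2"), f)
  rec <- read_detections(f)
  expect_equal(nrow(rec), 3)
  expect_s3_class(rec$timestamp, "POSIXct")
  expect_equal(format(rec$timestamp[rec$species == "fox"], "%H:%M"),
               c("08:00", "10:30"))
  expect_equal(rec$group_size[rec$species == "hare"], 2L)
})

test_that("invalid rows are reported with their row numbers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,site_id,camera_id,timestamp,latitude,longitude",
               "fox,A,A_cam1,2015-07-01 10:30,95,-5.9",
               "fox,A,A_cam1,not-a-time,54.6,-5.9"), f)
  expect_error(read_detections(f), "row 1.*latitude 95")
  expect_error(read_detections(f), "row 2.*unparseable")
})

test_that("a missing mapped column is a schema error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,site_id,timestamp,latitude,longitude",
               "fox,A,2015-07-01 10:30,54.6,-5.9"), f)
  expect_error(read_detections(f), "missing column.*camera_id")
})

test_that("write_detections/read_detections round-trips simulated data", {
  plan <- default_deployment_plan(cameras_per_site = 1)
  plan$windows <- plan$windows[1, ]
  sc <- simulate_detections(plan = plan, seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_detections(sc$detections, f)
  back <- read_detections(f)
  expect_equal(back, sc$detections)
})

test_that("same-minute bursts collapse to a single record on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,site_id,camera_id,timestamp,latitude,longitude",
               "fox,A,A_cam1,2015-07-01 10:30,54.6,-5.9",
               "fox,A,A_cam1,2015-07-01 10:30,54.6,-5.9",
               "fox,A,A_cam2,2015-07-01 10:30,54.6,-5.9"), f)
  expect_equal(nrow(read_detections(f)), 2)
})

test_that("independence filtering keeps the greedy-scan events", {
  rec <- make_records(c("2015-07-01 10:00", "2015-07-01 10:30",
                        "2015-07-01 11:30"))
  ev <- filter_independent(rec, 1)
  expect_equal(format(ev$timestamp, "%H:%M"), c("10:00", "11:30"))
  expect_equal(attr(ev, "n_removed"), 1)
})

test_that("single records and separate cameras are untouched", {
  one <- filter_independent(make_records("2015-07-01 10:00"), 1)
  expect_equal(nrow(one), 1)
  two <- rbind(make_records("2015-07-01 10:00", camera = "c1"),
               make_records("2015-07-01 10:00", camera = "c2"))
  expect_equal(nrow(filter_independent(two, 1)), 2)
})

test_that("independence filter matches the greedy oracle on random streams", {
  set.seed(101)
  for (rep in 1:20) {
    hrs <- sort(runif(40, 0, 72))
    rec <- make_records(format(as.POSIXct("2015-07-01", tz = "UTC") +
                                 round(hrs * 3600), "%Y-%m-%d %H:%M:%S"))
    interval <- sample(c(0.5, 1, 2), 1)
    got <- filter_independent(rec, interval)
    want <- oracle_greedy_filter(as.numeric(rec$timestamp) / 3600, interval)
    expect_equal(as.numeric(got$timestamp),
                 sort(as.numeric(rec$timestamp[want])))
  }
})

test_that("independence filtering is idempotent, monotone, and identity at 0", {
  set.seed(7)
  hrs <- sort(runif(60, 0, 48))
  rec <- make_records(format(as.POSIXct("2015-07-01", tz = "UTC") +
                               round(hrs * 3600), "%Y-%m-%d %H:%M:%S"))
  once <- filter_independent(rec, 1)
  twice <- filter_independent(as.data.frame(once), 1)
  expect_equal(as.data.frame(twice)[names(rec)], as.data.frame(once)[names(rec)])
  expect_equal(attr(twice, "n_removed"), 0)
  gaps <- diff(as.numeric(once$timestamp))
  expect_true(all(gaps >= 3600))
  counts <- sapply(c(0, 0.5, 1, 2, 4), function(iv)
    nrow(filter_independent(rec, iv)))
  expect_true(all(diff(counts) <= 0))
  expect_equal(nrow(filter_independent(rec, 0)), nrow(rec))
  expect_error(filter_independent(rec, -1), "non-negative")
})

test_that("co-occurrence restriction keeps only shared locations", {
  rec <- rbind(make_records("2015-07-01 10:00", species = "fox", site = "A"),
               make_records("2015-07-01 11:00", species = "fox", site = "B"),
               make_records("2015-07-01 12:00", species = "hare", site = "B"),
               make_records("2015-07-01 13:00", species = "hare", site = "C"))
  out <- restrict_to_cooccurrence(rec, "fox", "hare")
  expect_equal(attr(out, "locations"), "B")
  expect_true(all(out$site_id == "B"))
  expect_error(restrict_to_cooccurrence(rec, "fox", "badger"),
               "unknown species")
  only_a <- rec[rec$site_id %in% c("A", "C"), ]
  expect_warning(empty <- restrict_to_cooccurrence(only_a, "fox", "hare"),
                 "no shared locations")
  expect_equal(nrow(empty), 0)
})

test_that("co-occurrence restriction equals brute-force set intersection", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 60
    rec <- make_records(rep("2015-07-01 10:00", n),
                        species = sample(c("fox", "hare", "badger"), n, TRUE),
                        site = sample(LETTERS[1:6], n, TRUE))
    rec$camera_id <- paste0(rec$site_id, "_c1")
    got <- restrict_to_cooccurrence(rec, "fox", "hare")
    shared <- intersect(unique(rec$site_id[rec$species == "fox"]),
                        unique(rec$site_id[rec$species == "hare"]))
    expect_setequal(attr(got, "locations"), shared)
    expect_equal(nrow(got), sum(rec$species %in% c("fox", "hare") &
                                  rec$site_id %in% shared))
  }
})
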