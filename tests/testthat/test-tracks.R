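write_track_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

mb_rows <- function(id, times, lon, lat, sensor = "gps", lc = NA) {
  data.frame(`individual-local-identifier` = id, timestamp = times,
             `location-long` = lon, `location-lat` = lat,
             `sensor-type` = sensor, `argos-lc` = lc, check.names = FALSE)
}

test_that("reading a small valid file yields one track with all fixes", {
  f <- write_track_csv(mb_rows("A", sprintf("2016-04-0%d 12:00:00", 1:3),
                               20 + 0:2 / 10, 60 + 0:2 / 10))
  ts <- read_tracks(f)
  expect_s3_class(ts, "trackset")
  expect_equal(nrow(ts), 3)
  expect_equal(unique(ts$individual), "A")
  expect_equal(attr(ts, "log")$n_unparseable, 0)
})

test_that("a missing coordinate column is reported by name", {
  df <- mb_rows("A", "2016-04-01 12:00:00", 20, 60)
  df$`location-lat` <- NULL
  expect_error(read_tracks(write_track_csv(df)), "location-lat")
  expect_error(read_tracks(write_track_csv(df[0, ])), "empty")
})

test_that("duplicate timestamps keep the first fix and are logged", {
  df <- mb_rows("A", c("2016-04-01 12:00:00", "2016-04-01 12:00:00",
                       "2016-04-02 12:00:00"), c(20, 21, 22), c(60, 61, 62))
  expect_message(ts <- read_tracks(write_track_csv(df)), "1 duplicate")
  expect_equal(nrow(ts), 2)
  expect_equal(ts$lon[1], 20)  # first kept
  expect_equal(attr(ts, "log")$n_duplicate, 1)
})

test_that("Argos class filter keeps classes 3 and 2 and never touches GPS", {
  df <- rbind(
    mb_rows("A", sprintf("2016-04-%02d 12:00:00", 1:6), 20, 60 + 1:6,
            sensor = "argos", lc = c("3", "2", "1", "0", "A", "B")),
    mb_rows("G", sprintf("2016-04-%02d 12:00:00", 1:4), 20, 60 + 1:4))
  ts <- read_tracks(write_track_csv(df))
  expect_warning(out <- filter_quality(ts), "< 3 fixes")  # A keeps only 2 fixes
  a <- out[out$individual == "A", ]
  expect_setequal(a$argos_class, character(0))     # dropped entirely
  g <- out[out$individual == "G", ]
  expect_equal(nrow(g), 4)                         # GPS untouched
  # with a laxer class the Argos track survives with exactly classes >= 0
  out0 <- filter_quality(ts, min_class = "0")
  expect_setequal(out0$argos_class[out0$individual == "A"], c("3", "2", "1", "0"))
})

test_that("an all-class-B Argos track is dropped with a warning", {
  df <- rbind(mb_rows("B1", sprintf("2016-04-%02d 12:00:00", 1:5), 20, 60 + 1:5,
                      sensor = "argos", lc = "B"),
              mb_rows("G", sprintf("2016-04-%02d 12:00:00", 1:4), 20, 60 + 1:4))
  ts <- read_tracks(write_track_csv(df))
  expect_warning(out <- filter_quality(ts), "dropped")
  expect_false("B1" %in% out$individual)
})

test_that("hourly fixes resample to one daily burst", {
  t0 <- as.POSIXct("2016-04-01 00:00:00", tz = "UTC")
  tr <- data.frame(timestamp = t0 + 3600 * (0:216), lon = 20,
                   lat = 60 + (0:216) / 100)
  b <- resample_steps(tr, 1, 0.1)
  expect_length(b, 1)
  expect_equal(nrow(b[[1]]), 10)
  dt <- diff(as.numeric(b[[1]]$timestamp)) / 86400
  expect_true(all(abs(dt - 1) <= 0.1 + 1e-9))
})

test_that("a four-day gap splits daily fixes into two bursts", {
  t0 <- as.POSIXct("2016-04-01 00:00:00", tz = "UTC")
  days <- c(0:4, 8:12)
  tr <- data.frame(timestamp = t0 + 86400 * days, lon = 20, lat = 60 + days)
  b <- resample_steps(tr, 1, 0.1)
  expect_length(b, 2)
  expect_equal(nrow(b[[1]]), 5)
  expect_equal(nrow(b[[2]]), 5)
})

test_that("the greedy rule removes too-close fixes ({0, 0.2, 1, 2} case)", {
  t0 <- as.POSIXct("2016-04-01 00:00:00", tz = "UTC")
  tr <- data.frame(timestamp = t0 + 86400 * c(0, 0.2, 1, 2),
                   lon = 20, lat = c(60, 60.2, 61, 62))
  b <- resample_steps(tr, 1, 0.1)
  expect_length(b, 1)
  expect_equal(b[[1]]$lat, c(60, 61, 62))
})

test_that("resampling is idempotent and keeps intervals inside the window", {
  set.seed(31)
  for (rep in 1:5) {
    t0 <- as.POSIXct("2016-04-01 00:00:00", tz = "UTC")
    gaps <- cumsum(rexp(120, 1 / 0.4))
    tr <- data.frame(timestamp = t0 + 86400 * gaps, lon = 20,
                     lat = 60 + seq_along(gaps) / 50)
    b1 <- resample_steps(tr, 1, 0.1)
    flat <- do.call(rbind, b1)
    b2 <- resample_steps(flat, 1, 0.1)
    expect_equal(lapply(b2, function(d) d$timestamp),
                 lapply(b1, function(d) d$timestamp))
    for (bb in b1) {
      dt <- diff(as.numeric(bb$timestamp)) / 86400
      expect_true(all(dt >= 0.9 - 1e-9 & dt <= 1.1 + 1e-9))
    }
  }
})

test_that("step geometry gives known lengths, headings and turn angles", {
  t0 <- as.POSIXct("2016-04-01 00:00:00", tz = "UTC")
  north3 <- data.frame(timestamp = t0 + 86400 * (0:2), lon = 20,
                       lat = c(70, 71, 72))
  st <- step_geometry(north3)
  expect_equal(st$length_km[1], 111.19, tolerance = 0.1 / 111.19)
  expect_equal(st$heading, c(0, 0))
  expect_equal(st$turn, c(NA_real_, 0))
  back <- data.frame(timestamp = t0 + 86400 * (0:2), lon = 20,
                     lat = c(70, 71, 70))
  expect_equal(step_geometry(back)$turn[2], 180)
})

test_that("coincident fixes carry the previous heading and are flagged", {
  t0 <- as.POSIXct("2016-04-01 00:00:00", tz = "UTC")
  tr <- data.frame(timestamp = t0 + 86400 * (0:3), lon = 20,
                   lat = c(70, 71, 71, 72))
  st <- step_geometry(tr)
  expect_true(st$zero_length[2])
  expect_equal(st$length_km[2], 0)
  expect_equal(st$heading[2], st$heading[1])
  expect_equal(st$turn[3], 0)
})
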