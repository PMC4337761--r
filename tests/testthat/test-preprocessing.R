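test_that("hourly retention keeps the best class per hour and floors timestamps", {
  t0 <- as.POSIXct("2010-01-01 05:10:00", tz = "UTC")
  fx <- tibble::tibble(
    animal_id = "a1",
    timestamp = t0 + c(0, 600, 1200),
    lon = c(90, 90.1, 90.2), lat = c(30, 30.1, 30.2),
    sensor = "ARGOS", location_class = c("B", "1", "A")
  )
  got <- retain_hourly_best(fx)
  expect_equal(nrow(got), 1)
  expect_equal(got$location_class, "1")
  expect_equal(format(got$timestamp, "%H:%M:%S"), "05:00:00")

  # singleton hour: kept, floored
  one <- fx[1, ]
  g1 <- retain_hourly_best(one)
  expect_equal(nrow(g1), 1)
  expect_equal(format(g1$timestamp, "%M:%S"), "00:00")
})

test_that("hourly retention count matches brute force and is idempotent", {
  t0 <- as.POSIXct("2010-01-01 00:00:00", tz = "UTC")
  set.seed(3)
  # 48 fixes, 2 per hour over 24 h
  fx <- tibble::tibble(
    animal_id = "a1",
    timestamp = t0 + rep(0:23, each = 2) * 3600 + rep(c(300, 2100), 24),
    lon = runif(48, 89, 91), lat = runif(48, 29, 31),
    sensor = "ARGOS",
    location_class = sample(c("3", "2", "1", "0", "A", "B"), 48, replace = TRUE)
  )
  got <- retain_hourly_best(fx)
  expect_equal(nrow(got), 24)
  # brute-force oracle: per hour, min quality rank, earliest on ties
  rank <- match(fx$location_class, c("G", "3", "2", "1", "0", "A", "B", "Z"))
  hours <- floor(as.numeric(fx$timestamp) / 3600)
  keep <- vapply(unique(hours), function(h) {
    i <- which(hours == h)
    i[order(rank[i], fx$timestamp[i])][1]
  }, integer(1))
  expect_equal(sort(got$lon), sort(fx$lon[keep]))
  expect_equal(retain_hourly_best(got), got) # idempotent
})

test_that("ties within an hour keep the earlier fix; GPS outranks class 3", {
  t0 <- as.POSIXct("2010-01-01 00:00:00", tz = "UTC")
  fx <- tibble::tibble(
    animal_id = "a1",
    timestamp = t0 + c(100, 200, 300),
    lon = c(1, 2, 3), lat = c(1, 2, 3),
    sensor = c("ARGOS", "ARGOS", "GPS"),
    location_class = c("3", "3", "G")
  )
  expect_equal(retain_hourly_best(fx)$lon, 3) # G beats 3
  fx2 <- fx[1:2, ]
  expect_equal(retain_hourly_best(fx2)$lon, 1) # tie -> earlier
})

test_that("error assignment fills the published SDs and alters nothing else", {
  fx <- tibble::tibble(
    animal_id = "a1",
    timestamp = as.POSIXct("2010-01-01", tz = "UTC") + 1:3 * 3600,
    lon = c(90, 91, 92), lat = c(30, 31, 32),
    sensor = c("GPS", "ARGOS", "ARGOS"),
    location_class = c("G", "3", "B")
  )
  got <- assign_errors(fx, error_model())
  expect_equal(got$error_sd, c(23.5, 450, 7920))
  expect_equal(got$lon, fx$lon)
  expect_equal(got$timestamp, fx$timestamp)

  # error_sd monotone non-increasing in quality rank
  em <- error_model()
  sds <- c(23.5, unname(em$class_sd_m[c("3", "2", "1", "0", "A", "B")]))
  expect_true(all(diff(sds) >= 0))

  # class Z must be removed before error assignment
  fxz <- dplyr::mutate(fx, location_class = c("G", "Z", "B"))
  expect_error(assign_errors(fxz, em), "Z")
})

test_that("error model validates its table", {
  expect_error(error_model(class_sd_m = c("3" = 450)), "all Argos classes")
  expect_error(error_model(gps_error_m = -1), "positive")
  expect_error(
    error_model(class_sd_m = c("3" = 9000, "2" = 630, "1" = 1190,
                               "0" = 2580, "A" = 5070, "B" = 7920)),
    "ordering")
})

test_that("plausibility filter removes the spike a brute-force oracle removes", {
  # 5-fix track: fix 3 implies an out-and-back at ~1000 km/h
  t0 <- as.POSIXct("2010-01-01", tz = "UTC")
  fx <- tibble::tibble(
    animal_id = "a1",
    timestamp = t0 + (0:4) * 3600,
    lon = c(90.0, 90.2, 99.5, 90.4, 90.6),
    lat = rep(30, 5),
    sensor = "ARGOS", location_class = "1"
  )
  # oracle: the single removal that brings max speed under vmax
  speeds_without <- vapply(1:5, function(j) {
    sub <- fx[-j, ]
    max(flywayr:::.track_speeds_kmh(sub))
  }, numeric(1))
  oracle_removed <- which(speeds_without <= 120)
  expect_equal(oracle_removed, 3L) # construction check

  got <- suppressMessages(plausibility_filter(fx, vmax_kmh = 120))
  expect_equal(nrow(got), 4)
  expect_false(99.5 %in% got$lon)
  expect_equal(attr(got, "n_removed"), 1)
})

test_that("filter output always respects the speed bound; clean tracks untouched", {
  set.seed(21)
  t0 <- as.POSIXct("2010-01-01", tz = "UTC")
  slow <- tibble::tibble(
    animal_id = "a1", timestamp = t0 + (0:19) * 3600,
    lon = 90 + cumsum(runif(20, 0, 0.3)), lat = 30 + cumsum(runif(20, 0, 0.2)),
    sensor = "ARGOS", location_class = "2"
  )
  expect_equal(suppressMessages(plausibility_filter(slow, 120)), slow,
               ignore_attr = TRUE)
  # noisy track: property holds regardless of how many fixes go
  noisy <- dplyr::mutate(slow, lon = lon + sample(c(0, 3), 20, TRUE, prob = c(.8, .2)))
  got <- suppressMessages(suppressWarnings(plausibility_filter(noisy, 120)))
  expect_true(all(flywayr:::.track_speeds_kmh(got) <= 120))
})

test_that("class-Z fixes are removed unconditionally, with a warning when all go", {
  t0 <- as.POSIXct("2010-01-01", tz = "UTC")
  fx <- tibble::tibble(
    animal_id = "a1", timestamp = t0 + (0:3) * 3600,
    lon = 90 + (0:3) * 0.1, lat = rep(30, 4),
    sensor = "ARGOS", location_class = "Z"
  )
  expect_warning(got <- suppressMessages(plausibility_filter(fx, 120)), "empty")
  expect_equal(nrow(got), 0)
})

# --- migration-event segmentation on scripted toy tracks -------------------

toy_dwell <- function(lon, lat, start_h, days, gap_h = 6) {
  hours <- seq(start_h, start_h + days * 24, by = gap_h)
  fix_tbl(lon = lon + 0.02 * sin(hours), lat = lat + 0.02 * cos(hours), hours = hours)
}

toy_travel <- function(from, to, start_h, days, gap_h = 6) {
  hours <- seq(start_h + gap_h, start_h + days * 24 - gap_h, by = gap_h)
  f <- (hours - start_h) / (days * 24)
  fix_tbl(lon = from[1] + f * (to[1] - from[1]),
          lat = from[2] + f * (to[2] - from[2]), hours = hours)
}

test_that("a simple A -> B track yields one complete event of the right duration", {
  A <- c(90, 25); B <- c(92, 45)
  fx <- dplyr::bind_rows(
    toy_dwell(A[1], A[2], 0, 30),
    toy_travel(A, B, 30 * 24, 10),
    toy_dwell(B[1], B[2], 40 * 24, 30)
  )
  seg <- suppressMessages(segment_migration_events(fx))
  ev <- migration_events(seg)
  expect_equal(nrow(ev), 1)
  expect_true(ev$complete)
  expect_equal(ev$season, "SPRING")
  expect_equal(ev$duration_days, 10, tolerance = 0.05)
})

test_that("travel that loops back to the start yields no complete event", {
  A <- c(90, 25); H <- c(91, 35)
  fx <- dplyr::bind_rows(
    toy_dwell(A[1], A[2], 0, 30),
    toy_travel(A, H, 30 * 24, 5),
    toy_travel(H, A, 35 * 24, 5),
    toy_dwell(A[1], A[2], 40 * 24, 30)
  )
  seg <- suppressMessages(segment_migration_events(fx))
  ev <- migration_events(seg)
  expect_true(nrow(ev) == 0 || !any(ev$complete))
})

test_that("molt clusters are excluded from the fall event while travel is kept", {
  A <- c(90, 25); B <- c(92, 45); C <- c(93.5, 45.5) # molt site ~150 km from B
  fx <- dplyr::bind_rows(
    toy_dwell(A[1], A[2], 0, 30),              # winter
    toy_travel(A, B, 30 * 24, 8),              # spring migration
    toy_dwell(B[1], B[2], 38 * 24, 40),        # breeding
    toy_travel(B, C, 78 * 24, 1),              # post-breeding molt movement
    toy_dwell(C[1], C[2], 79 * 24, 20),        # molt cluster
    toy_travel(C, A, 99 * 24, 9),              # fall migration
    toy_dwell(A[1], A[2], 108 * 24, 30)        # winter again
  )
  seg <- suppressMessages(segment_migration_events(fx, dwell_days = 15))
  ev <- migration_events(seg)
  expect_equal(sum(ev$complete), 2)
  fall <- ev[ev$season == "FALL", ]
  expect_equal(nrow(fall), 1)
  fall_fixes <- event_fixes(seg, fall$event_id)
  # travel B -> C and C -> A is inside the event ...
  expect_true(any(fall_fixes$lon > 92.5 & fall_fixes$stage == "MIGRATION"))
  # ... but within-cluster molt fixes are not
  expect_false(any(fall_fixes$stage == "MOLT"))
  molt_fixes <- seg[!is.na(seg$stage) & seg$stage == "MOLT", ]
  expect_gt(nrow(molt_fixes), 0)
  expect_true(all(is.na(molt_fixes$event_id)))
})

test_that("tracks with no stationary range report a diagnostic and no events", {
  fx <- toy_travel(c(90, 25), c(92, 45), 0, 10)
  expect_message(seg <- segment_migration_events(fx), "no stationary")
  expect_equal(nrow(migration_events(seg)), 0)
})

test_that("sub-day and multi-month event durations are both handled", {
  A <- c(90, 25); B <- c(90.8, 26.5) # short hop > 2 x stationary radius
  fast <- dplyr::bind_rows(
    toy_dwell(A[1], A[2], 0, 30, gap_h = 2),
    toy_travel(A, B, 30 * 24, 0.5, gap_h = 2),
    toy_dwell(B[1], B[2], 30.5 * 24, 30, gap_h = 2)
  )
  seg <- suppressMessages(segment_migration_events(fast, stationary_radius_km = 40))
  ev <- migration_events(seg)
  expect_equal(nrow(ev), 1)
  expect_lt(ev$duration_days, 1)
  expect_gt(ev$duration_days, 0)

  slowA <- c(90, 25); slowB <- c(92, 45)
  slow <- dplyr::bind_rows(
    toy_dwell(slowA[1], slowA[2], 0, 40, gap_h = 12),
    toy_travel(slowA, slowB, 40 * 24, 170, gap_h = 12),
    toy_dwell(slowB[1], slowB[2], 210 * 24, 40, gap_h = 12)
  )
  seg2 <- suppressMessages(segment_migration_events(slow))
  ev2 <- migration_events(seg2)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$duration_days, 170, tolerance = 0.1)
})
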