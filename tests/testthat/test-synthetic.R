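test_that("scenario configuration validates its inputs", {
  expect_error(scenario_config(corridors = list(matrix(c(90, 30), 1))), "2 waypoints")
  expect_error(scenario_config(flight_speed_kmh = 0), "positive")
  bad_freq <- c("3" = 0.5, "2" = 0.1, "1" = 0.1, "0" = 0.1, "A" = 0.1,
                "B" = 0.1, "Z" = 0.2)
  expect_error(scenario_config(argos_class_freq = bad_freq), "sum to 1")
})

test_that("a fixed seed reproduces the cohort bit-identically", {
  cfg <- fast_scenario(n_individuals = 2, rng_seed = 31)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth, b$truth)
  expect_identical(a$groups, b$groups)
  # and individuals are driven by independent substreams of the master seed
  one <- simulate_individual(cfg, 2)
  expect_identical(one$track, a$tracks[a$tracks$animal_id == "bird_002", ])
})

test_that("ground-truth labels partition the timeline and precede corruption", {
  cfg <- fast_scenario(n_individuals = 1, molt_prob = 1, rng_seed = 5)
  sim <- simulate_individual(cfg, 1)
  expect_equal(nrow(sim$track), nrow(sim$truth))
  expect_false(anyNA(sim$truth$regime))
  expect_setequal(
    intersect(unique(sim$truth$regime),
              c("WINTER", "SPRING_MIG", "BREED", "MOLT", "FALL_MIG", "STOPOVER")),
    unique(sim$truth$regime))
  expect_true("MOLT" %in% sim$truth$regime)
  # observed = truth + error: GPS-scale discrepancies only
  d <- geosphere::distGeo(cbind(sim$track$lon, sim$track$lat),
                          cbind(sim$truth$true_lon, sim$truth$true_lat))
  expect_lt(stats::median(d), 5 * cfg$gps_error_m + 50)
})

test_that("degenerate single-site scenarios stay home", {
  site <- cbind(lon = c(90, 90.0001), lat = c(30, 30.0001))
  cfg <- scenario_config(corridors = list(site),
                         stopovers = list(data.frame(frac = numeric(0),
                                                     mean_dwell_days = numeric(0))),
                         winter_dwell_days = 10, breed_dwell_days = 0.1,
                         frac_gps = 1, rng_seed = 2)
  sim <- simulate_individual(cfg, 1)
  expect_gt(mean(sim$truth$regime == "WINTER"), 0.8)
  spread <- geosphere::distGeo(cbind(sim$truth$true_lon, sim$truth$true_lat),
                               c(90, 30))
  expect_lt(max(spread), 20000) # jitter-scale displacement only
})

test_that("empirical inter-fix gaps match the configured duty cycles", {
  per_track_gaps <- function(sim) {
    unlist(lapply(split(sim$tracks, sim$tracks$animal_id),
                  function(d) diff(as.numeric(d$timestamp)) / 3600))
  }
  gps <- simulate_cohort(scenario_config(n_individuals = 30, winter_dwell_days = 15,
                                         breed_dwell_days = 15, frac_gps = 1,
                                         rng_seed = 2))
  expect_lt(abs(mean(per_track_gaps(gps)) - 4.5) / 4.5, 0.1)
  argos <- simulate_cohort(scenario_config(n_individuals = 30, winter_dwell_days = 15,
                                           breed_dwell_days = 15, frac_gps = 0,
                                           rng_seed = 3))
  expect_lt(abs(mean(per_track_gaps(argos)) - 22.4) / 22.4, 0.1)
  # Argos tracks carry the configured class mix, GPS tracks class G
  expect_setequal(unique(gps$tracks$location_class), "G")
  expect_true(all(argos$tracks$location_class %in% c("3", "2", "1", "0", "A", "B", "Z")))
})

test_that("flight-leg displacement variance matches the configured sigma2", {
  # densely sampled, error-free variant; lateral increments estimate sigma2
  lat_var <- function(seed) {
    cfg <- scenario_config(n_individuals = 1, winter_dwell_days = 20,
                           breed_dwell_days = 20, frac_gps = 1,
                           gps_gap_hours = 0.5, gps_error_m = 0.1, rng_seed = seed)
    tr <- simulate_individual(cfg, 1)$truth
    fl <- which(tr$regime %in% c("SPRING_MIG", "FALL_MIG"))
    ok <- fl[which(diff(fl) == 1)]
    dx <- tr$true_x[ok + 1] - tr$true_x[ok]
    dy <- tr$true_y[ok + 1] - tr$true_y[ok]
    dt <- as.numeric(tr$timestamp[ok + 1]) - as.numeric(tr$timestamp[ok])
    hx <- tr$true_x[pmin(ok + 2, nrow(tr))] - tr$true_x[pmax(ok - 2, 1)]
    hy <- tr$true_y[pmin(ok + 2, nrow(tr))] - tr$true_y[pmax(ok - 2, 1)]
    hn <- sqrt(hx^2 + hy^2)
    lateral <- (-dx * hy + dy * hx) / hn
    c(ss = sum(lateral^2), st = sum(dt))
  }
  acc <- rowSums(vapply(1:8, lat_var, numeric(2)))
  est <- acc[["ss"]] / acc[["st"]]
  expect_lt(abs(est - 200) / 200, 0.15)
})

test_that("Brownian track generator matches its nominal moments", {
  fx <- simulate_brownian_track(n = 4001, dt_s = 1800, sigma2 = 12,
                                error_sd = 0, seed = 9)
  est <- (stats::var(diff(fx$x)) + stats::var(diff(fx$y))) / (2 * 1800)
  expect_lt(abs(est - 12) / 12, 0.1)
})

test_that("separated populations produce near-disjoint population UDs", {
  cfg <- scenario_config(n_populations = 2, n_individuals = 2,
                         winter_dwell_days = 30, breed_dwell_days = 30,
                         frac_gps = 1, rng_seed = 17)
  sim <- simulate_cohort(cfg)
  seg <- preprocess_cohort(sim)
  grid <- make_grid(seg, cell_side_km = 20, padding_km = 80)
  ev <- cohort_event_uds(seg, grid)
  fly <- build_flyway(dplyr::select(ev, animal_id, event_id, duration_days, ud),
                      sim$groups)
  pops <- fly[fly$level == "POPULATION", ]
  expect_equal(nrow(pops), 2)
  expect_lt(percent_vi(pops$ud[[1]], pops$ud[[2]]), 5)
})

test_that("the pipeline recovers the true corridor on error-free dense tracks", {
  cfg <- scenario_config(n_individuals = 3, winter_dwell_days = 30,
                         breed_dwell_days = 30, frac_gps = 1,
                         gps_gap_hours = 1, gps_error_m = 0.5,
                         stopovers = list(data.frame(frac = c(0.45, 0.75),
                                                     mean_dwell_days = c(3, 3))),
                         rng_seed = 23)
  sim <- simulate_cohort(cfg)
  seg <- preprocess_cohort(sim, dwell_days = 15, thin_hourly = FALSE)
  grid <- make_grid(seg, cell_side_km = 10, padding_km = 40)
  ev <- cohort_event_uds(seg, grid)
  fly <- build_flyway(dplyr::select(ev, animal_id, event_id, duration_days, ud),
                      sim$groups)
  full <- fly$ud[[which(fly$level == "MULTISPECIES")]]
  # envelope proxy: true positions of all birds, projected onto the UD grid
  center <- grid$center
  tp <- flywayr:::.laea_forward(sim$truth$true_lon, sim$truth$true_lat,
                                center[1], center[2])
  df <- tidy(full)
  near <- vapply(seq_len(nrow(df)), function(i) {
    min((df$x[i] - tp$x)^2 + (df$y[i] - tp$y)^2)
  }, numeric(1))
  frac_near <- sum(df$mass[sqrt(near) <= 2 * grid$cell_side])
  expect_gte(frac_near, 0.95)
})

test_that("event segmentation recovers true boundaries within two fixes", {
  cfg <- scenario_config(n_individuals = 2, winter_dwell_days = 30,
                         breed_dwell_days = 30, frac_gps = 1,
                         gps_gap_hours = 2, gps_error_m = 0.5,
                         stopovers = list(data.frame(frac = c(0.45, 0.75),
                                                     mean_dwell_days = c(3, 3))),
                         rng_seed = 29)
  sim <- simulate_cohort(cfg)
  # no hourly thinning here so fix indices align one-to-one with the truth
  trk <- project_fixes(assign_errors(sim$tracks, error_model()))
  seg <- suppressMessages(segment_migration_events(
    trk, stationary_radius_km = 60, dwell_days = 15))
  ev <- migration_events(seg)
  for (aid in unique(ev$animal_id)) {
    tr <- sim$truth[sim$truth$animal_id == aid, ]
    fx <- seg[seg$animal_id == aid, ]
    truth_idx <- function(regime) range(which(tr$regime == regime))
    for (season in c("SPRING", "FALL")) {
      e <- ev[ev$animal_id == aid & ev$season == season, ]
      expect_equal(nrow(e), 1)
      regime <- if (season == "SPRING") "SPRING_MIG" else "FALL_MIG"
      ti <- truth_idx(regime)
      # detected boundaries in fix indices vs true regime transition indices
      det <- range(which(!is.na(fx$event_id) & fx$event_id == e$event_id))
      expect_lte(abs(det[1] - (ti[1] - 1)), 2)
      expect_lte(abs(det[2] - (ti[2] + 1)), 2)
    }
  }
})

test_that("a 31-bird cohort mirrors a single-population flyway sample", {
  cfg <- scenario_config(n_individuals = 31, winter_dwell_days = 5,
                         breed_dwell_days = 5, frac_gps = 1,
                         gps_gap_hours = 12, rng_seed = 41)
  sim <- simulate_cohort(cfg)
  expect_equal(length(unique(sim$tracks$animal_id)), 31)
  expect_equal(nrow(sim$groups), 31)
  expect_equal(unique(sim$groups$population), "pop_01")
})
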