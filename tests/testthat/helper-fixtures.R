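# fixture builders shared across test files; everything is generated in code

fix_tbl <- function(lon, lat, hours, animal_id = "a1", sensor = "GPS",
                    location_class = "G", t0 = as.POSIXct("2010-01-01", tz = "UTC")) {
  tibble::tibble(
    animal_id = animal_id,
    timestamp = t0 + hours * 3600,
    lon = lon, lat = lat,
    sensor = sensor, location_class = location_class
  )
}

# planar fixes ready for estimate_variances()/compute_ud()
planar_fixes <- function(x, y, t_s, error_sd = 10, animal_id = "a1") {
  tibble::tibble(
    animal_id = animal_id,
    timestamp = as.POSIXct("2010-01-01", tz = "UTC") + t_s,
    x = x, y = y, error_sd = error_sd
  )
}

# a hand-built dbbmm_fit for rasterizer tests (bypasses estimation)
manual_fit <- function(x, y, t_s, sigma2, error_sd, config = dbbmm_config()) {
  n <- length(x)
  segments <- tibble::tibble(
    segment = seq_len(n - 1),
    t0 = t_s[-n], t1 = t_s[-1],
    x0 = x[-n], y0 = y[-n], x1 = x[-1], y1 = y[-1],
    err0 = rep_len(error_sd, n)[-n], err1 = rep_len(error_sd, n)[-1],
    T = diff(t_s),
    sigma2_m = rep_len(sigma2, n - 1),
    n_windows = 1L
  )
  structure(list(segments = segments, windows = tibble::tibble(),
                 config = config, n_fixes = n,
                 animal_id = "manual", event_id = "manual_ev"),
            class = "dbbmm_fit")
}

# uniform UD over an arbitrary set of cells (linear indices into the mass matrix)
uniform_ud <- function(grid, cells) {
  m <- matrix(0, grid$n_rows, grid$n_cols)
  m[cells] <- 1 / length(cells)
  flyway_ud(m, grid)
}

# discrete isotropic Gaussian UD centered on the grid
gaussian_ud <- function(grid, sd_m, cx = NULL, cy = NULL) {
  xc <- grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_side
  yc <- grid$origin_y + (seq_len(grid$n_rows) - 0.5) * grid$cell_side
  if (is.null(cx)) cx <- mean(xc)
  if (is.null(cy)) cy <- mean(yc)
  m <- outer(exp(-(yc - cy)^2 / (2 * sd_m^2)), exp(-(xc - cx)^2 / (2 * sd_m^2)))
  flyway_ud(m / sum(m), grid)
}

small_grid <- function(n = 10, side = 1000) {
  grid_spec(origin_x = 0, origin_y = 0, cell_side = side, n_cols = n, n_rows = n)
}

# random UDs for aggregation/sensitivity property tests
random_ud <- function(grid, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(grid$n_rows * grid$n_cols), grid$n_rows, grid$n_cols)
  flyway_ud(m / sum(m), grid)
}

# small fast scenario used by several pipeline-level tests
fast_scenario <- function(n_individuals = 3, n_populations = 1, frac_gps = 1,
                          rng_seed = 7, ...) {
  scenario_config(
    n_populations = n_populations, n_individuals = n_individuals,
    winter_dwell_days = 30, breed_dwell_days = 30,
    frac_gps = frac_gps, rng_seed = rng_seed, ...
  )
}

# standard preprocessing chain for simulated cohorts
preprocess_cohort <- function(sim, vmax_kmh = 150, stationary_radius_km = 60,
                              dwell_days = 12, thin_hourly = TRUE) {
  # hourly truncation suits Argos-style duty cycles; sub-hourly GPS
  # validation runs keep native timestamps
  trk <- if (thin_hourly) suppressMessages(retain_hourly_best(sim$tracks)) else sim$tracks
  trk <- suppressMessages(suppressWarnings(plausibility_filter(trk, vmax_kmh)))
  trk <- trk[trk$location_class != "Z", , drop = FALSE]
  trk <- assign_errors(trk, error_model())
  trk <- project_fixes(trk)
  seg <- suppressMessages(segment_migration_events(
    trk, stationary_radius_km = stationary_radius_km, dwell_days = dwell_days))
  seg
}

# run events through the dBBMM and return the event-UD table build_flyway() wants
cohort_event_uds <- function(seg, grid, config = dbbmm_config()) {
  ev <- migration_events(seg)
  ev <- ev[ev$complete, , drop = FALSE]
  ev$ud <- purrr::map(ev$event_id, function(e) {
    fx <- event_fixes(seg, e)
    fit <- suppressMessages(estimate_variances(fx, config))
    compute_ud(fit, grid)
  })
  ev
}
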