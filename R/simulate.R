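#' Scenario configuration for the synthetic-track simulator
#'
#' Describes a multi-population migratory system with known ground truth.
#' Each population follows one corridor (a lon/lat polyline from the winter
#' site to the breeding site) with per-individual lateral jitter; birds
#' alternate stationary dwells (winter, stopovers, breeding, optional molt)
#' with directed flight legs. Defaults emulate Asian waterfowl telemetry:
#' mean inter-fix gaps of 4.5 h for GPS and 22.4 h for Argos duty cycles,
#' Argos location-class error from hundreds of meters (class 3) to several
#' kilometers (class B), GPS error 23.5 m, flight speeds around 60 km/h,
#' and a Brownian motion variance contrast of two orders of magnitude
#' between flight (200 m^2/s) and stopover (2 m^2/s) behavior.
#'
#' @param n_populations Number of populations (default 1).
#' @param n_individuals Individuals per population (default 10).
#' @param corridors List of lon/lat waypoint matrices (>= 2 rows), one per
#'   population; first row = winter site, last row = breeding site.
#' @param stopovers List (per population) of data frames with `frac`
#'   (position along the corridor, 0-1) and `mean_dwell_days`.
#' @param flight_speed_kmh Cruise speed during flight legs.
#' @param flight_sigma2,stopover_sigma2 Brownian motion variance (m^2/s)
#'   during flight legs and stationary dwells.
#' @param winter_dwell_days,breed_dwell_days Mean seasonal dwell lengths.
#' @param molt_prob Probability a bird molt-migrates after breeding.
#' @param molt_days,molt_offset_km Molt-cluster dwell and its displacement
#'   from the breeding site.
#' @param frac_gps Fraction of birds carrying GPS (vs Argos) transmitters.
#' @param gps_gap_hours,argos_gap_hours Mean inter-fix gap per sensor.
#' @param gap_shape Gamma shape of the gap distribution (mean fixed above).
#' @param argos_class_freq Named class frequencies for Argos fixes
#'   (B-heavy by default; must sum to 1).
#' @param argos_class_sd_m Named per-class error SDs (meters) used to
#'   corrupt Argos fixes (class Z gets `z_error_m`).
#' @param z_error_m Error SD applied to class-Z (rejected) fixes.
#' @param gps_error_m GPS error SD, meters.
#' @param corridor_jitter_km SD of per-individual lateral waypoint jitter.
#' @param species Character vector of species codes, one per population
#'   (recycled).
#' @param rng_seed Master seed; all randomness derives from it through
#'   per-individual substreams.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(
    n_populations = 1,
    n_individuals = 10,
    corridors = NULL,
    stopovers = NULL,
    flight_speed_kmh = 60,
    flight_sigma2 = 200,
    stopover_sigma2 = 2,
    winter_dwell_days = 60,
    breed_dwell_days = 50,
    molt_prob = 0,
    molt_days = 20,
    molt_offset_km = 150,
    frac_gps = 0.5,
    gps_gap_hours = 4.5,
    argos_gap_hours = 22.4,
    gap_shape = 4,
    argos_class_freq = c("3" = 0.04, "2" = 0.06, "1" = 0.08, "0" = 0.12,
                         "A" = 0.20, "B" = 0.45, "Z" = 0.05),
    argos_class_sd_m = c("3" = 450, "2" = 630, "1" = 1190, "0" = 2580,
                         "A" = 5070, "B" = 7920),
    z_error_m = 15000,
    gps_error_m = 23.5,
    corridor_jitter_km = 30,
    species = "SYNT",
    rng_seed = 1) {
  if (is.null(corridors)) {
    base <- cbind(lon = c(90, 93, 97, 100), lat = c(25, 32, 39, 46))
    corridors <- purrr::map(seq_len(n_populations), function(p) {
      shift <- (p - 1) * 8 # populations offset ~ several hundred km apart
      sweep(base, 2, c(shift, 0), "+")
    })
  }
  if (is.null(stopovers)) {
    stopovers <- purrr::map(seq_len(n_populations), function(p) {
      data.frame(frac = c(0.45, 0.75), mean_dwell_days = c(5, 4))
    })
  }
  if (length(corridors) != n_populations) abort("one corridor per population required")
  for (cw in corridors) {
    if (nrow(cw) < 2) abort("each corridor needs at least 2 waypoints")
  }
  if (abs(sum(argos_class_freq) - 1) > 1e-8) abort("argos_class_freq must sum to 1")
  if (flight_speed_kmh <= 0) abort("flight speed must be positive")
  if (flight_sigma2 <= 0 || stopover_sigma2 <= 0) abort("sigma2 values must be positive")
  structure(list(
    n_populations = n_populations, n_individuals = n_individuals,
    corridors = corridors, stopovers = stopovers,
    flight_speed_kmh = flight_speed_kmh,
    flight_sigma2 = flight_sigma2, stopover_sigma2 = stopover_sigma2,
    winter_dwell_days = winter_dwell_days, breed_dwell_days = breed_dwell_days,
    molt_prob = molt_prob, molt_days = molt_days, molt_offset_km = molt_offset_km,
    frac_gps = frac_gps, gps_gap_hours = gps_gap_hours,
    argos_gap_hours = argos_gap_hours, gap_shape = gap_shape,
    argos_class_freq = argos_class_freq, argos_class_sd_m = argos_class_sd_m,
    z_error_m = z_error_m, gps_error_m = gps_error_m,
    corridor_jitter_km = corridor_jitter_km,
    species = rep_len(species, n_populations),
    rng_seed = as.integer(rng_seed)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %d population(s) x %d individuals, seed %d\n",
              x$n_populations, x$n_individuals, x$rng_seed))
  cat(sprintf("  flight %g m^2/s @ %g km/h; stopover %g m^2/s; GPS share %.0f%%\n",
              x$flight_sigma2, x$flight_speed_kmh, x$stopover_sigma2,
              100 * x$frac_gps))
  invisible(x)
}

# deterministic per-individual substream of the master seed
.substream_seed <- function(rng_seed, animal_index) {
  as.integer((as.numeric(rng_seed) + 104729 * animal_index) %% 2147483647L)
}

#' Simulate one migratory individual
#'
#' Builds a continuous true path on a fine time lattice -- stationary
#' jitter (mean-reverting, intensity `stopover_sigma2`) at the winter site,
#' directed flight along the jittered corridor with Brownian-bridge lateral
#' perturbation of intensity `flight_sigma2`, stopover dwells, breeding
#' dwell, optional molt cluster, and the fall return -- then samples fixes
#' at sensor-specific intervals and corrupts them with per-class Gaussian
#' location error. Ground truth (regime labels, error-free coordinates,
#' true variance) is returned alongside.
#'
#' @param cfg A [scenario_config()].
#' @param animal_index Global 1-based individual index (drives the RNG
#'   substream and population membership).
#' @return List with `track` (observed fix tibble) and `truth` (per-fix
#'   regime, true lon/lat and true sigma2, plus attribute `phases`).
#' @export
simulate_individual <- function(cfg, animal_index = 1) {
  stopifnot(inherits(cfg, "scenario_config"))
  pop <- ((animal_index - 1) %/% cfg$n_individuals) + 1
  if (pop > cfg$n_populations) pop <- ((animal_index - 1) %% cfg$n_populations) + 1
  set.seed(.substream_seed(cfg$rng_seed, animal_index))
  wp_ll <- cfg$corridors[[pop]]
  center <- c(mean(wp_ll[, 1]), mean(wp_ll[, 2]))
  wp <- .laea_forward(wp_ll[, 1], wp_ll[, 2], center[1], center[2])
  wp <- cbind(wp$x, wp$y)
  # per-individual corridor jitter: lateral displacement of interior waypoints
  if (nrow(wp) > 2) {
    for (i in 2:(nrow(wp) - 1)) {
      dirv <- wp[i + 1, ] - wp[i - 1, ]
      nrm <- c(-dirv[2], dirv[1]) / sqrt(sum(dirv^2))
      wp[i, ] <- wp[i, ] + nrm * rnorm(1, 0, cfg$corridor_jitter_km * 1000)
    }
  }
  dt <- 900 # fine lattice step, seconds
  v <- cfg$flight_speed_kmh / 3.6 # m/s
  # route plan: positions along corridor where the bird pauses
  stops <- cfg$stopovers[[pop]]
  seg_len <- sqrt(rowSums((wp[-1, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE])^2))
  cum_len <- c(0, cumsum(seg_len))
  total_len <- cum_len[length(cum_len)]
  point_at <- function(d) {
    d <- max(0, min(d, total_len))
    i <- findInterval(d, cum_len, rightmost.closed = TRUE)
    i <- min(i, length(seg_len))
    f <- (d - cum_len[i]) / seg_len[i]
    wp[i, ] + f * (wp[i + 1, ] - wp[i, ])
  }
  pause_d <- sort(stops$frac) * total_len
  pause_dwell <- pmax(0.5, stats::rexp(nrow(stops), 1 / stops$mean_dwell_days))

  molt <- runif(1) < cfg$molt_prob
  molt_site <- point_at(total_len) +
    c(rnorm(1, cfg$molt_offset_km * 1000, cfg$molt_offset_km * 200),
      rnorm(1, 0, cfg$molt_offset_km * 200))

  # phase plan: list of (type, site or from/to, days)
  plan <- list()
  addp <- function(p) plan[[length(plan) + 1L]] <<- p
  jit <- function(d) max(d * 0.6, d + rnorm(1, 0, d * 0.15))
  addp(list(type = "dwell", regime = "WINTER", site = point_at(0),
            days = jit(cfg$winter_dwell_days)))
  d_from <- 0
  for (i in seq_along(pause_d)) {
    addp(list(type = "flight", regime = "SPRING_MIG",
              from_d = d_from, to_d = pause_d[i]))
    addp(list(type = "dwell", regime = "STOPOVER", site = point_at(pause_d[i]),
              days = pause_dwell[i]))
    d_from <- pause_d[i]
  }
  addp(list(type = "flight", regime = "SPRING_MIG", from_d = d_from, to_d = total_len))
  addp(list(type = "dwell", regime = "BREED", site = point_at(total_len),
            days = jit(cfg$breed_dwell_days)))
  if (molt) {
    addp(list(type = "flight", regime = "FALL_MIG", to_site = molt_site))
    addp(list(type = "dwell", regime = "MOLT", site = molt_site, days = cfg$molt_days))
  }
  # fall return: reverse the corridor with one mid-route stopover
  fall_pause <- if (length(pause_d)) pause_d[ceiling(length(pause_d) / 2)] else NA
  if (molt) {
    addp(list(type = "flight", regime = "FALL_MIG", to_site = point_at(total_len)))
  }
  if (!is.na(fall_pause)) {
    addp(list(type = "flight", regime = "FALL_MIG", from_d = total_len, to_d = fall_pause))
    addp(list(type = "dwell", regime = "STOPOVER", site = point_at(fall_pause),
              days = max(0.5, stats::rexp(1, 1 / mean(stops$mean_dwell_days)))))
    addp(list(type = "flight", regime = "FALL_MIG", from_d = fall_pause, to_d = 0))
  } else {
    addp(list(type = "flight", regime = "FALL_MIG", from_d = total_len, to_d = 0))
  }
  addp(list(type = "dwell", regime = "WINTER", site = point_at(0),
            days = jit(cfg$winter_dwell_days)))

  # phase durations in seconds (flight durations from site-to-site distance)
  prev_site <- point_at(0)
  for (i in seq_along(plan)) {
    ph <- plan[[i]]
    if (ph$type == "dwell") {
      plan[[i]]$dur <- ph$days * 86400
      prev_site <- ph$site
    } else if (!is.null(ph$to_site)) {
      plan[[i]]$dur <- max(dt, sqrt(sum((ph$to_site - prev_site)^2)) / v)
      prev_site <- ph$to_site
    } else {
      plan[[i]]$dur <- max(dt, abs(ph$to_d - ph$from_d) / v)
      prev_site <- point_at(ph$to_d)
    }
  }
  durs <- vapply(plan, `[[`, numeric(1), "dur")
  starts <- cumsum(c(0, durs[-length(durs)]))
  t_total <- sum(durs)

  # sensor assignment and fix times, drawn before rolling the path so the
  # true path can be evaluated exactly at the fix instants
  is_gps <- runif(1) < cfg$frac_gps
  gap_mean_s <- (if (is_gps) cfg$gps_gap_hours else cfg$argos_gap_hours) * 3600
  n_guess <- ceiling(t_total / gap_mean_s * 1.8) + 20
  gaps <- pmax(900, stats::rgamma(n_guess, cfg$gap_shape,
                                  scale = gap_mean_s / cfg$gap_shape))
  fix_t <- cumsum(gaps)
  while (fix_t[length(fix_t)] < t_total) {
    more <- pmax(900, stats::rgamma(n_guess, cfg$gap_shape,
                                    scale = gap_mean_s / cfg$gap_shape))
    fix_t <- c(fix_t, fix_t[length(fix_t)] + cumsum(more))
  }
  fix_t <- fix_t[fix_t < t_total - dt]

  # roll the plan on the union of the fine lattice and the fix instants
  pos <- point_at(0)
  ts <- vector("list", length(plan)); xs <- ts; ys <- ts
  regime <- ts; sig2 <- ts
  theta <- 1 / 21600 # dwell jitter mean-reversion rate (1 / 6 h)
  for (i in seq_along(plan)) {
    ph <- plan[[i]]
    t0p <- starts[i]; t1p <- t0p + ph$dur
    inner <- fix_t[fix_t > t0p & fix_t < t1p]
    tt <- sort(unique(c(seq(t0p, t1p, by = dt), t1p, inner)))
    n_st <- length(tt)
    dts <- diff(tt)
    if (ph$type == "dwell") {
      px <- numeric(n_st); py <- numeric(n_st)
      px[1] <- pos[1]; py[1] <- pos[2]
      sd_st <- sqrt(cfg$stopover_sigma2 * dts)
      for (k in 2:n_st) {
        px[k] <- px[k - 1] + theta * (ph$site[1] - px[k - 1]) * dts[k - 1] +
          rnorm(1, 0, sd_st[k - 1])
        py[k] <- py[k - 1] + theta * (ph$site[2] - py[k - 1]) * dts[k - 1] +
          rnorm(1, 0, sd_st[k - 1])
      }
      s2 <- rep(cfg$stopover_sigma2, n_st)
    } else {
      frac_t <- (tt - t0p) / ph$dur
      if (is.null(ph$to_site)) {
        dd <- ph$from_d + frac_t * (ph$to_d - ph$from_d)
        base <- t(vapply(dd, point_at, numeric(2)))
      } else {
        from <- if (i > 1 && plan[[i - 1]]$type == "dwell") plan[[i - 1]]$site else pos
        base <- cbind(from[1] + frac_t * (ph$to_site[1] - from[1]),
                      from[2] + frac_t * (ph$to_site[2] - from[2]))
      }
      # Brownian bridge perturbation: starts at the current offset, ends on site
      off0 <- pos - base[1, ]
      wx <- c(0, cumsum(rnorm(n_st - 1, 0, sqrt(cfg$flight_sigma2 * dts))))
      wy <- c(0, cumsum(rnorm(n_st - 1, 0, sqrt(cfg$flight_sigma2 * dts))))
      px <- base[, 1] + wx - frac_t * wx[n_st] + (1 - frac_t) * off0[1]
      py <- base[, 2] + wy - frac_t * wy[n_st] + (1 - frac_t) * off0[2]
      s2 <- rep(cfg$flight_sigma2, n_st)
    }
    keep <- if (i == 1) seq_len(n_st) else seq(2L, n_st) # drop shared boundary
    ts[[i]] <- tt[keep]; xs[[i]] <- px[keep]; ys[[i]] <- py[keep]
    regime[[i]] <- rep(ph$regime, length(keep)); sig2[[i]] <- s2[keep]
    pos <- c(px[n_st], py[n_st])
  }
  ts <- unlist(ts); xs <- unlist(xs); ys <- unlist(ys)
  regime <- unlist(regime); sig2 <- unlist(sig2)
  idx <- findInterval(fix_t + 1e-3, ts)
  true_x <- xs[idx]; true_y <- ys[idx]
  fix_regime <- regime[idx]; fix_sig2 <- sig2[idx]
  n_fix <- length(fix_t)
  if (is_gps) {
    lc <- rep("G", n_fix)
    err <- rep(cfg$gps_error_m, n_fix)
    sensor <- "GPS"
  } else {
    lc <- sample(names(cfg$argos_class_freq), n_fix, replace = TRUE,
                 prob = cfg$argos_class_freq)
    err <- ifelse(lc == "Z", cfg$z_error_m, cfg$argos_class_sd_m[lc])
    sensor <- "ARGOS"
  }
  obs_x <- true_x + rnorm(n_fix, 0, err)
  obs_y <- true_y + rnorm(n_fix, 0, err)
  t0 <- as.POSIXct("2010-01-01 00:00:00", tz = "UTC")
  ll_obs <- .laea_inverse(obs_x, obs_y, center[1], center[2])
  ll_true <- .laea_inverse(true_x, true_y, center[1], center[2])
  aid <- sprintf("bird_%03d", animal_index)
  track <- tibble(
    animal_id = aid,
    timestamp = t0 + fix_t,
    lon = ll_obs$lon, lat = ll_obs$lat,
    sensor = sensor, location_class = lc,
    species_code = cfg$species[pop],
    marking_site = sprintf("site_%02d", pop)
  )
  truth <- tibble(
    animal_id = aid,
    timestamp = t0 + fix_t,
    regime = fix_regime,
    true_lon = ll_true$lon, true_lat = ll_true$lat,
    true_x = true_x, true_y = true_y,
    true_sigma2 = fix_sig2
  )
  attr(truth, "center") <- center
  list(track = track, truth = truth)
}

#' Simulate a full multi-population cohort
#'
#' Independent individuals (per-individual RNG substreams of the master
#' seed, so results are bit-identical for a fixed seed) plus the grouping
#' table the aggregation module consumes.
#'
#' @param cfg A [scenario_config()].
#' @return List with `tracks` (all observed fixes), `truth` (all ground
#'   truth) and `groups` (`animal_id`, `population`, `species`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  n_total <- cfg$n_populations * cfg$n_individuals
  sims <- purrr::map(seq_len(n_total), ~ simulate_individual(cfg, .x))
  tracks <- bind_rows(purrr::map(sims, "track"))
  truth <- bind_rows(purrr::map(sims, "truth"))
  groups <- tibble(
    animal_id = sprintf("bird_%03d", seq_len(n_total)),
    population = sprintf("pop_%02d", ((seq_len(n_total) - 1) %/% cfg$n_individuals) + 1),
    species = cfg$species[((seq_len(n_total) - 1) %/% cfg$n_individuals) + 1]
  )
  list(tracks = tracks, truth = truth, groups = groups)
}

#' Simulate a pure Brownian-motion track
#'
#' A planar Brownian motion sampled at `n` regular fixes, with optional
#' per-segment variance switching and Gaussian location error. Used for
#' parameter-recovery checks of the variance estimator.
#'
#' @param n Number of fixes.
#' @param dt_s Sampling interval, seconds.
#' @param sigma2 True Brownian motion variance (m^2/s); scalar or vector
#'   of length `n - 1` (per segment).
#' @param error_sd Location error SD, meters (0 allowed; `error_sd` in the
#'   output is floored at 0.1 m so likelihoods stay proper).
#' @param seed Optional seed.
#' @param animal_id Identifier for the output tibble.
#' @return A projected-fix tibble (`x`, `y`, `timestamp`, `error_sd`)
#'   ready for [estimate_variances()].
#' @export
simulate_brownian_track <- function(n, dt_s = 3600, sigma2 = 20, error_sd = 0,
                                    seed = NULL, animal_id = "sim") {
  if (!is.null(seed)) set.seed(seed)
  s2 <- rep_len(sigma2, n - 1)
  steps_x <- rnorm(n - 1, 0, sqrt(s2 * dt_s))
  steps_y <- rnorm(n - 1, 0, sqrt(s2 * dt_s))
  x <- c(0, cumsum(steps_x))
  y <- c(0, cumsum(steps_y))
  if (error_sd > 0) {
    x <- x + rnorm(n, 0, error_sd)
    y <- y + rnorm(n, 0, error_sd)
  }
  tibble(
    animal_id = animal_id,
    timestamp = as.POSIXct("2010-01-01", tz = "UTC") + dt_s * (seq_len(n) - 1),
    x = x, y = y,
    error_sd = max(error_sd, 0.1),
    true_sigma2 = c(s2, s2[n - 1])
  )
}
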