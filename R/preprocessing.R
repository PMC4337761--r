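#' Location-error model for Argos and GPS fixes
#'
#' One isotropic standard deviation (meters) per Argos location class, plus
#' the GPS error. The class-3 value (450 m) and class-B value (7920 m) are
#' published mean errors for free-ranging waterfowl; the GPS error is
#' 23.5 m. The intermediate class values (2, 1, 0, A) are package defaults
#' interpolating the published endpoints, not published estimates --
#' override them when better calibration data exist. Class Z fixes are
#' rejected locations and carry no usable error; they must be removed by
#' [plausibility_filter()] before error assignment.
#'
#' @param class_sd_m Named numeric vector of per-class SDs in meters for
#'   classes `3,2,1,0,A,B`.
#' @param gps_error_m GPS location error SD in meters.
#' @return An `error_model` object (named list).
#' @export
error_model <- function(class_sd_m = c("3" = 450, "2" = 630, "1" = 1190,
                                       "0" = 2580, "A" = 5070, "B" = 7920),
                        gps_error_m = 23.5) {
  needed <- c("3", "2", "1", "0", "A", "B")
  if (!all(needed %in% names(class_sd_m))) {
    abort("class_sd_m must name all Argos classes 3,2,1,0,A,B")
  }
  if (any(class_sd_m <= 0) || gps_error_m <= 0) abort("error SDs must be positive")
  if (class_sd_m[["3"]] > class_sd_m[["B"]]) {
    abort("quality ordering violated: class-3 SD must not exceed class-B SD")
  }
  structure(list(class_sd_m = class_sd_m[needed], gps_error_m = gps_error_m),
            class = "error_model")
}

#' Keep the highest-quality fix in each hour
#'
#' Retains at most one fix per animal per clock hour: within an hour the
#' best location class wins under the quality ordering
#' `G > 3 > 2 > 1 > 0 > A > B > Z`; a tie keeps the earlier fix. Retained
#' timestamps are truncated to the hour, which regularizes Argos data and
#' bounds downstream model cost. Idempotent.
#'
#' @param fixes A fix tibble.
#' @return The thinned fix tibble, timestamps floored to `hh:00:00`.
#' @export
retain_hourly_best <- function(fixes) {
  if (nrow(fixes) == 0) return(fixes)
  out <- fixes %>%
    mutate(
      .hour = as.POSIXct(floor(as.numeric(.data$timestamp) / 3600) * 3600,
                         origin = "1970-01-01", tz = "UTC"),
      .rank = .lc_rank(.data$location_class)
    ) %>%
    arrange(.data$animal_id, .data$.hour, .data$.rank, .data$timestamp) %>%
    group_by(.data$animal_id, .data$.hour) %>%
    slice(1L) %>%
    ungroup() %>%
    mutate(timestamp = .data$.hour) %>%
    select(-".hour", -".rank") %>%
    arrange(.data$animal_id, .data$timestamp)
  .keep_proj(out, fixes)
}

#' Assign per-fix location error
#'
#' Fills `error_sd` (meters, one isotropic SD) from the [error_model()]:
#' GPS fixes get `gps_error_m`, Argos fixes the SD of their location class.
#' Coordinates and fix order are untouched. Class-Z fixes are an error here:
#' they are rejected locations and must be removed first.
#'
#' @param fixes A fix tibble.
#' @param model An [error_model()].
#' @return `fixes` with `error_sd` filled.
#' @export
assign_errors <- function(fixes, model = error_model()) {
  if (!inherits(model, "error_model")) abort("model must be an error_model")
  if (nrow(fixes) == 0) return(dplyr::mutate(fixes, error_sd = numeric(0)))
  lc <- as.character(fixes$location_class)
  if (any(lc == "Z")) {
    abort("class-Z fixes present; run plausibility_filter() first (Z fixes are rejected locations)")
  }
  is_gps <- fixes$sensor == "GPS" | lc == "G"
  sd <- ifelse(is_gps, model$gps_error_m, unname(model$class_sd_m[lc]))
  if (anyNA(sd)) {
    abort(paste0("unknown location class: ",
                 paste(unique(lc[is.na(sd)]), collapse = ", ")))
  }
  fixes$error_sd <- sd
  fixes
}

#' Speed-plausibility filter
#'
#' A simplified sustained-speed filter standing in for published Argos
#' pre-filtering algorithms (which are external software and out of scope
#' here): class-Z fixes are removed unconditionally, then while any
#' inter-fix speed exceeds `vmax_kmh` the fix whose removal most reduces
#' the maximum implied speed is dropped. The result is guaranteed to have
#' all inter-fix speeds at or below `vmax_kmh`. Removal counts are reported
#' via attribute `n_removed` and a message; a track losing more than half
#' its fixes triggers a warning flagging it for review.
#'
#' Speeds are geodesic (WGS84) over lon/lat, so the filter can run before
#' projection.
#'
#' @param fixes A fix tibble (may contain several animals).
#' @param vmax_kmh Maximum plausible sustained speed, km/h (default 120).
#' @return Filtered fix tibble with attribute `n_removed`.
#' @export
plausibility_filter <- function(fixes, vmax_kmh = 120) {
  if (nrow(fixes) == 0) return(fixes)
  n_in <- nrow(fixes)
  pieces <- fixes %>%
    arrange(.data$animal_id, .data$timestamp) %>%
    group_split(.data$animal_id)
  out <- purrr::map(pieces, .filter_one_track, vmax_kmh = vmax_kmh)
  res <- bind_rows(out)
  n_removed <- n_in - nrow(res)
  if (n_removed > 0) {
    inform(paste0("plausibility_filter removed ", n_removed, " of ", n_in, " fixes"))
  }
  attr(res, "n_removed") <- n_removed
  .keep_proj(res, fixes)
}

.filter_one_track <- function(trk, vmax_kmh) {
  keep_z <- trk$location_class != "Z"
  if (!all(keep_z)) {
    trk <- trk[keep_z, , drop = FALSE]
  }
  n0 <- nrow(trk)
  if (n0 == 0) {
    warn("track is empty after removing class-Z fixes")
    return(trk)
  }
  speeds <- .track_speeds_kmh(trk)
  while (length(speeds) > 0 && max(speeds) > vmax_kmh && nrow(trk) > 2) {
    i <- which.max(speeds) # segment i connects fixes i and i+1
    cand <- unique(pmin(pmax(c(i, i + 1L), 1L), nrow(trk)))
    best_max <- Inf; best_j <- cand[1]
    for (j in cand) {
      sp <- .track_speeds_kmh(trk[-j, , drop = FALSE])
      m <- if (length(sp)) max(sp) else 0
      if (m < best_max) { best_max <- m; best_j <- j }
    }
    trk <- trk[-best_j, , drop = FALSE]
    speeds <- .track_speeds_kmh(trk)
  }
  if (nrow(trk) < n0 / 2 && n0 >= 4) {
    warn(paste0("track ", trk$animal_id[1], ": more than 50% of fixes removed; flag for review"))
  }
  trk
}

.track_speeds_kmh <- function(trk) {
  n <- nrow(trk)
  if (n < 2) return(numeric(0))
  d_m <- geosphere::distGeo(cbind(trk$lon[-n], trk$lat[-n]),
                            cbind(trk$lon[-1], trk$lat[-1]))
  dt_h <- diff(as.numeric(trk$timestamp)) / 3600
  dt_h[dt_h <= 0] <- 1e-9
  (d_m / 1000) / dt_h
}

#' Segment a track into full migration events
#'
#' Splits a track into stationary seasonal ranges and the migration events
#' between them. A stationary range is a maximal run of fixes that stays
#' within `stationary_radius_km` of its running centroid for at least
#' `dwell_days`. Fixes between departure from one range and arrival at the
#' next form a migration event; an event is `complete` only when its two
#' flanking ranges are geographically distinct areas (centroids separated
#' by more than twice the stationary radius), i.e. the bird spanned the
#' full distance between seasonal ranges. Travel that loops back to the
#' same range yields no complete event.
#'
#' A middle stationary range is treated as a molt/staging cluster -- travel
#' to and from it stays inside the surrounding event while the
#' within-cluster fixes are excluded -- when it dwells less than
#' `molt_max_days` and lies close to the preceding seasonal range relative
#' to the span between its two neighbors (under a third of it), matching
#' post-breeding molt movements to nearby wetlands. Other middle ranges are
#' seasonal endpoints.
#'
#' Events are labeled `SPRING` when the arrival range lies poleward (higher
#' latitude) of the departure range, else `FALL`. `duration_days` is the
#' fractional elapsed time from the event's first to last fix, floored at
#' 0.01 d so sub-day events keep a positive weight.
#'
#' @param fixes A filtered, error-assigned fix tibble for one or more
#'   animals.
#' @param stationary_radius_km Radius defining "staying put" (default 50).
#' @param dwell_days Minimum dwell to call a run a stationary range
#'   (default 21; brief stopovers of a few days stay inside events).
#' @param molt_max_days Middle ranges dwelling less than this are molt
#'   clusters rather than seasonal endpoints (default 45).
#' @return The input tibble with columns `stage` (`"RANGE"`, `"MOLT"`,
#'   `"MIGRATION"`), `event_id` (NA outside events) and `range_id`;
#'   per-event metadata via [migration_events()].
#' @export
segment_migration_events <- function(fixes, stationary_radius_km = 50,
                                     dwell_days = 21, molt_max_days = 45) {
  pieces <- fixes %>%
    arrange(.data$animal_id, .data$timestamp) %>%
    group_split(.data$animal_id)
  out <- purrr::map(pieces, .segment_one, radius_km = stationary_radius_km,
                    dwell_days = dwell_days, molt_max_days = molt_max_days)
  res <- bind_rows(purrr::map(out, "fixes"))
  attr(res, "events") <- bind_rows(purrr::map(out, "events"))
  .keep_proj(res, fixes)
}

# run-based stationary-range detection for a single animal
.segment_one <- function(trk, radius_km, dwell_days, molt_max_days) {
  n <- nrow(trk)
  trk$stage <- "MIGRATION"
  trk$event_id <- NA_character_
  trk$range_id <- NA_integer_
  ev_meta <- tibble(animal_id = character(0), event_id = character(0),
                    season = character(0), complete = logical(0))
  if (n < 2) {
    if (n > 0) inform(paste0("track ", trk$animal_id[1], ": too few fixes to segment"))
    return(list(fixes = trk, events = ev_meta))
  }
  lon <- trk$lon; lat <- trk$lat
  t_days <- as.numeric(trk$timestamp) / 86400
  run_id <- integer(n)
  cur <- 1L; start <- 1L
  c_lon <- lon[1]; c_lat <- lat[1]
  run_id[1] <- cur
  for (i in 2:n) {
    d_km <- geosphere::distGeo(c(c_lon, c_lat), c(lon[i], lat[i])) / 1000
    if (d_km <= radius_km) {
      k <- i - start + 1L
      c_lon <- c_lon + (lon[i] - c_lon) / k
      c_lat <- c_lat + (lat[i] - c_lat) / k
    } else {
      cur <- cur + 1L; start <- i
      c_lon <- lon[i]; c_lat <- lat[i]
    }
    run_id[i] <- cur
  }
  runs <- tibble(run = run_id, lon = lon, lat = lat, t = t_days) %>%
    group_by(.data$run) %>%
    summarise(first = min(.data$t), last = max(.data$t),
              lon = mean(.data$lon), lat = mean(.data$lat), .groups = "drop") %>%
    mutate(dwell = .data$last - .data$first)
  stat <- runs[runs$dwell >= dwell_days, , drop = FALSE]
  if (nrow(stat) == 0) {
    inform(paste0("track ", trk$animal_id[1],
                  ": no stationary seasonal ranges detected; no events returned"))
    return(list(fixes = trk, events = ev_meta))
  }
  n_stat <- nrow(stat)
  # A middle range is a molt/staging cluster only when it dwells briefly AND
  # sits near the preceding seasonal range relative to the span between its
  # neighbors (molt sites lie near the breeding area, not mid-corridor).
  stat$role <- "SEASONAL"
  if (n_stat > 2) {
    for (r in seq(2L, n_stat - 1L)) {
      d_prev <- geosphere::distGeo(c(stat$lon[r - 1], stat$lat[r - 1]),
                                   c(stat$lon[r], stat$lat[r])) / 1000
      d_span <- geosphere::distGeo(c(stat$lon[r - 1], stat$lat[r - 1]),
                                   c(stat$lon[r + 1], stat$lat[r + 1])) / 1000
      if (stat$dwell[r] < molt_max_days && d_prev < 0.33 * max(d_span, 1e-9)) {
        stat$role[r] <- "MOLT"
      }
    }
  }
  for (r in seq_len(n_stat)) {
    idx <- run_id == stat$run[r]
    trk$stage[idx] <- if (stat$role[r] == "MOLT") "MOLT" else "RANGE"
    trk$range_id[idx] <- r
  }
  seas <- which(stat$role == "SEASONAL")
  ev <- 0L
  if (length(seas) >= 2) {
    for (s in seq_len(length(seas) - 1L)) {
      a <- seas[s]; b <- seas[s + 1L]
      sep_km <- geosphere::distGeo(c(stat$lon[a], stat$lat[a]),
                                   c(stat$lon[b], stat$lat[b])) / 1000
      dep <- max(which(run_id == stat$run[a])) # last fix in departure range
      arr <- min(which(run_id == stat$run[b])) # first fix in arrival range
      if (arr <= dep) next
      ev <- ev + 1L
      idx <- seq(dep, arr)
      idx <- idx[trk$stage[idx] != "MOLT"] # travel kept, molt-cluster fixes excluded
      id <- paste0(trk$animal_id[1], "_ev", ev)
      trk$event_id[idx] <- id
      complete <- sep_km > 2 * radius_km
      season <- if (stat$lat[b] > stat$lat[a]) "SPRING" else "FALL"
      ev_meta <- bind_rows(ev_meta,
                           tibble(animal_id = trk$animal_id[1], event_id = id,
                                  season = season, complete = complete))
    }
  }
  list(fixes = trk, events = ev_meta)
}

#' Summarise migration events
#'
#' One row per detected migration event with season, completeness and
#' fractional duration in days (first to last fix, floored at 0.01 d).
#'
#' @param segmented Output of [segment_migration_events()].
#' @return A tibble: `animal_id`, `event_id`, `season`, `complete`,
#'   `n_fixes`, `start`, `end`, `duration_days`.
#' @export
migration_events <- function(segmented) {
  meta <- attr(segmented, "events")
  empty <- tibble(animal_id = character(0), event_id = character(0),
                  season = character(0), complete = logical(0),
                  n_fixes = integer(0),
                  start = as.POSIXct(character(0), tz = "UTC"),
                  end = as.POSIXct(character(0), tz = "UTC"),
                  duration_days = numeric(0))
  if (all(is.na(segmented$event_id))) return(empty)
  ev <- segmented %>%
    filter(!is.na(.data$event_id)) %>%
    group_by(.data$animal_id, .data$event_id) %>%
    summarise(n_fixes = dplyr::n(), start = min(.data$timestamp),
              end = max(.data$timestamp), .groups = "drop") %>%
    mutate(duration_days = pmax(as.numeric(.data$end) - as.numeric(.data$start),
                                0.01 * 86400) / 86400)
  if (!is.null(meta)) {
    ev <- left_join(ev, as_tibble(meta), by = c("animal_id", "event_id"))
  } else {
    ev$season <- character(0); ev$complete <- logical(0)
  }
  ev[, c("animal_id", "event_id", "season", "complete", "n_fixes",
         "start", "end", "duration_days")]
}

#' Extract the fixes of one migration event
#'
#' @param segmented Output of [segment_migration_events()].
#' @param event_id Event identifier from [migration_events()].
#' @return Time-ordered fix tibble of that event.
#' @export
event_fixes <- function(segmented, event_id) {
  out <- segmented %>%
    filter(.data$event_id == !!event_id) %>%
    arrange(.data$timestamp)
  if (nrow(out) == 0) abort(paste0("no fixes for event ", event_id))
  .keep_proj(out, segmented)
}
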