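#' Duration-weighted aggregation of utilization distributions
#'
#' Sums child UDs cell by cell after multiplying each by its weight in
#' days (migration-event duration, or mean event duration at the higher
#' levels), then re-scales the cumulative cell values to sum to 1. The
#' result is invariant to rescaling all weights by a common factor.
#'
#' @param uds List of [flyway_ud] objects sharing one grid.
#' @param weight_days Positive weights, one per child.
#' @param level Level label stored in the result's metadata.
#' @param meta Extra metadata entries.
#' @return A [flyway_ud].
#' @export
aggregate_uds <- function(uds, weight_days, level = "AGGREGATE", meta = list()) {
  if (length(uds) == 0) abort("need at least one child UD")
  if (length(weight_days) != length(uds)) abort("one weight per child UD required")
  if (any(!is.finite(weight_days)) || any(weight_days <= 0)) {
    abort("weights must be positive and finite")
  }
  g <- uds[[1]]$grid
  for (u in uds) {
    if (!inherits(u, "flyway_ud")) abort("children must be flyway_ud objects")
    if (!grid_identical(u$grid, g)) {
      abort("all child UDs must share one identical grid_spec")
    }
  }
  mass <- Reduce(`+`, purrr::map2(uds, weight_days, ~ .x$mass * .y))
  mass <- mass / sum(mass)
  flyway_ud(mass, g, meta = c(list(level = level,
                                   n_children = length(uds),
                                   weight_days = as.numeric(weight_days)),
                              meta))
}

#' Build the flyway hierarchy of utilization distributions
#'
#' Applies the duration-weighted aggregation recursively: event UDs roll up
#' to individual routes (weights = event durations), individuals to
#' populations (weights = each bird's total migration days), populations to
#' species and species to the multi-species flyway (weights = the child's
#' mean migration-event duration). Seasons are pooled throughout: spring
#' and fall events of one bird enter the same individual route.
#'
#' @param event_uds A tibble with columns `animal_id`, `event_id`,
#'   `duration_days` and `ud` (list-column of event [flyway_ud]s).
#' @param groups Grouping table with columns `animal_id`, `population`,
#'   `species` (population membership is an input, typically marking-site
#'   proximity, never inferred).
#' @return A tibble with one row per node: `level`, `name`, `ud`
#'   (list-column), `n_events`, `total_days`, `mean_event_days`.
#' @export
build_flyway <- function(event_uds, groups) {
  need <- c("animal_id", "event_id", "duration_days", "ud")
  if (!all(need %in% names(event_uds))) {
    abort(paste0("event_uds must have columns: ", paste(need, collapse = ", ")))
  }
  missing <- setdiff(unique(event_uds$animal_id), groups$animal_id)
  if (length(missing) > 0) {
    abort(paste0("animal(s) missing from grouping table: ",
                 paste(missing, collapse = ", ")))
  }
  ev <- left_join(event_uds, groups, by = "animal_id")

  roll_up <- function(df, key, child_weight, level) {
    df %>%
      group_by(.data[[key]]) %>%
      summarise(
        ud = list(aggregate_uds(.data$ud, .data[[child_weight]], level = level,
                                meta = list(name = .data[[key]][1]))),
        n_events = sum(.data$n_events),
        total_days = sum(.data$total_days),
        .groups = "drop"
      ) %>%
      mutate(mean_event_days = .data$total_days / .data$n_events) %>%
      rename(name = !!key)
  }

  ev2 <- ev %>% mutate(n_events = 1L, total_days = .data$duration_days)
  ind <- ev2 %>%
    group_by(.data$animal_id, .data$population, .data$species) %>%
    summarise(
      ud = list(aggregate_uds(.data$ud, .data$duration_days, level = "INDIVIDUAL",
                              meta = list(name = .data$animal_id[1]))),
      n_events = dplyr::n(),
      total_days = sum(.data$duration_days),
      .groups = "drop"
    ) %>%
    mutate(mean_event_days = .data$total_days / .data$n_events)
  pop <- roll_up(ind, "population", "total_days", "POPULATION")
  pop$species <- ind$species[match(pop$name, ind$population)]
  spp <- roll_up(pop, "species", "mean_event_days", "SPECIES")
  all_lvl <- spp %>% mutate(flyway = "FLYWAY")
  fly <- roll_up(all_lvl, "flyway", "mean_event_days", "MULTISPECIES")

  bind_rows(
    ind %>% mutate(level = "INDIVIDUAL") %>% rename(name = "animal_id") %>%
      select("level", "name", "ud", "n_events", "total_days", "mean_event_days"),
    pop %>% mutate(level = "POPULATION") %>%
      select("level", "name", "ud", "n_events", "total_days", "mean_event_days"),
    spp %>% mutate(level = "SPECIES") %>%
      select("level", "name", "ud", "n_events", "total_days", "mean_event_days"),
    fly %>% mutate(level = "MULTISPECIES") %>%
      select("level", "name", "ud", "n_events", "total_days", "mean_event_days")
  )
}

#' Cumulative probability contours of a UD
#'
#' For each level `q`, selects the shortest prefix of cells (sorted by mass
#' descending, ties broken by row-major cell index) whose cumulative mass
#' reaches `q/100`, and polygonizes the union of the selected cells on the
#' analysis lattice. Regions are nested by construction. The three-way zone
#' interpretation follows waterfowl flyway practice: mass inside the 50%
#' contour marks stopover sites (multi-day resting and feeding), 50-75%
#' core movement areas with short flights and frequent stops, 75-99%
#' flight corridors with minimal stops.
#'
#' @param ud A [flyway_ud].
#' @param levels Contour percentages in (0, 100); default `c(50, 75, 99)`.
#' @return A `contour_set`: summary tibble (`$levels`), cell masks
#'   (`$masks`), boundary polygons in planar meters (`$polygons`), and the
#'   grid. See [write_contours_geojson()], [autoplot.contour_set()].
#' @export
contour_set <- function(ud, levels = c(50, 75, 99)) {
  stopifnot(inherits(ud, "flyway_ud"))
  if (any(levels <= 0 | levels >= 100)) abort("contour levels must lie in (0, 100)")
  levels <- sort(levels)
  g <- ud$grid
  m <- ud$mass
  # row-major index for deterministic tie-breaking (cells stored column-major)
  i <- seq_along(m)
  rm_index <- (((i - 1L) %% g$n_rows)) * g$n_cols + ((i - 1L) %/% g$n_rows) + 1L
  v <- as.vector(m)
  ord <- order(-v, rm_index)
  cum <- cumsum(v[ord])
  zones <- c("50" = "STOPOVER", "75" = "CORE", "99" = "CORRIDOR")
  masks <- list(); polys <- list(); rows <- list()
  for (q in levels) {
    k <- which(cum >= q / 100 - 1e-12)[1]
    if (is.na(k)) k <- length(ord)
    sel <- ord[seq_len(k)]
    mask <- matrix(FALSE, g$n_rows, g$n_cols)
    mask[sel] <- TRUE
    key <- as.character(q)
    masks[[key]] <- mask
    polys[[key]] <- .polygonize_mask(mask, g)
    rows[[key]] <- tibble(
      level = q,
      zone = if (key %in% names(zones)) zones[[key]] else NA_character_,
      n_cells = k,
      area_km2 = k * (g$cell_side / 1000)^2,
      enclosed_mass = cum[k]
    )
  }
  structure(list(levels = bind_rows(rows), masks = masks, polygons = polys,
                 grid = g, meta = ud$meta),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat("<contour_set>\n")
  print(x$levels)
  invisible(x)
}

#' @method tidy contour_set
#' @export
tidy.contour_set <- function(x, ...) x$levels

# Trace the boundary of a cell mask into closed rings, interior kept on the
# left of travel (outer rings counter-clockwise, holes clockwise). Vertices
# are lattice corners in planar meters.
.polygonize_mask <- function(mask, grid) {
  nr <- nrow(mask); nc <- ncol(mask)
  cells <- which(mask, arr.ind = TRUE)
  if (nrow(cells) == 0) return(list())
  has <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    res <- logical(length(r))
    res[ok] <- mask[cbind(r[ok], c[ok])]
    res
  }
  r <- cells[, 1]; c <- cells[, 2]
  edges <- list()
  add <- function(fr_x, fr_y, to_x, to_y, take) {
    if (!any(take)) return()
    edges[[length(edges) + 1L]] <<- cbind(fr_x[take], fr_y[take], to_x[take], to_y[take])
  }
  south <- !has(r - 1L, c); add(c - 1L, r - 1L, c, r - 1L, south)
  east <- !has(r, c + 1L); add(c, r - 1L, c, r, east)
  north <- !has(r + 1L, c); add(c, r, c - 1L, r, north)
  west <- !has(r, c - 1L); add(c - 1L, r, c - 1L, r - 1L, west)
  E <- do.call(rbind, edges)
  key <- function(x, y) paste(x, y)
  from_key <- key(E[, 1], E[, 2])
  lookup <- split(seq_len(nrow(E)), from_key)
  used <- logical(nrow(E))
  rings <- list()
  for (e0 in seq_len(nrow(E))) {
    if (used[e0]) next
    ring_x <- E[e0, 1]; ring_y <- E[e0, 2]
    cur <- e0
    repeat {
      used[cur] <- TRUE
      cx <- E[cur, 3]; cy <- E[cur, 4]
      ring_x <- c(ring_x, cx); ring_y <- c(ring_y, cy)
      if (cx == ring_x[1] && cy == ring_y[1]) break # ring closed
      nxt_all <- lookup[[key(cx, cy)]]
      nxt_all <- nxt_all[!used[nxt_all]]
      if (length(nxt_all) == 0) break
      if (length(nxt_all) > 1) {
        # diagonal-touch corner: turn left (keep interior on the left)
        din <- c(E[cur, 3] - E[cur, 1], E[cur, 4] - E[cur, 2])
        cross <- vapply(nxt_all, function(e) {
          dout <- c(E[e, 3] - E[e, 1], E[e, 4] - E[e, 2])
          din[1] * dout[2] - din[2] * dout[1]
        }, numeric(1))
        nxt_all <- nxt_all[order(-cross)]
      }
      cur <- nxt_all[1]
    }
    rings[[length(rings) + 1L]] <- cbind(
      x = grid$origin_x + ring_x * grid$cell_side,
      y = grid$origin_y + ring_y * grid$cell_side
    )
  }
  rings
}

.ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]); n <- n + 1 }
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Plot a contour set
#'
#' @param object A `contour_set`.
#' @param ... Unused.
#' @return A ggplot with one layer per contour level, darkest innermost.
#' @method autoplot contour_set
#' @export
autoplot.contour_set <- function(object, ...) {
  dfs <- purrr::imap(object$polygons, function(rings, lev) {
    purrr::imap(rings, function(rg, i) {
      tibble(x = rg[, 1] / 1000, y = rg[, 2] / 1000,
             ring = paste0(lev, "_", i), level = lev)
    }) %>% bind_rows()
  }) %>% bind_rows()
  dfs$level <- factor(dfs$level, levels = rev(names(object$polygons)))
  ggplot2::ggplot(dfs, ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$ring, fill = .data$level)) +
    ggplot2::geom_polygon(color = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_brewer(palette = "YlOrRd", direction = -1,
                               name = "contour (%)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "east (km)", y = "north (km)") +
    ggplot2::theme_minimal()
}

#' Write contours as GeoJSON (WGS84)
#'
#' Each contour level becomes one MultiPolygon feature with properties
#' `level`, `zone` and `enclosed_mass`. Ring coordinates are
#' inverse-projected from the analysis plane to lon/lat.
#'
#' @param cs A `contour_set`.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_contours_geojson <- function(cs, path) {
  center <- cs$grid$center
  if (anyNA(center)) abort("grid has no projection center; cannot export to WGS84")
  features <- purrr::map(seq_len(nrow(cs$levels)), function(i) {
    lev <- as.character(cs$levels$level[i])
    rings <- cs$polygons[[lev]]
    areas <- vapply(rings, .ring_area, numeric(1))
    outers <- which(areas > 0)
    holes <- which(areas <= 0)
    to_ll <- function(rg) {
      ll <- unproject_xy(rg[, 1], rg[, 2], center)
      m <- cbind(ll$lon, ll$lat)
      if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
      lapply(seq_len(nrow(m)), function(k) c(m[k, 1], m[k, 2]))
    }
    polys <- purrr::map(outers, function(o) {
      ring_list <- list(to_ll(rings[[o]]))
      for (h in holes) {
        pt <- rings[[h]][1, ]
        if (.point_in_ring(pt, rings[[o]])) {
          ring_list[[length(ring_list) + 1L]] <- to_ll(rings[[h]])
        }
      }
      ring_list
    })
    list(
      type = "Feature",
      properties = list(level = cs$levels$level[i],
                        zone = cs$levels$zone[i],
                        enclosed_mass = cs$levels$enclosed_mass[i]),
      geometry = list(type = "MultiPolygon", coordinates = polys)
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

.point_in_ring <- function(pt, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- n; inside <- FALSE
  for (i in seq_len(n)) {
    if (((y[i] > pt[2]) != (y[j] > pt[2])) &&
        (pt[1] < (x[j] - x[i]) * (pt[2] - y[i]) / (y[j] - y[i]) + x[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}
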