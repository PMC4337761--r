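#' Read telemetry tracks from a Movebank-style CSV
#'
#' Reads one fix per row and returns a time-ordered fix table grouped by
#' animal. Required columns are `animal_id`, `timestamp` (UTC), `lon`, `lat`,
#' `sensor` (`"ARGOS"` or `"GPS"`) and `location_class` (`3,2,1,0,A,B,Z` for
#' Argos, `G` for GPS); `species_code` and `marking_site` are carried through
#' when present. Column names in other dialects can be remapped via
#' `col_map`, e.g. `c(animal_id = "individual-local-identifier")`.
#'
#' Malformed rows (unparseable timestamp or coordinates out of range) are
#' dropped, counted, and reported via a message and the `n_malformed`
#' attribute -- never silently.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector mapping required names to
#'   the file's column names.
#' @return A tibble of fixes, one row per fix, sorted by `animal_id` then
#'   `timestamp`, with attribute `n_malformed`.
#' @seealso [write_tracks()], [project_fixes()]
#' @export
read_tracks <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[std]]] <- std
      }
    }
  }
  required <- c("animal_id", "timestamp", "lon", "lat", "sensor", "location_class")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  raw$.row <- seq_len(nrow(raw))
  ts <- raw$timestamp
  if (!inherits(ts, "POSIXct")) {
    ts <- .parse_timestamps(as.character(ts))
  }
  attr(ts, "tzone") <- "UTC"
  bad_ts <- is.na(ts)
  if (any(bad_ts)) {
    inform(paste0("dropped ", sum(bad_ts), " row(s) with unparseable timestamp (lines ",
                  paste(head(raw$.row[bad_ts], 10L), collapse = ", "), ")"))
  }
  raw$timestamp <- ts
  bad_coord <- !is.finite(raw$lon) | !is.finite(raw$lat) |
    raw$lat < -90 | raw$lat > 90 | raw$lon <= -180 | raw$lon > 180
  bad_coord[is.na(bad_coord)] <- TRUE
  if (any(bad_coord & !bad_ts)) {
    inform(paste0("dropped ", sum(bad_coord & !bad_ts),
                  " row(s) with out-of-range coordinates"))
  }
  keep <- !bad_ts & !bad_coord
  fixes <- raw[keep, , drop = FALSE]
  fixes$.row <- NULL
  fixes <- as_tibble(fixes) %>%
    mutate(
      animal_id = as.character(.data$animal_id),
      sensor = toupper(as.character(.data$sensor)),
      location_class = toupper(as.character(.data$location_class))
    ) %>%
    arrange(.data$animal_id, .data$timestamp)
  attr(fixes, "n_malformed") <- sum(!keep)
  fixes
}

#' Write telemetry fixes to CSV
#'
#' Inverse of [read_tracks()]: `read_tracks(write_tracks(fixes, f))` returns
#' the same fix sequence.
#'
#' @param fixes A fix tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# parse timestamps element-wise: unparseable entries become NA instead of
# failing the whole read
.parse_timestamps <- function(x) {
  formats <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
               "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in formats) {
    idx <- which(is.na(out) & !is.na(x))
    if (length(idx) == 0) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"))
  }
  out
}

# Spherical Lambert azimuthal equal-area projection. Equal-area so that
# probability mass per grid cell keeps its areal meaning.
.earth_radius <- 6371008.8

.laea_forward <- function(lon, lat, lon0, lat0) {
  lam <- (lon - lon0) * pi / 180
  phi <- lat * pi / 180
  phi0 <- lat0 * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  k <- sqrt(2 / denom)
  list(
    x = .earth_radius * k * cos(phi) * sin(lam),
    y = .earth_radius * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam))
  )
}

.laea_inverse <- function(x, y, lon0, lat0) {
  phi0 <- lat0 * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- 2 * asin(pmin(1, rho / (2 * .earth_radius)))
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cos(c_ang) * sin(phi0) + y * sin(c_ang) * cos(phi0) / rho))
  lam <- ifelse(rho < 1e-12, 0,
                atan2(x * sin(c_ang),
                      rho * cos(phi0) * cos(c_ang) - y * sin(c_ang) * sin(phi0)))
  list(lon = lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}

#' Project fixes to planar coordinates
#'
#' Fills `x`, `y` (meters) using an azimuthal equal-area projection centered
#' on the centroid of all fixes (or an explicit `center`). The equal-area
#' property keeps grid-cell probability mass proportional to true ground
#' area. The projection center is recorded in attributes `proj_lon0` /
#' `proj_lat0` so the inverse ([unproject_xy()]) is available downstream.
#'
#' @param fixes A fix tibble with `lon`, `lat`.
#' @param center Optional `c(lon0, lat0)`; defaults to the data centroid.
#' @return `fixes` with `x` and `y` columns filled.
#' @export
project_fixes <- function(fixes, center = NULL) {
  if (nrow(fixes) == 0) abort("no fixes to project")
  span <- diff(range(fixes$lon))
  if (span > 170) {
    abort("fixes span more than 170 degrees of longitude; split the data per flyway before projecting")
  }
  if (is.null(center)) {
    center <- c(mean(fixes$lon), mean(fixes$lat))
  }
  xy <- .laea_forward(fixes$lon, fixes$lat, center[1], center[2])
  fixes$x <- xy$x
  fixes$y <- xy$y
  attr(fixes, "proj_lon0") <- center[1]
  attr(fixes, "proj_lat0") <- center[2]
  fixes
}

#' Invert the planar projection
#'
#' @param x,y Planar coordinates in meters.
#' @param center `c(lon0, lat0)` of the projection (as stored by
#'   [project_fixes()] or in a [grid_spec()]).
#' @return A tibble with `lon`, `lat`.
#' @export
unproject_xy <- function(x, y, center) {
  ll <- .laea_inverse(x, y, center[1], center[2])
  tibble(lon = ll$lon, lat = ll$lat)
}

#' Define the shared analysis grid
#'
#' Builds the single planar grid on which every utilization distribution of
#' an analysis is rasterized (all UDs must share one grid so they can be
#' summed and compared cell by cell). The default cell area of 10 km^2 gives
#' a square cell side of `sqrt(10)` km (about 3162.3 m); set
#' `cell_side_km` instead to force a given side length (e.g. 10 km cells
#' under the alternative reading of a "10 km^2 resolution").
#'
#' Padding defaults to `max(20 km, 4 x the largest location error SD)` so
#' that bridge and error mass near the data hull stays on the grid.
#'
#' @param fixes A projected fix tibble (see [project_fixes()]).
#' @param cell_area_km2 Cell area in km^2 (default 10).
#' @param cell_side_km Optional explicit cell side in km; overrides
#'   `cell_area_km2`.
#' @param padding_km Padding added on every side, in km. Default as above.
#' @return A `grid_spec` object.
#' @export
make_grid <- function(fixes, cell_area_km2 = 10, cell_side_km = NULL,
                      padding_km = NULL) {
  if (nrow(fixes) == 0) abort("cannot build a grid from zero fixes")
  if (is.null(fixes[["x"]]) || anyNA(fixes[["x"]])) {
    abort("fixes must be projected first (see project_fixes())")
  }
  side <- if (!is.null(cell_side_km)) cell_side_km * 1000 else sqrt(cell_area_km2) * 1000
  if (side <= 0) abort("cell side must be positive")
  if (is.null(padding_km)) {
    err <- fixes[["error_sd"]]
    max_err <- if (!is.null(err) && any(is.finite(err))) {
      max(err, na.rm = TRUE)
    } else 0
    padding_km <- max(20, 4 * max_err / 1000)
  }
  pad <- padding_km * 1000
  x0 <- min(fixes$x) - pad
  y0 <- min(fixes$y) - pad
  n_cols <- ceiling((max(fixes$x) + pad - x0) / side)
  n_rows <- ceiling((max(fixes$y) + pad - y0) / side)
  grid_spec(
    origin_x = x0, origin_y = y0, cell_side = side,
    n_cols = n_cols, n_rows = n_rows,
    center = c(attr(fixes, "proj_lon0") %||% NA_real_,
               attr(fixes, "proj_lat0") %||% NA_real_)
  )
}

#' Grid specification
#'
#' The shared raster geometry: lower-left corner `(origin_x, origin_y)` in
#' projected meters, square cells of side `cell_side` meters, `n_cols` x
#' `n_rows` cells, and the lon/lat center of the equal-area projection.
#' Cells follow a half-open convention: a point exactly on a shared edge
#' belongs to the cell with the larger index.
#'
#' @param origin_x,origin_y Lower-left corner, meters.
#' @param cell_side Cell side, meters.
#' @param n_cols,n_rows Grid dimensions.
#' @param center Projection center `c(lon0, lat0)`.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(origin_x, origin_y, cell_side, n_cols, n_rows,
                      center = c(NA_real_, NA_real_)) {
  stopifnot(cell_side > 0, n_cols >= 1, n_rows >= 1)
  structure(
    list(origin_x = origin_x, origin_y = origin_y, cell_side = cell_side,
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         center = as.numeric(center)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, side %.1f m (%.2f km^2/cell)\n",
              x$n_cols, x$n_rows, x$cell_side, (x$cell_side / 1000)^2))
  cat(sprintf("  origin (%.0f, %.0f) m; projection center (%.4f, %.4f)\n",
              x$origin_x, x$origin_y, x$center[1], x$center[2]))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("grid_spec(%d x %d, side %.1f m)", x$n_cols, x$n_rows, x$cell_side)
}

grid_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0))
}

# half-open binning: a point on a shared edge falls in the larger-index cell
grid_col <- function(grid, x) floor((x - grid$origin_x) / grid$cell_side) + 1L
grid_row <- function(grid, y) floor((y - grid$origin_y) / grid$cell_side) + 1L

# centers of columns/rows
grid_col_centers <- function(grid) {
  grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_side
}
grid_row_centers <- function(grid) {
  grid$origin_y + (seq_len(grid$n_rows) - 0.5) * grid$cell_side
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dplyr verbs drop non-standard attributes; carry the projection center along
.keep_proj <- function(out, src) {
  attr(out, "proj_lon0") <- attr(src, "proj_lon0")
  attr(out, "proj_lat0") <- attr(src, "proj_lat0")
  out
}
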