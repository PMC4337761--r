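#' Utilization distribution on the shared grid
#'
#' A discrete utilization distribution: one nonnegative probability mass
#' per grid cell, summing to 1, on a shared [grid_spec()]. Rows of `mass`
#' run south to north (row 1 is the southernmost row), columns west to
#' east.
#'
#' @param mass Numeric matrix `n_rows x n_cols` of cell masses.
#' @param grid The [grid_spec()] the masses live on.
#' @param meta Optional metadata list (`animal_id`, `level`,
#'   `duration_days`, ...).
#' @return A `flyway_ud` object.
#' @export
flyway_ud <- function(mass, grid, meta = list()) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(mass) || nrow(mass) != grid$n_rows || ncol(mass) != grid$n_cols) {
    abort("mass must be an n_rows x n_cols matrix matching the grid")
  }
  if (any(mass < 0)) abort("utilization distribution mass must be nonnegative")
  if (abs(sum(mass) - 1) > 1e-6) {
    abort(sprintf("utilization distribution must sum to 1 (+/- 1e-6), got %.8f", sum(mass)))
  }
  structure(list(mass = mass, grid = grid, meta = meta), class = "flyway_ud")
}

#' @export
print.flyway_ud <- function(x, ...) {
  lvl <- x$meta$level %||% "?"
  cat(sprintf("<flyway_ud> level %s on %s; total mass %.6f\n",
              lvl, format(x$grid), sum(x$mass)))
  occ <- sum(x$mass > 0)
  cat(sprintf("  %d of %d cells carry mass; peak cell mass %.4g\n",
              occ, length(x$mass), max(x$mass)))
  invisible(x)
}

#' Tidy a utilization distribution
#'
#' @param x A `flyway_ud`.
#' @param drop_zero Drop zero-mass cells (default TRUE).
#' @param ... Unused.
#' @return A tibble with `col`, `row`, cell-center `x`, `y` (meters) and
#'   `mass`.
#' @method tidy flyway_ud
#' @export
tidy.flyway_ud <- function(x, drop_zero = TRUE, ...) {
  g <- x$grid
  mass_vec <- as.vector(x$mass) # column-major: row index varies fastest
  out <- tidyr::expand_grid(col = seq_len(g$n_cols), row = seq_len(g$n_rows)) %>%
    mutate(
      x = g$origin_x + (.data$col - 0.5) * g$cell_side,
      y = g$origin_y + (.data$row - 0.5) * g$cell_side,
      mass = mass_vec[(.data$col - 1L) * g$n_rows + .data$row]
    )
  if (drop_zero) out <- filter(out, .data$mass > 0)
  out
}

#' @method glance flyway_ud
#' @export
glance.flyway_ud <- function(x, ...) {
  tibble(
    level = x$meta$level %||% NA_character_,
    total_mass = sum(x$mass),
    n_cells = length(x$mass),
    n_occupied = sum(x$mass > 0),
    peak_mass = max(x$mass),
    cell_side_m = x$grid$cell_side
  )
}

#' Plot a utilization distribution
#'
#' @param object A `flyway_ud`.
#' @param trans Scale transform for the fill (default `"sqrt"` to lift the
#'   long UD tail).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flyway_ud
#' @export
autoplot.flyway_ud <- function(object, trans = "sqrt", ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000,
                                   fill = .data$mass)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "cell mass") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "east (km)", y = "north (km)",
                  title = paste0("Utilization distribution (",
                                 object$meta$level %||% "?", ")")) +
    ggplot2::theme_minimal()
}

#' Write a UD as an ESRI ASCII grid
#'
#' Plain-text raster readable by standard GIS software. Values are cell
#' probability masses; coordinates are in the analysis projection (meters).
#'
#' @param ud A `flyway_ud`.
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(ud, path) {
  g <- ud$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", g$n_cols),
    paste("nrows", g$n_rows),
    paste("xllcorner", format(g$origin_x, scientific = FALSE)),
    paste("yllcorner", format(g$origin_y, scientific = FALSE)),
    paste("cellsize", format(g$cell_side, scientific = FALSE)),
    "NODATA_value -9999"
  ), con)
  # ASCII grids store the top row first
  for (r in rev(seq_len(g$n_rows))) {
    writeLines(paste(formatC(ud$mass[r, ], format = "g", digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}
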