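#' Percent volume of intersection between two UDs
#'
#' The standard volume-of-intersection overlap index,
#' `100 * sum(min(p, q))` over cells: 100 when the two distributions are
#' cell-wise identical, 0 when their supports are disjoint. Symmetric and
#' bounded in `[0, 100]`. Both UDs must share one grid.
#'
#' @param p,q [flyway_ud] objects on the same grid.
#' @return Percent overlap (scalar).
#' @export
percent_vi <- function(p, q) {
  stopifnot(inherits(p, "flyway_ud"), inherits(q, "flyway_ud"))
  if (!grid_identical(p$grid, q$grid)) {
    abort("percent_vi requires both UDs on one identical grid_spec")
  }
  100 * sum(pmin(p$mass, q$mass))
}

#' Subsampling sensitivity curve for flyway sample size
#'
#' Asks how representative `n` marked birds are of the flyway they map.
#' For each subsample size `k` on the grid `1, 1+step, ..., n` (with `n`
#' itself always included, since the full sample is the single reference
#' combination), draws up to `max_combos` distinct combinations of `k`
#' individuals (exhaustively when there are `max_combos` or fewer),
#' aggregates each combination's UDs with duration weights, and averages
#' the percent volume of intersection against the full flyway UD. A LOESS
#' smooth (span 0.75, degree 2) is fitted through the mean %VI values. A
#' curve that keeps rising to `k = n` indicates the sample is too small to
#' be representative; an early asymptote near 100 indicates sufficiency
#' (see [asymptote_check()]).
#'
#' @param individual_uds List of individual-level [flyway_ud]s.
#' @param durations Positive weights (total migration days per individual).
#' @param rng_seed Integer seed; fixing it reproduces the curve exactly.
#' @param max_combos Maximum combinations sampled per `k` (default 100).
#' @param step Increment of the `k` grid (default 3).
#' @param full_ud Optional reference UD; defaults to the duration-weighted
#'   aggregate of all individuals.
#' @param loess_span,loess_degree LOESS parameters (defaults 0.75, 2).
#' @return A `sensitivity_curve` object; see [tidy.sensitivity_curve()],
#'   [autoplot.sensitivity_curve()].
#' @export
sensitivity_curve <- function(individual_uds, durations, rng_seed,
                              max_combos = 100, step = 3, full_ud = NULL,
                              loess_span = 0.75, loess_degree = 2) {
  n <- length(individual_uds)
  if (n < 2) abort("need at least 2 individuals for a sensitivity curve")
  if (length(durations) != n) abort("one duration per individual required")
  if (is.null(full_ud)) {
    full_ud <- aggregate_uds(individual_uds, durations, level = "FLYWAY")
  }
  ks <- seq(1, n, by = step)
  if (ks[length(ks)] != n) ks <- c(ks, n) # full-sample point always present
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(rng_seed)
  rows <- purrr::map(ks, function(k) {
    combos <- .sample_combinations(n, k, max_combos)
    pvis <- vapply(combos, function(idx) {
      sub <- aggregate_uds(individual_uds[idx], durations[idx], level = "SUBSAMPLE")
      percent_vi(sub, full_ud)
    }, numeric(1))
    tibble(k = k, n_combos = length(combos),
           exhaustive = choose(n, k) <= max_combos,
           mean_pvi = mean(pvis), sd_pvi = stats::sd(pvis))
  })
  curve <- bind_rows(rows)
  curve$loess_pvi <- .loess_smooth(curve$k, curve$mean_pvi,
                                   span = loess_span, degree = loess_degree)
  structure(list(curve = curve, n = n, rng_seed = rng_seed,
                 max_combos = max_combos, step = step,
                 loess_span = loess_span, loess_degree = loess_degree),
            class = "sensitivity_curve")
}

# distinct k-subsets of 1..n, uniform without replacement over the
# combination space; exhaustive when feasible
.sample_combinations <- function(n, k, max_combos) {
  total <- choose(n, k)
  if (total <= max_combos) {
    return(unlist(apply(combn(n, k), 2, list), recursive = FALSE))
  }
  seen <- new.env(hash = TRUE)
  out <- vector("list", max_combos)
  got <- 0L
  while (got < max_combos) {
    cand <- sort(sample.int(n, k))
    key <- paste(cand, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- cand
    }
  }
  out
}

.loess_smooth <- function(k, y, span, degree) {
  if (length(k) < 4 || stats::var(y) < 1e-12) return(y)
  fit <- tryCatch(
    suppressWarnings(loess(y ~ k, span = span, degree = degree,
                           control = stats::loess.control(surface = "direct"))),
    error = function(e) NULL
  )
  if (is.null(fit)) return(y)
  out <- tryCatch(
    suppressWarnings(as.numeric(predict(fit, newdata = data.frame(k = k)))),
    error = function(e) y
  )
  if (anyNA(out)) y else out
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat(sprintf("<sensitivity_curve> n = %d individuals, k grid of %d points, seed %d\n",
              x$n, nrow(x$curve), x$rng_seed))
  print(x$curve)
  invisible(x)
}

#' Tidy a sensitivity curve
#'
#' @param x A `sensitivity_curve`.
#' @param ... Unused.
#' @return Tibble: `k`, `n_combos`, `exhaustive`, `mean_pvi`, `sd_pvi`,
#'   `loess_pvi`.
#' @method tidy sensitivity_curve
#' @export
tidy.sensitivity_curve <- function(x, ...) x$curve

#' @method glance sensitivity_curve
#' @export
glance.sensitivity_curve <- function(x, ...) {
  v <- asymptote_check(x)
  tibble(n = x$n, n_k = nrow(x$curve),
         final_pvi = x$curve$mean_pvi[nrow(x$curve)],
         verdict = v$verdict, final_slope = v$final_slope,
         rng_seed = x$rng_seed)
}

#' Plot a sensitivity curve
#'
#' @param object A `sensitivity_curve`.
#' @param ... Unused.
#' @return A ggplot of mean %VI vs k with its LOESS smooth.
#' @method autoplot sensitivity_curve
#' @export
autoplot.sensitivity_curve <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_pvi)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loess_pvi), color = "steelblue") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "individuals in subsample (k)",
                  y = "mean % volume of intersection",
                  title = sprintf("Subsampling sensitivity (n = %d)", object$n)) +
    ggplot2::theme_minimal()
}

#' Asymptote verdict for a sensitivity curve
#'
#' Declares the curve `ASYMPTOTIC` when each of the last `window` LOESS
#' increments is below `tol` percentage points, else `INCREASING` (the
#' sample is not yet representative of the flyway). Also reports the slope
#' of the final LOESS segment (%VI per added individual), which compares
#' steepness across cohorts.
#'
#' @param curve A `sensitivity_curve`.
#' @param window Number of trailing increments examined (default 3).
#' @param tol Maximum increment, percentage points (default 2).
#' @return List with `verdict`, `final_slope`, `increments`.
#' @export
asymptote_check <- function(curve, window = 3, tol = 2) {
  stopifnot(inherits(curve, "sensitivity_curve"))
  cv <- curve$curve
  if (nrow(cv) < 3) abort("need at least 3 k points for an asymptote verdict")
  inc <- diff(cv$loess_pvi)
  last_inc <- tail(inc, window)
  dk <- diff(cv$k)
  final_slope <- tail(inc, 1) / tail(dk, 1)
  list(
    verdict = if (all(last_inc < tol)) "ASYMPTOTIC" else "INCREASING",
    final_slope = final_slope,
    increments = last_inc
  )
}
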