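#' Dynamic Brownian bridge model configuration
#'
#' Tuning parameters for the sliding-window variance estimator and the UD
#' rasterizer. Defaults follow common practice for waterfowl telemetry: a
#' window of 31 locations with margins of 11 locations (about six days of
#' GPS data or four weeks of Argos data at typical duty cycles), 25
#' integration steps per bridge and Gaussian truncation at 4 SD (the
#' truncated tail mass is restored by the final renormalization).
#'
#' @param window_size Odd number of locations per sliding window (default 31).
#' @param margin Odd margin, in locations, at each end of a window within
#'   which no breakpoint may fall (default 11, minimum 3).
#' @param alpha_steps Trapezoid integration steps per bridge (default 25).
#' @param sigma2_bounds Search bounds for the Brownian motion variance,
#'   m^2/s (default `c(1e-4, 1e4)`).
#' @param truncation_radius Gaussian evaluation radius in local SDs
#'   (default 4).
#' @return A `dbbmm_config` object.
#' @export
dbbmm_config <- function(window_size = 31, margin = 11, alpha_steps = 25,
                         sigma2_bounds = c(1e-4, 1e4), truncation_radius = 4) {
  if (window_size %% 2 == 0) abort("window_size must be odd")
  if (margin %% 2 == 0) abort("margin must be odd")
  if (margin < 3) abort("margin must be at least 3 locations")
  if (window_size < 2 * margin + 1) abort("window_size must be >= 2 * margin + 1")
  if (sigma2_bounds[1] <= 0 || sigma2_bounds[2] <= sigma2_bounds[1]) {
    abort("sigma2_bounds must be positive and increasing")
  }
  structure(list(window_size = as.integer(window_size),
                 margin = as.integer(margin),
                 alpha_steps = as.integer(alpha_steps),
                 sigma2_bounds = as.numeric(sigma2_bounds),
                 truncation_radius = truncation_radius),
            class = "dbbmm_config")
}

#' @export
print.dbbmm_config <- function(x, ...) {
  cat(sprintf("<dbbmm_config> window %d, margin %d, alpha_steps %d, sigma2 in [%g, %g] m^2/s\n",
              x$window_size, x$margin, x$alpha_steps,
              x$sigma2_bounds[1], x$sigma2_bounds[2]))
  invisible(x)
}

# Bridge terms under the odd/even conditioning scheme: every even-indexed
# fix is treated as an independent observation of the Brownian bridge pinned
# at its flanking odd-indexed fixes. For intermediate j with flanks a, b:
#   alpha = (t_j - t_a) / (t_b - t_a)
#   mean  = z_a + alpha (z_b - z_a)
#   var   = T alpha (1-alpha) sigma2 + (1-alpha)^2 delta_a^2 + alpha^2 delta_b^2
# per axis. Returned: a2 = T alpha (1-alpha) (coefficient on sigma2),
# c0 = error part of the variance, r2 = squared residual from the mean,
# j = window-local index of the intermediate fix.
.bridge_terms <- function(t, x, y, err) {
  n <- length(t)
  if (n < 3) abort("need at least 3 fixes for a bridge likelihood")
  if (any(diff(t) <= 0)) abort("duplicate or non-increasing timestamps in window")
  j <- seq(2L, n - 1L, by = 2L)
  a <- j - 1L; b <- j + 1L
  T_ab <- t[b] - t[a]
  alpha <- (t[j] - t[a]) / T_ab
  mx <- x[a] + alpha * (x[b] - x[a])
  my <- y[a] + alpha * (y[b] - y[a])
  list(
    a2 = T_ab * alpha * (1 - alpha),
    c0 = (1 - alpha)^2 * err[a]^2 + alpha^2 * err[b]^2,
    r2 = (x[j] - mx)^2 + (y[j] - my)^2,
    j = j
  )
}

.bridge_ll <- function(terms, sigma2, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(terms$j)
  s <- terms$a2[idx] * sigma2 + terms$c0[idx]
  sum(-log(2 * pi * s) - terms$r2[idx] / (2 * s))
}

# Adaptive quadrature grid over the bridge's relative time. The bridge mean
# advances L * d_alpha per step; steps larger than the local kernel width
# leave visible lumps on fine grids, so the step is capped by half the local
# SD (and by side/8), with 1/base_steps as the coarse baseline. Returns
# midpoints and interval weights (midpoint rule).
.alpha_grid <- function(L, T, sigma2, err0, err1, side, base_steps) {
  s_of <- function(a) T * a * (1 - a) * sigma2 + (1 - a)^2 * err0^2 + a^2 * err1^2
  coarse <- 1 / base_steps
  if (L < 1e-9) {
    knots <- seq(0, 1, length.out = base_steps + 1)
  } else {
    knots <- numeric(4096)
    knots[1] <- 0
    n_k <- 1L
    a <- 0
    while (a < 1 && n_k < 4096L) {
      da <- min(coarse, max(0.5 * sqrt(s_of(a)), side / 8) / L)
      a <- min(1, a + max(da, 1e-4))
      n_k <- n_k + 1L
      knots[n_k] <- a
    }
    knots <- knots[seq_len(n_k)]
  }
  list(alpha = (knots[-1] + knots[-length(knots)]) / 2, weight = diff(knots))
}

# bounded MLE of sigma2 on the log scale (Brent-type search)
.fit_sigma2 <- function(terms, bounds, idx = NULL) {
  opt <- optimize(function(ls) .bridge_ll(terms, exp(ls), idx),
                  interval = log(bounds), maximum = TRUE, tol = 1e-6)
  list(sigma2 = exp(opt$maximum), ll = opt$objective)
}

#' Brownian bridge window log-likelihood
#'
#' Log-likelihood of the even-indexed (intermediate) fixes of a window
#' under Brownian bridges pinned at the flanking odd-indexed fixes, with
#' per-axis variance `T a (1-a) sigma2 + (1-a)^2 d_a^2 + a^2 d_b^2` at
#' relative time `a` along the bridge (Gaussian location errors `d`).
#'
#' @param window_fixes A projected fix tibble (>= 3 rows) with `x`, `y`,
#'   `timestamp`, `error_sd`.
#' @param sigma2 Brownian motion variance, m^2/s.
#' @return The log-likelihood (scalar).
#' @export
bridge_loglik <- function(window_fixes, sigma2) {
  terms <- .bridge_terms(as.numeric(window_fixes$timestamp),
                         window_fixes$x, window_fixes$y,
                         window_fixes$error_sd)
  .bridge_ll(terms, sigma2)
}

#' Estimate the dynamic Brownian motion variance along an event
#'
#' Slides a window of `window_size` locations (one fix at a time) along the
#' event. Per window it fits a single Brownian motion variance (one free
#' parameter) and, for every admissible breakpoint outside the two margins,
#' a two-variance model (two free parameters; the breakpoint position is
#' not counted), and keeps the model with the lower
#' `BIC = -2 logL + k log(n_intermediate)`. A segment's final variance is
#' the unweighted mean over all windows covering it outside their margins;
#' the few segments inside every window's margin (the event's very ends)
#' inherit the nearest covered estimate. Events shorter than the window get
#' a single event-wide MLE (reported via a message) rather than being
#' dropped, which preserves short Argos events.
#'
#' @param fixes One event's projected, error-assigned fixes (time-ordered).
#' @param config A [dbbmm_config()].
#' @return A `dbbmm_fit` object: per-segment variances (`$segments`),
#'   window diagnostics (`$windows`), the config and the fixes. Methods:
#'   [tidy.dbbmm_fit()], [glance.dbbmm_fit()], [compute_ud()].
#' @export
estimate_variances <- function(fixes, config = dbbmm_config()) {
  n <- nrow(fixes)
  if (n < 3) abort("need at least 3 fixes to estimate a Brownian motion variance")
  t <- as.numeric(fixes$timestamp)
  if (any(diff(t) <= 0)) abort("fixes must strictly increase in time")
  x <- fixes[["x"]]; y <- fixes[["y"]]; err <- fixes[["error_sd"]]
  if (is.null(x) || anyNA(x)) abort("fixes must be projected (x, y) first")
  if (is.null(err) || anyNA(err)) abort("fixes must carry error_sd (see assign_errors())")
  w <- config$window_size; m <- config$margin
  bounds <- config$sigma2_bounds
  n_seg <- n - 1L
  acc_sum <- numeric(n_seg)
  acc_cnt <- integer(n_seg)
  windows <- list()

  degenerate <- all(abs(x - x[1]) < 1e-9) && all(abs(y - y[1]) < 1e-9)
  if (degenerate) {
    warn("all coordinates identical; sigma2 pinned to the lower bound")
  }

  if (n < w || degenerate) {
    terms <- .bridge_terms(t, x, y, err)
    fit <- if (degenerate) list(sigma2 = bounds[1], ll = NA_real_) else
      .fit_sigma2(terms, bounds)
    if (n < w && !degenerate) {
      inform(sprintf("event has %d fixes (< window of %d); using a single event-wide sigma2",
                     n, w))
    }
    acc_sum[] <- fit$sigma2
    acc_cnt[] <- 1L
    windows <- tibble(window = 1L, start = 1L, breakpoint = NA_integer_,
                      bic_single = NA_real_, bic_split = NA_real_,
                      sigma2_single = fit$sigma2,
                      sigma2_left = NA_real_, sigma2_right = NA_real_)
  } else {
    bp_cand <- seq(m + 1L, w - m)
    n_win <- n - w + 1L
    windows <- vector("list", n_win)
    for (i in seq_len(n_win)) {
      loc <- i:(i + w - 1L)
      terms <- .bridge_terms(t[loc], x[loc], y[loc], err[loc])
      n_int <- length(terms$j)
      single <- .fit_sigma2(terms, bounds)
      bic1 <- -2 * single$ll + 1 * log(n_int)
      best <- list(bic = Inf, b = NA_integer_, s1 = NA_real_, s2 = NA_real_)
      for (b in bp_cand) {
        left <- which(terms$j <= b)
        right <- which(terms$j > b)
        if (length(left) == 0 || length(right) == 0) next
        fl <- .fit_sigma2(terms, bounds, left)
        fr <- .fit_sigma2(terms, bounds, right)
        bic2 <- -2 * (fl$ll + fr$ll) + 2 * log(n_int)
        if (bic2 < best$bic) best <- list(bic = bic2, b = b,
                                          s1 = fl$sigma2, s2 = fr$sigma2)
      }
      split <- is.finite(best$bic) && best$bic < bic1
      # window-local non-margin segments: between fixes m+1 .. w-m
      segs_loc <- seq(m + 1L, w - m - 1L)
      vals <- if (split) {
        ifelse(segs_loc < best$b, best$s1, best$s2)
      } else rep(single$sigma2, length(segs_loc))
      segs_glob <- segs_loc + i - 1L
      acc_sum[segs_glob] <- acc_sum[segs_glob] + vals
      acc_cnt[segs_glob] <- acc_cnt[segs_glob] + 1L
      windows[[i]] <- tibble(
        window = i, start = i,
        breakpoint = if (split) best$b + i - 1L else NA_integer_,
        bic_single = bic1, bic_split = best$bic,
        sigma2_single = single$sigma2,
        sigma2_left = if (split) best$s1 else NA_real_,
        sigma2_right = if (split) best$s2 else NA_real_
      )
    }
    windows <- bind_rows(windows)
  }

  sigma2_m <- ifelse(acc_cnt > 0, acc_sum / pmax(acc_cnt, 1L), NA_real_)
  # event-edge segments inside every margin inherit the nearest estimate
  if (anyNA(sigma2_m)) {
    covered <- which(!is.na(sigma2_m))
    for (s in which(is.na(sigma2_m))) {
      sigma2_m[s] <- sigma2_m[covered[which.min(abs(covered - s))]]
    }
  }
  segments <- tibble(
    segment = seq_len(n_seg),
    t0 = t[-n], t1 = t[-1],
    x0 = x[-n], y0 = y[-n], x1 = x[-1], y1 = y[-1],
    err0 = err[-n], err1 = err[-1],
    T = t[-1] - t[-n],
    sigma2_m = sigma2_m,
    n_windows = acc_cnt
  )
  structure(list(segments = segments, windows = windows, config = config,
                 n_fixes = n,
                 animal_id = fixes[["animal_id"]][1] %||% NA_character_,
                 event_id = fixes[["event_id"]][1] %||% NA_character_),
            class = "dbbmm_fit")
}

#' @export
print.dbbmm_fit <- function(x, ...) {
  cat(sprintf("<dbbmm_fit> %s: %d fixes, %d segments, window %d / margin %d\n",
              x$animal_id %||% "?", x$n_fixes, nrow(x$segments),
              x$config$window_size, x$config$margin))
  cat(sprintf("  sigma2_m: median %.3g, range [%.3g, %.3g] m^2/s; %d/%d windows split\n",
              stats::median(x$segments$sigma2_m), min(x$segments$sigma2_m),
              max(x$segments$sigma2_m), sum(!is.na(x$windows$breakpoint)),
              nrow(x$windows)))
  invisible(x)
}

#' Tidy a dBBMM fit
#'
#' @param x A `dbbmm_fit`.
#' @param ... Unused.
#' @return One row per track segment: times, endpoints, elapsed seconds `T`
#'   and the estimated Brownian motion variance `sigma2_m` (m^2/s).
#' @method tidy dbbmm_fit
#' @export
tidy.dbbmm_fit <- function(x, ...) x$segments

#' One-row summary of a dBBMM fit
#'
#' @param x A `dbbmm_fit`.
#' @param ... Unused.
#' @method glance dbbmm_fit
#' @export
glance.dbbmm_fit <- function(x, ...) {
  tibble(
    n_fixes = x$n_fixes,
    n_segments = nrow(x$segments),
    n_windows = nrow(x$windows),
    frac_windows_split = mean(!is.na(x$windows$breakpoint)),
    sigma2_median = stats::median(x$segments$sigma2_m),
    sigma2_min = min(x$segments$sigma2_m),
    sigma2_max = max(x$segments$sigma2_m),
    window_size = x$config$window_size,
    margin = x$config$margin
  )
}

#' Rasterize one event's utilization distribution
#'
#' Integrates, for every track segment, the Brownian bridge density over
#' relative time (trapezoid rule with `alpha_steps` nodes), weights segment
#' contributions by their elapsed time, and accumulates exact per-cell
#' Gaussian mass (products of 1-D interval probabilities, so cells smaller
#' than the local SD are handled correctly). Each Gaussian slice is
#' truncated at `truncation_radius` local SDs; the lost tail mass is
#' restored by the final renormalization to total mass 1.
#'
#' @param fit A `dbbmm_fit` from [estimate_variances()].
#' @param grid The shared [grid_spec()].
#' @param config A [dbbmm_config()]; defaults to the fit's own.
#' @return A [flyway_ud] object.
#' @export
compute_ud <- function(fit, grid, config = fit$config) {
  stopifnot(inherits(fit, "dbbmm_fit"), inherits(grid, "grid_spec"))
  seg <- fit$segments
  steps <- config$alpha_steps
  trunc_r <- config$truncation_radius
  side <- grid$cell_side
  mass <- matrix(0, nrow = grid$n_rows, ncol = grid$n_cols)
  for (s in seq_len(nrow(seg))) {
    w_seg <- seg$T[s]
    L <- sqrt((seg$x1[s] - seg$x0[s])^2 + (seg$y1[s] - seg$y0[s])^2)
    aw <- .alpha_grid(L, seg$T[s], seg$sigma2_m[s], seg$err0[s], seg$err1[s],
                      side, steps)
    for (k in seq_along(aw$alpha)) {
      a <- aw$alpha[k]
      mx <- seg$x0[s] + a * (seg$x1[s] - seg$x0[s])
      my <- seg$y0[s] + a * (seg$y1[s] - seg$y0[s])
      sv <- seg$T[s] * a * (1 - a) * seg$sigma2_m[s] +
        (1 - a)^2 * seg$err0[s]^2 + a^2 * seg$err1[s]^2
      sd_loc <- sqrt(sv)
      r <- trunc_r * sd_loc
      c1 <- max(1L, grid_col(grid, mx - r)); c2 <- min(grid$n_cols, grid_col(grid, mx + r))
      r1 <- max(1L, grid_row(grid, my - r)); r2 <- min(grid$n_rows, grid_row(grid, my + r))
      if (c1 > c2 || r1 > r2) next
      # exact per-cell Gaussian mass: product of 1-D interval probabilities
      xe <- grid$origin_x + (c1 - 1L):c2 * side
      ye <- grid$origin_y + (r1 - 1L):r2 * side
      px <- diff(stats::pnorm(xe, mean = mx, sd = sd_loc))
      py <- diff(stats::pnorm(ye, mean = my, sd = sd_loc))
      mass[r1:r2, c1:c2] <- mass[r1:r2, c1:c2] + (w_seg * aw$weight[k]) * outer(py, px)
    }
  }
  total <- sum(mass)
  if (total <= 0) abort("utilization distribution has zero mass; check inputs")
  boundary <- sum(mass[1, ]) + sum(mass[grid$n_rows, ]) +
    sum(mass[, 1]) + sum(mass[, grid$n_cols])
  if (boundary / total > 1e-4) {
    abort("probability mass reaches the grid boundary; rebuild the grid with larger padding")
  }
  mass <- mass / sum(mass)
  flyway_ud(mass, grid, meta = list(
    animal_id = fit$animal_id, event_id = fit$event_id, level = "EVENT",
    duration_days = (max(seg$t1) - min(seg$t0)) / 86400
  ))
}
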