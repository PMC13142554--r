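#' Extract a point trace from a trajectory
#'
#' Returns the time series of `u`, `lap(u)`, `grad(u).grad(v)`, `v` and
#' `lap(v)` at a fixed grid position. If the trajectory was run with probe
#' positions (see [sim_config()] `trace_positions`) the densely recorded
#' trace is returned; otherwise the series is recomputed from the stored
#' snapshots, which requires a reasonably dense snapshot cadence.
#'
#' @param traj A `ks_trajectory`.
#' @param pos Position `c(x, y)` (1-based; `x` = column, `y` = row), interior
#'   to the grid — boundary cells are rejected because their stencils use
#'   mirrored ghosts and are not comparable to interior dynamics.
#' @return An object of class `ks_point_trace`: a data.frame with columns
#'   `t, u, lap_u, grad_uv, v, lap_v` and attribute `pos`.
#' @export
extract_trace <- function(traj, pos) {
  stopifnot(inherits(traj, "ks_trajectory"))
  nx <- traj$cfg$nx; ny <- traj$cfg$ny
  ij <- pos_to_rowcol(pos, nx, ny)
  if (ij[1] <= 1 || ij[1] >= ny || ij[2] <= 1 || ij[2] >= nx) {
    stop("position must be interior to the grid")
  }
  key <- paste(pos, collapse = ",")
  if (!is.null(traj$traces) && key %in% names(traj$traces)) {
    out <- traj$traces[[key]]
  } else {
    h <- traj$params$h
    vals <- lapply(seq_along(traj$times), function(k) {
      u <- traj$u[[k]]; v <- traj$v[[k]]
      c(u = u[ij[1], ij[2]],
        lap_u = cpp_laplacian(u, h)[ij[1], ij[2]],
        grad_uv = cpp_grad_dot(u, v, h)[ij[1], ij[2]],
        v = v[ij[1], ij[2]],
        lap_v = cpp_laplacian(v, h)[ij[1], ij[2]])
    })
    m <- do.call(rbind, vals)
    out <- data.frame(t = traj$times, m)
  }
  structure(out, class = c("ks_point_trace", "data.frame"), pos = pos)
}

#' Segment a trace into three temporal phases
#'
#' Fits a continuous two-breakpoint piecewise-linear model to a scalar time
#' series by exhaustive least squares over candidate breakpoint pairs, and
#' reports the three per-phase slopes. This operationalizes the visually
#' identified "very fast / fast / slow" phase structure of the network-forming
#' dynamics: the chemoattractant at a fixed position first rises steeply,
#' then drops abruptly, then creeps to its stationary value.
#'
#' Breakpoints are restricted to sample times and the search is exhaustive
#' over all admissible pairs, which is intended for series of at most a few
#' hundred samples. Longer series are first evenly subsampled to
#' `max_samples` working points (the SSE is computed on the working grid).
#' This matters scientifically, not just computationally: on a uniformly
#' oversampled long run, plain SSE is dominated by the long slow phase and
#' the fit drifts away from the short fast transients; a few hundred samples
#' across the run recover them. On a noiseless piecewise-linear input whose
#' true breakpoints are sample times of the working grid, recovery is exact.
#'
#' @param trace A `ks_point_trace`, or any data.frame with a `t` column and
#'   the signal column.
#' @param signal Column to segment (default `"v"`; the chemoattractant shows
#'   the sharpest phase transitions, `"u"` is available as an option).
#' @param min_seg Minimum number of samples per segment (default 3).
#' @param max_samples Cap on the number of working samples (default 400).
#' @return An object of class `ks_phase_segmentation`: a list with
#'   `breakpoints` (two times), `slopes` (three per-phase slopes),
#'   `sse` (fit error), `degenerate` (TRUE when the three slopes are
#'   indistinguishable, e.g. an exactly linear input), `signal`, and
#'   `fitted` (fitted values on the working grid, with times in `t_used`).
#' @export
segment_phases <- function(trace, signal = c("v", "u"), min_seg = 3,
                           max_samples = 400) {
  signal <- match.arg(signal)
  t <- trace$t
  y <- trace[[signal]]
  n <- length(t)
  if (n < 20) stop("need at least 20 samples to segment")
  stopifnot(min_seg >= 2)
  if (n > max_samples) {
    keep <- unique(round(seq(1, n, length.out = max_samples)))
    t <- t[keep]; y <- y[keep]
    n <- length(t)
  }

  idx <- seq(1 + min_seg, n - min_seg)
  best <- list(sse = Inf)
  for (a in seq_along(idx)) {
    i1 <- idx[a]
    for (b in seq_along(idx)) {
      i2 <- idx[b]
      if (i2 - i1 < min_seg) next
      X <- cbind(1, t, pmax(t - t[i1], 0), pmax(t - t[i2], 0))
      fit <- stats::.lm.fit(X, y)
      sse <- sum(fit$residuals^2)
      if (sse < best$sse) {
        best <- list(sse = sse, i1 = i1, i2 = i2, coef = fit$coefficients,
                     fitted = y - fit$residuals)
      }
    }
  }
  beta <- best$coef
  slopes <- c(beta[2], beta[2] + beta[3], beta[2] + beta[3] + beta[4])
  spread <- diff(range(slopes))
  scale <- max(abs(slopes), 1e-300)
  structure(list(breakpoints = c(t[best$i1], t[best$i2]),
                 breakpoint_index = c(best$i1, best$i2),
                 slopes = slopes, sse = best$sse,
                 degenerate = spread < 1e-8 * scale,
                 signal = signal, fitted = best$fitted, t_used = t),
            class = "ks_phase_segmentation")
}

#' @export
print.ks_phase_segmentation <- function(x, ...) {
  cat(sprintf("Three-phase segmentation of %s(t):\n", x$signal))
  cat(sprintf("  breakpoints t1=%.3f t2=%.3f\n",
              x$breakpoints[1], x$breakpoints[2]))
  cat(sprintf("  slopes %.4g | %.4g | %.4g  (SSE %.3g)%s\n",
              x$slopes[1], x$slopes[2], x$slopes[3], x$sse,
              if (x$degenerate) "  [degenerate: slopes indistinguishable]" else ""))
  invisible(x)
}
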