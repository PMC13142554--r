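#' Simulation configuration
#'
#' Collects everything a forward run of the modified Keller-Segel system
#' needs: parameters, grid size, time stepping, snapshot times, probe
#' positions and the RNG seed for the initial perturbation.
#'
#' The explicit RK4 scheme requires `dt <= h^2 / (4 max(du, dv))`; a `dt`
#' violating the bound is shrunk (halved until stable) with a warning.
#'
#' @param params A [ks_params()] object.
#' @param nx,ny Grid extents in cells (default 100 x 100).
#' @param t_end Final time (default 180, long enough for the network
#'   patterns to become stationary).
#' @param dt Time step (default 0.01).
#' @param snapshot_times Times at which full fields are stored (rounded to
#'   the nearest step). `t_end` is always included.
#' @param seed RNG seed for the initial noise.
#' @param ic Initial-condition descriptor: `"nine-squares"` (the reference
#'   pattern, see [make_initial_condition()]) or `"uniform"` (constant
#'   `uniform_u` with noise).
#' @param square_frac Side of each seeded square as a fraction of `nx`
#'   (default 0.1).
#' @param noise_amp Amplitude of the uniform noise added to `u0`
#'   (default 0.2; each cell gets an i.i.d. Uniform\[0, noise_amp\] offset).
#' @param uniform_u Background value for `ic = "uniform"`.
#' @param uniform_v Initial chemoattractant level (default 0.5).
#' @param trace_positions List of `c(x, y)` probe positions (1-based column,
#'   row) at which dense point traces are recorded, or `NULL`.
#' @param trace_dt Cadence of trace recording in time units (default 0.1).
#' @param scheme Face-density scheme for the chemotaxis term,
#'   `"arithmetic"` (default) or `"upwind"`; see [chemotaxis_div()].
#' @return An object of class `ks_sim_config`.
#' @export
sim_config <- function(params = ks_params(), nx = 100, ny = 100,
                       t_end = 180, dt = 0.01,
                       snapshot_times = c(0, 2.5, 7.8, 19.2, 46.3, 180),
                       seed = 1L, ic = c("nine-squares", "uniform"),
                       square_frac = 0.1, noise_amp = 0.2, uniform_u = 0.5,
                       uniform_v = 0.5, trace_positions = NULL, trace_dt = 0.1,
                       scheme = c("arithmetic", "upwind")) {
  ic <- match.arg(ic)
  scheme <- match.arg(scheme)
  stopifnot(inherits(params, "ks_params"), nx >= 3, ny >= 3, t_end > 0, dt > 0)
  dmax <- max(params$du, params$dv)
  if (dmax > 0) {
    bound <- params$h^2 / (4 * dmax)
    if (dt > bound) {
      dt0 <- dt
      while (dt > bound) dt <- dt / 2
      warning(sprintf("dt=%g violates the stability bound h^2/(4 max(du,dv))=%g; using dt=%g",
                      dt0, bound, dt))
    }
  }
  snapshot_times <- sort(unique(pmin(c(snapshot_times, t_end), t_end)))
  structure(list(params = params, nx = as.integer(nx), ny = as.integer(ny),
                 t_end = t_end, dt = dt, snapshot_times = snapshot_times,
                 seed = as.integer(seed), ic = ic, square_frac = square_frac,
                 noise_amp = noise_amp, uniform_u = uniform_u,
                 uniform_v = uniform_v,
                 trace_positions = trace_positions, trace_dt = trace_dt,
                 scheme = scheme),
            class = "ks_sim_config")
}

#' Reference initial condition
#'
#' Builds the seeded-colony initial state: cell density 0.2 everywhere
#' except nine equal squares at value 0.8, centered on the 3 x 3 lattice at
#' fractions (1/4, 1/2, 3/4) of each axis, plus an i.i.d. Uniform\[0, 0.2\]
#' perturbation per cell. The chemoattractant starts at the constant 0.5.
#'
#' @param cfg A [sim_config()] object.
#' @return `list(u0, v0)` of numeric matrices (`ny` rows, `nx` columns).
#' @export
make_initial_condition <- function(cfg) {
  stopifnot(inherits(cfg, "ks_sim_config"))
  nx <- cfg$nx; ny <- cfg$ny
  set.seed(cfg$seed)
  if (cfg$ic == "uniform") {
    u0 <- matrix(cfg$uniform_u, ny, nx)
  } else {
    side <- max(1L, round(cfg$square_frac * nx))
    pitch <- min(nx, ny) / 4
    if (side >= pitch) {
      stop(sprintf("square side %d exceeds the lattice pitch %g", side, pitch))
    }
    u0 <- matrix(0.2, ny, nx)
    cx <- round(nx * c(1, 2, 3) / 4)
    cy <- round(ny * c(1, 2, 3) / 4)
    half <- side %/% 2
    for (x in cx) for (y in cy) {
      rows <- (y - half):(y - half + side - 1)
      cols <- (x - half):(x - half + side - 1)
      u0[rows, cols] <- 0.8
    }
  }
  if (cfg$noise_amp > 0) {
    u0 <- u0 + matrix(runif(nx * ny, 0, cfg$noise_amp), ny, nx)
  }
  list(u0 = u0, v0 = matrix(cfg$uniform_v, ny, nx))
}

#' PDE right-hand side
#'
#' Semi-discrete right-hand side of the modified Keller-Segel system:
#' `du/dt = f(u) - b div(u grad v) + du lap(u)` and
#' `dv/dt = c u - e v + dv lap(v)`, with zero-flux boundaries. Because the
#' transport term is in conservative form and the Laplacian telescopes, the
#' discrete integral of `du/dt` equals the integral of `f(u)` exactly — the
#' semi-discrete counterpart of the mean-value identity of the continuum
#' system.
#'
#' @param u,v Numeric matrices (cell density, chemoattractant).
#' @param p A [ks_params()] object.
#' @param scheme Face-density scheme, `"arithmetic"` or `"upwind"`.
#' @return `list(du_dt, dv_dt)` of matrices.
#' @export
ks_rhs <- function(u, v, p, scheme = c("arithmetic", "upwind")) {
  scheme <- match.arg(scheme)
  check_field(u); check_same_shape(u, v)
  cpp_ks_rhs(u, v, p$a, p$b, p$c, p$e, p$du, p$dv, p$gamma, p$h,
             upwind = as.integer(scheme == "upwind"))
}

#' Run the forward simulation
#'
#' Integrates the modified Keller-Segel system with classical RK4, records
#' per-step diagnostics (spatial means and extrema of both fields), stores
#' snapshots at the configured times and, if probe positions are set, dense
#' point traces of `u`, `lap(u)`, `grad(u).grad(v)`, `v`, `lap(v)`.
#'
#' @param cfg A [sim_config()] object.
#' @param blowup Abort threshold on `max(abs(u))` (default 1e3).
#' @return An object of class `ks_trajectory`: a list with elements
#'   `times` (snapshot times), `u`, `v` (lists of matrices), `diag`
#'   (per-step data.frame `t, mean_u, mean_v, min_u, max_u, min_v`),
#'   `traces` (list of per-position data.frames, or `NULL`), `cfg`, and
#'   `params`.
#' @examples
#' \donttest{
#' cfg <- sim_config(ks_params(gamma = 0.1), nx = 40, ny = 40, t_end = 3,
#'                   snapshot_times = c(0, 3), seed = 1)
#' traj <- simulate_ks(cfg)
#' classify_regime(traj)
#' }
#' @export
simulate_ks <- function(cfg, blowup = 1e3) {
  stopifnot(inherits(cfg, "ks_sim_config"))
  p <- cfg$params
  ic <- make_initial_condition(cfg)
  nsteps <- as.integer(round(cfg$t_end / cfg$dt))
  snap_steps <- sort(unique(as.integer(round(cfg$snapshot_times / cfg$dt))))
  snap_steps <- snap_steps[snap_steps <= nsteps]

  tr_rows <- integer(0); tr_cols <- integer(0)
  if (!is.null(cfg$trace_positions)) {
    for (pos in cfg$trace_positions) {
      ij <- pos_to_rowcol(pos, cfg$nx, cfg$ny)
      tr_rows <- c(tr_rows, ij[1] - 1L)  # 0-based for the kernel
      tr_cols <- c(tr_cols, ij[2] - 1L)
    }
  }
  trace_every <- max(1L, as.integer(round(cfg$trace_dt / cfg$dt)))

  res <- cpp_ks_simulate(ic$u0, ic$v0, p$a, p$b, p$c, p$e, p$du, p$dv,
                         p$gamma, p$h, cfg$dt, nsteps, snap_steps,
                         tr_rows, tr_cols, trace_every, blowup,
                         upwind = as.integer(identical(cfg$scheme, "upwind")))
  if (isTRUE(res$blowup)) {
    stop(sprintf("simulation blew up at step %d (t=%g): max|u| exceeded %g",
                 res$blow_step, res$blow_step * cfg$dt, blowup))
  }
  ns <- res$n_snaps
  traces <- NULL
  if (length(tr_rows) > 0) {
    nt <- res$n_trace
    traces <- lapply(seq_along(tr_rows), function(q) {
      data.frame(t = res$trace_t[seq_len(nt)],
                 u = res$trace_u[seq_len(nt), q],
                 lap_u = res$trace_lap_u[seq_len(nt), q],
                 grad_uv = res$trace_grad_uv[seq_len(nt), q],
                 v = res$trace_v[seq_len(nt), q],
                 lap_v = res$trace_lap_v[seq_len(nt), q])
    })
    names(traces) <- vapply(cfg$trace_positions,
                            function(pos) paste(pos, collapse = ","), "")
  }
  structure(list(times = snap_steps[seq_len(ns)] * cfg$dt,
                 u = res$snaps_u[seq_len(ns)],
                 v = res$snaps_v[seq_len(ns)],
                 diag = res$diag,
                 traces = traces,
                 u_final = res$u_final, v_final = res$v_final,
                 cfg = cfg, params = p, seed = cfg$seed),
            class = "ks_trajectory")
}

# (x, y) position (1-based, x = column, y = row) -> c(row, col)
pos_to_rowcol <- function(pos, nx, ny) {
  stopifnot(length(pos) == 2)
  x <- as.integer(pos[1]); y <- as.integer(pos[2])
  if (x < 1 || x > nx || y < 1 || y > ny) stop("position outside the grid")
  c(y, x)
}

#' @export
print.ks_trajectory <- function(x, ...) {
  cat(sprintf("Keller-Segel trajectory: %dx%d grid, t in [0, %g], %d snapshots\n",
              x$cfg$ny, x$cfg$nx, max(x$diag$t), length(x$times)))
  cat(sprintf("  final mean u=%.4f, min u=%.3g, max u=%.4f\n",
              tail(x$diag$mean_u, 1), tail(x$diag$min_u, 1),
              tail(x$diag$max_u, 1)))
  invisible(x)
}

#' Spatial mean values and their balance law
#'
#' Computes the domain integrals `ubar(t) = sum(u) h^2` and
#' `vbar(t) = sum(v) h^2` along a trajectory together with the residual of
#' the exact balance law `dvbar/dt = c ubar - e vbar`, estimated by central
#' differences in time on the per-step diagnostic series. At a stationary
#' state the law reduces to `c ubar = e vbar`.
#'
#' @param traj A `ks_trajectory`.
#' @return A list with `t`, `u_bar`, `v_bar` (integrals at each recorded
#'   step), `residual` (at interior steps) and `max_residual`.
#' @export
mean_values <- function(traj) {
  stopifnot(inherits(traj, "ks_trajectory"))
  d <- traj$diag
  if (nrow(d) < 3) stop("need at least 3 recorded steps")
  p <- traj$params
  area <- traj$cfg$nx * traj$cfg$ny * p$h^2
  ub <- d$mean_u * area
  vb <- d$mean_v * area
  n <- length(ub)
  dt <- diff(d$t)
  dvb <- (vb[3:n] - vb[1:(n - 2)]) / (d$t[3:n] - d$t[1:(n - 2)])
  resid <- abs(dvb - (p$c * ub[2:(n - 1)] - p$e * vb[2:(n - 1)]))
  list(t = d$t, u_bar = ub, v_bar = vb,
       residual = resid, max_residual = max(resid))
}

#' Label the long-time pattern regime
#'
#' Classifies the final state of a trajectory into one of the qualitative
#' regimes observed as the reaction threshold `gamma` varies:
#'
#' * `"homogeneous-high"` / `"homogeneous-low"`: spatially uniform at 1
#'   (resp. 0) to within `hom_tol`;
#' * `"network"`: bimodal final field — both the low (`u < 0.3`) and high
#'   (`u > 0.7`) populations exceed `mode_frac` of the domain — whose
#'   high-density phase forms one essentially connected skeleton;
#' * `"degenerate-network"`: a non-homogeneous final state whose
#'   high-density phase is fragmented into disconnected remnants (either
#'   bimodal with a broken skeleton, or a sparse high mode below
#'   `mode_frac` that never coalesced);
#' * `"traveling-invasion"`: one phase swept the other — the high-phase
#'   area fraction crossed 50\% during the run and what remains of the
#'   displaced phase is a single coherent region (typically a boundary
#'   layer);
#' * `"transient"`: none of the above, or the run was stopped before
#'   `t = 180` without reaching a homogeneous state.
#'
#' The thresholds operationalize regimes that are described qualitatively
#' from simulation snapshots; they are deliberate package choices (see the
#' methods vignette). Connectivity is measured as the fraction of
#' high-phase (`u > 0.5`) cells inside the largest 4-connected component.
#'
#' @param traj A `ks_trajectory`.
#' @param hom_tol Maximum deviation for a field to count as homogeneous
#'   (default 0.01).
#' @param mode_frac Minimum area fraction of each mode for bimodality
#'   (default 0.05).
#' @param connected_frac Largest-component fraction at or above which the
#'   high phase counts as one connected network (default 0.5).
#' @return A single regime label (character).
#' @export
classify_regime <- function(traj, hom_tol = 0.01, mode_frac = 0.05,
                            connected_frac = 0.5) {
  stopifnot(inherits(traj, "ks_trajectory"))
  uT <- traj$u_final
  if (max(abs(uT - 1)) < hom_tol) return("homogeneous-high")
  if (max(abs(uT)) < hom_tol) return("homogeneous-low")
  if (max(traj$diag$t) < 180) return("transient")
  frac_low <- mean(uT < 0.3)
  frac_high <- mean(uT > 0.7)
  lcc <- lcc_fraction(uT > 0.5)
  if (frac_low > mode_frac && frac_high > mode_frac) {
    return(if (lcc >= connected_frac) "network" else "degenerate-network")
  }
  high_area <- vapply(traj$u, function(m) mean(m > 0.5), numeric(1))
  crossed <- length(high_area) >= 2 && any(diff(sign(high_area - 0.5)) != 0)
  if (frac_high > 0 && frac_high <= mode_frac) {
    if (lcc < 0.9) return("degenerate-network")
    if (crossed) return("traveling-invasion")
  }
  if (crossed) return("traveling-invasion")
  "transient"
}

# fraction of TRUE cells in the largest 4-connected component of a mask
lcc_fraction <- function(mask) {
  tot <- sum(mask)
  if (tot == 0) return(0)
  nr <- nrow(mask)
  lab <- matrix(0L, nr, ncol(mask))
  best <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    stack <- s
    size <- 0L
    while (length(stack)) {
      k <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[k] != 0L) next
      lab[k] <- 1L
      size <- size + 1L
      i <- (k - 1L) %% nr + 1L
      nb <- c(if (i > 1L) k - 1L, if (i < nr) k + 1L,
              k - nr, k + nr)
      nb <- nb[nb >= 1L & nb <= length(mask)]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) stack <- c(stack, nb)
    }
    if (size > best) best <- size
  }
  best / tot
}
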