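#' Bistable reaction term
#'
#' The cubic production function `f(u) = a u (1 - u)(u - gamma)` of the cell
#' density equation. Its roots 0 and 1 are the stable rest states of the
#' space-free kinetics (no cells / confluent cells) and `gamma` is the
#' unstable threshold separating their basins.
#'
#' @param u Cell density; any numeric vector, matrix or array (evaluated
#'   elementwise).
#' @param p A [ks_params()] object.
#' @return Reaction rate, same shape as `u`.
#' @export
reaction_f <- function(u, p) {
  p$a * u * (1 - u) * (u - p$gamma)
}

#' Derivative of the reaction term
#'
#' Exact derivative `f'(u) = a (-3 u^2 + 2 (1 + gamma) u - gamma)` of
#' [reaction_f()], used for Jacobians and eigenvalue-based stability labels.
#'
#' @inheritParams reaction_f
#' @return `f'(u)`, same shape as `u`.
#' @export
reaction_f_prime <- function(u, p) {
  p$a * (-3 * u^2 + 2 * (1 + p$gamma) * u - p$gamma)
}

#' Right-hand side of the space-free kinetics
#'
#' The two-dimensional ODE obtained by dropping all spatial terms:
#' `u' = f(u)`, `v' = c u - e v`.
#'
#' @param state Numeric vector `c(u, v)`.
#' @param p A [ks_params()] object.
#' @return Numeric vector `c(du_dt, dv_dt)`.
#' @export
ode2_rhs <- function(state, p) {
  c(reaction_f(state[1], p), p$c * state[1] - p$e * state[2])
}

#' Equilibria of the space-free kinetics
#'
#' The space-free system has exactly three stationary points:
#' `(0, 0)`, `(gamma, c gamma / e)` and `(1, c / e)`. The Jacobian is lower
#' triangular, so each equilibrium has eigenvalues `f'(u*)` and `-e`.
#' The outer equilibria are stable nodes and the middle one is a saddle
#' whose stable manifold is the line `u = gamma`.
#'
#' @param p A [ks_params()] object.
#' @param tol Magnitude below which an eigenvalue is treated as zero and the
#'   point labelled `"non-hyperbolic"`.
#' @return A data.frame with one row per equilibrium and columns
#'   `u`, `v`, `eig1` (`f'(u*)`), `eig2` (`-e`), `label`.
#' @examples
#' ode2_equilibria(ks_params(gamma = 0.25))
#' @export
ode2_equilibria <- function(p, tol = 1e-10) {
  u <- c(0, p$gamma, 1)
  v <- p$c * u / p$e
  eig1 <- reaction_f_prime(u, p)
  eig2 <- rep(-p$e, 3)
  label <- mapply(function(e1, e2) {
    if (abs(e1) < tol || abs(e2) < tol) return("non-hyperbolic")
    if (e1 < 0 && e2 < 0) return("stable node")
    if (e1 > 0 && e2 > 0) return("unstable node")
    "saddle"
  }, eig1, eig2)
  data.frame(u = u, v = v, eig1 = eig1, eig2 = eig2, label = label,
             stringsAsFactors = FALSE)
}

#' Predict the limit equilibrium of the space-free kinetics
#'
#' Classifies an initial cell density by the basin it belongs to: densities
#' below the threshold `gamma` decay to the empty state, densities above it
#' grow to the confluent state, and `u0 = gamma` sits exactly on the stable
#' manifold of the saddle.
#'
#' @param u0 Initial cell density, >= 0.
#' @param p A [ks_params()] object.
#' @return Numeric vector `c(u, v)` of the predicted limit equilibrium.
#' @export
ode2_classify_basin <- function(u0, p) {
  if (!is.numeric(u0) || length(u0) != 1 || !is.finite(u0)) {
    stop("u0 must be a finite scalar")
  }
  if (u0 < 0) stop("u0 must be nonnegative")
  if (u0 < p$gamma) return(c(u = 0, v = 0))
  if (u0 == p$gamma) return(c(u = p$gamma, v = p$c * p$gamma / p$e))
  c(u = 1, v = p$c / p$e)
}

#' Classical fourth-order Runge-Kutta integration
#'
#' Fixed-step RK4 for a first-order system `y' = rhs(y)`. `y` may be a
#' vector or a matrix of stacked states (one state per row) provided `rhs`
#' is vectorized accordingly; this is how the basin and orbit property
#' checks integrate hundreds of initial conditions at once.
#'
#' @param rhs Function of one argument returning the derivative with the
#'   same shape as its input.
#' @param y0 Initial state (vector or matrix).
#' @param t_end Final time.
#' @param dt Step size (default 0.01); the last step is shortened to land
#'   exactly on `t_end`.
#' @param keep Either `"final"` (default) to return only the final state, or
#'   `"all"` to return the list of states at every step.
#' @return Final state, or `list(times, states)` when `keep = "all"`.
#' @export
rk4_integrate <- function(rhs, y0, t_end, dt = 0.01, keep = c("final", "all")) {
  keep <- match.arg(keep)
  nsteps <- ceiling(t_end / dt - 1e-12)
  y <- y0
  if (keep == "all") {
    times <- numeric(nsteps + 1)
    states <- vector("list", nsteps + 1)
    states[[1]] <- y
  }
  t <- 0
  for (s in seq_len(nsteps)) {
    step <- min(dt, t_end - t)
    k1 <- rhs(y)
    k2 <- rhs(y + step / 2 * k1)
    k3 <- rhs(y + step / 2 * k2)
    k4 <- rhs(y + step * k3)
    y <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + step
    if (keep == "all") {
      times[s + 1] <- t
      states[[s + 1]] <- y
    }
  }
  if (keep == "all") list(times = times, states = states) else y
}
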