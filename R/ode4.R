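#' Right-hand side of the reduced 4D coupled model
#'
#' Two-cell caricature of the PDE: two (cell density, chemoattractant)
#' compartments coupled by discrete diffusion `du (u2 - u1)`,
#' `dv (v2 - v1)` and a chemotaxis-like exchange `-b u1 (v2 - v1)`:
#'
#' \preformatted{
#'   u1' = f(u1) - b u1 (v2 - v1) + du (u2 - u1)
#'   v1' = c u1 - e v1 + dv (v2 - v1)
#'   u2' = f(u2) - b u2 (v1 - v2) + du (u1 - u2)
#'   v2' = c u2 - e v2 + dv (v1 - v2)
#' }
#'
#' The system is equivariant under swapping the two compartments.
#'
#' @param s State vector `c(u1, v1, u2, v2)`, or a matrix of stacked states
#'   (one per row).
#' @param p A [ks_params()] object.
#' @param b Chemotactic sensitivity override (default `p$b`); the reduced
#'   model is studied over `b` in \[10, 25\].
#' @return Derivative with the same shape as `s`.
#' @export
ode4_rhs <- function(s, p, b = p$b) {
  if (is.matrix(s)) {
    u1 <- s[, 1]; v1 <- s[, 2]; u2 <- s[, 3]; v2 <- s[, 4]
    cbind(reaction_f(u1, p) - b * u1 * (v2 - v1) + p$du * (u2 - u1),
          p$c * u1 - p$e * v1 + p$dv * (v2 - v1),
          reaction_f(u2, p) - b * u2 * (v1 - v2) + p$du * (u1 - u2),
          p$c * u2 - p$e * v2 + p$dv * (v1 - v2))
  } else {
    u1 <- s[1]; v1 <- s[2]; u2 <- s[3]; v2 <- s[4]
    c(reaction_f(u1, p) - b * u1 * (v2 - v1) + p$du * (u2 - u1),
      p$c * u1 - p$e * v1 + p$dv * (v2 - v1),
      reaction_f(u2, p) - b * u2 * (v1 - v2) + p$du * (u1 - u2),
      p$c * u2 - p$e * v2 + p$dv * (v1 - v2))
  }
}

#' Swap the two compartments of a 4D state
#' @param s State `c(u1, v1, u2, v2)` or matrix of states.
#' @return The swapped state(s) `(u2, v2, u1, v1)`.
#' @export
swap_state <- function(s) {
  if (is.matrix(s)) s[, c(3, 4, 1, 2), drop = FALSE] else s[c(3, 4, 1, 2)]
}

#' Linear response of the stationary chemoattractant pair
#'
#' At a stationary state the chemoattractant equations are linear in
#' `(v1, v2)`:
#' `(e + dv) v1 - dv v2 = c u1` and `-dv v1 + (e + dv) v2 = c u2`,
#' whose unique solution is `v1 = alpha1 u1 + alpha2 u2` (and symmetrically
#' for `v2`) with
#' `alpha1 = c (e + dv) / ((e + dv)^2 - dv^2)` and
#' `alpha2 = c dv / ((e + dv)^2 - dv^2)`.
#'
#' @param p A [ks_params()] object (needs `e > 0`).
#' @return A list with `alpha1`, `alpha2` (`alpha1 > alpha2 > 0`).
#' @export
alphas <- function(p) {
  if (p$e <= 0) stop("e must be positive (stationary v-system is singular)")
  det <- (p$e + p$dv)^2 - p$dv^2
  list(alpha1 = p$c * (p$e + p$dv) / det, alpha2 = p$c * p$dv / det)
}

#' Scalar fixed-point map of the reduced model
#'
#' Eliminating the stationary chemoattractants via [alphas()] reduces the
#' first stationary equation to `u2 = phi(u1)` with
#' `phi(u) = u + f(u) / (b u (alpha1 - alpha2) - du)`, and stationary states
#' are exactly the solutions of `u1 = phi(phi(u1))`. The map has a singular
#' abscissa at `u = du / (b (alpha1 - alpha2))` where the denominator
#' vanishes.
#'
#' @param u1 Cell density (vectorized).
#' @param p A [ks_params()] object.
#' @param b Sensitivity override (default `p$b`).
#' @param ap Precomputed [alphas()] (optional).
#' @param tol Denominators smaller than `tol` in magnitude are flagged: the
#'   value is returned as `NA`.
#' @return `phi(u1)` with `NA` at near-singular abscissae.
#' @export
phi <- function(u1, p, b = p$b, ap = alphas(p), tol = 1e-8) {
  den <- b * u1 * (ap$alpha1 - ap$alpha2) - p$du
  out <- u1 + reaction_f(u1, p) / den
  out[abs(den) < tol] <- NA_real_
  out
}

# analytic Jacobian of ode4_rhs at state s
ode4_jacobian <- function(s, p, b = p$b) {
  u1 <- s[1]; v1 <- s[2]; u2 <- s[3]; v2 <- s[4]
  matrix(c(
    reaction_f_prime(u1, p) - b * (v2 - v1) - p$du, b * u1, p$du, -b * u1,
    p$c, -(p$e + p$dv), 0, p$dv,
    p$du, -b * u2, reaction_f_prime(u2, p) - b * (v1 - v2) - p$du, b * u2,
    0, p$dv, p$c, -(p$e + p$dv)
  ), 4, 4, byrow = TRUE)
}

# Newton refinement on the full 4D vector field; returns NULL on failure
ode4_newton <- function(s, p, b = p$b, tol = 1e-13, max_iter = 50) {
  for (k in seq_len(max_iter)) {
    r <- ode4_rhs(s, p, b)
    if (max(abs(r)) < tol) return(s)
    J <- ode4_jacobian(s, p, b)
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    s <- s - step
    if (!all(is.finite(s)) || max(abs(s)) > 1e6) return(NULL)
  }
  if (max(abs(ode4_rhs(s, p, b))) < 1e-10) s else NULL
}

#' Enumerate the equilibria of the reduced 4D model
#'
#' Scans the scalar fixed-point equation `u1 = phi(phi(u1))` on a dense grid
#' over `[0, scan_max]`, brackets sign changes (excluding the singular
#' abscissae of the map), refines each root with `uniroot` followed by a
#' full 4D Newton polish on [ode4_rhs()], reconstructs `(v1, v2)` via
#' [alphas()], de-duplicates, and verifies that every returned state has
#' vector-field residual below `1e-10`.
#'
#' @param p A [ks_params()] object.
#' @param b Sensitivity (default `p$b`).
#' @param scan_max Upper end of the scan interval (default 2; the
#'   asymmetric stable branch slightly exceeds `u = 1`).
#' @param n_grid Number of scan points (default 1e4).
#' @param dedup_tol State-distance tolerance for de-duplication
#'   (default 1e-8).
#' @return A data.frame with columns `u1, v1, u2, v2`, residual `resid`,
#'   the four eigenvalue real parts `re1..re4`, and `label`
#'   (`"stable"` / `"unstable"` / `"marginal"`), sorted by `u1`.
#' @examples
#' p <- ks_params(gamma = 0.25)
#' nrow(find_equilibria(p, b = 10))   # 3
#' @export
find_equilibria <- function(p, b = p$b, scan_max = 2, n_grid = 1e4,
                            dedup_tol = 1e-8) {
  stopifnot(scan_max >= 1.5)
  ap <- alphas(p)
  ug <- seq(0, scan_max, length.out = n_grid)
  g <- ug - phi(phi(ug, p, b, ap), p, b, ap)
  ok <- is.finite(g)

  cands <- list()
  # exact zeros on the grid
  for (i in which(ok & abs(g) == 0)) cands[[length(cands) + 1]] <- ug[i]
  # sign changes between consecutive valid points
  for (i in seq_len(n_grid - 1)) {
    if (!ok[i] || !ok[i + 1]) next
    if (g[i] == 0 || g[i + 1] == 0) next
    if (sign(g[i]) != sign(g[i + 1])) {
      r <- tryCatch(
        suppressWarnings(uniroot(function(u) {
          val <- u - phi(phi(u, p, b, ap), p, b, ap)
          if (!is.finite(val)) NA_real_ else val
        }, c(ug[i], ug[i + 1]), tol = 1e-12)$root),
        error = function(e) NULL)
      if (!is.null(r)) cands[[length(cands) + 1]] <- r
    }
  }

  states <- list()
  for (u1 in cands) {
    u2 <- phi(u1, p, b, ap)
    if (!is.finite(u2)) next
    s0 <- c(u1, ap$alpha1 * u1 + ap$alpha2 * u2,
            u2, ap$alpha1 * u2 + ap$alpha2 * u1)
    s <- ode4_newton(s0, p, b)
    if (is.null(s)) next
    dup <- any(vapply(states, function(q) max(abs(q - s)) < dedup_tol,
                      logical(1)))
    if (!dup) states[[length(states) + 1]] <- s
  }

  if (!length(states)) {
    return(data.frame(u1 = numeric(0), v1 = numeric(0), u2 = numeric(0),
                      v2 = numeric(0), resid = numeric(0),
                      re1 = numeric(0), re2 = numeric(0), re3 = numeric(0),
                      re4 = numeric(0), label = character(0)))
  }
  m <- do.call(rbind, states)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- data.frame(u1 = m[, 1], v1 = m[, 2], u2 = m[, 3], v2 = m[, 4])
  out$resid <- apply(m, 1, function(s) max(abs(ode4_rhs(s, p, b))))
  lab <- t(apply(m, 1, function(s) {
    cl <- classify_stability(s, p, b)
    c(cl$re, cl$label)
  }))
  out$re1 <- as.numeric(lab[, 1]); out$re2 <- as.numeric(lab[, 2])
  out$re3 <- as.numeric(lab[, 3]); out$re4 <- as.numeric(lab[, 4])
  out$label <- lab[, 5]
  out
}

#' Stability of a 4D equilibrium
#'
#' Assembles the analytic 4x4 Jacobian and labels the equilibrium by the
#' eigenvalue real parts: `"stable"` if all are below `-eig_tol`,
#' `"unstable"` if any exceeds `+eig_tol`, otherwise `"marginal"` (near a
#' bifurcation; excluded from stable/unstable counts).
#'
#' @param s Equilibrium state `c(u1, v1, u2, v2)`.
#' @param p A [ks_params()] object.
#' @param b Sensitivity (default `p$b`).
#' @param eig_tol Spectral tolerance (default 1e-10).
#' @return A list with `re` (sorted eigenvalue real parts, decreasing),
#'   `eigenvalues` and `label`.
#' @export
classify_stability <- function(s, p, b = p$b, eig_tol = 1e-10) {
  ev <- eigen(ode4_jacobian(s, p, b), only.values = TRUE)$values
  re <- sort(Re(ev), decreasing = TRUE)
  label <- if (all(re < -eig_tol)) "stable"
           else if (any(re > eig_tol)) "unstable"
           else "marginal"
  list(re = re, eigenvalues = ev, label = label)
}

#' Bifurcation scan in the chemotactic sensitivity
#'
#' Runs [find_equilibria()] and the stability labels over a grid of `b`
#' values and tabulates the counts. At the reference parameters the counts
#' step from 3 (two stable) through 5 (two extra unstable asymmetric
#' states) to 9 (four extra, two of them stable), so four locally stable
#' states — empty, confluent, and an asymmetric high/low pair — coexist at
#' the upper end.
#'
#' @param p A [ks_params()] object.
#' @param b_grid Vector of `b` values (default 31 points over \[10, 25\]).
#' @param ... Passed to [find_equilibria()].
#' @return A data.frame `(b, n_eq, n_stable, n_unstable, n_marginal)` with
#'   the per-`b` equilibrium tables attached as attribute `"equilibria"`.
#' @export
bifurcation_scan <- function(p, b_grid = seq(10, 25, length.out = 31), ...) {
  tabs <- lapply(b_grid, function(b) find_equilibria(p, b = b, ...))
  out <- data.frame(
    b = b_grid,
    n_eq = vapply(tabs, nrow, integer(1)),
    n_stable = vapply(tabs, function(d) sum(d$label == "stable"), integer(1)),
    n_unstable = vapply(tabs, function(d) sum(d$label == "unstable"), integer(1)),
    n_marginal = vapply(tabs, function(d) sum(d$label == "marginal"), integer(1)))
  attr(out, "equilibria") <- tabs
  out
}

#' Heteroclinic orbits leaving the symmetric threshold state
#'
#' Integrates the reduced model from small displacements of the symmetric
#' saddle-type state `(gamma, c gamma/e, gamma, c gamma/e)` along each of
#' its unstable eigendirections (both signs) and classifies the omega-limit
#' by the nearest equilibrium. At `b = 25` the limit set contains the empty
#' state, the confluent state and an asymmetric stable state.
#'
#' @param p A [ks_params()] object.
#' @param b Sensitivity (default 25).
#' @param delta Initial displacement along each eigendirection
#'   (default 1e-6).
#' @param t_max Maximum integration time (default 1000).
#' @param dt RK4 step (default 0.01).
#' @param settle_tol State distance below which an orbit counts as settled
#'   at an equilibrium (default 1e-6).
#' @param path_dt Cadence at which the orbit path is recorded (default 0.5).
#' @return A data.frame with one row per launched orbit: `direction` (index
#'   of the unstable eigendirection), `sign`, the limit state coordinates
#'   `u1, v1, u2, v2`, `limit_label` (stability label of the limit
#'   equilibrium), and `resolved`. Orbit paths are attached as attribute
#'   `"paths"` (list of matrices with a time column).
#' @export
heteroclinic_orbits <- function(p, b = 25, delta = 1e-6, t_max = 1000,
                                dt = 0.01, settle_tol = 1e-6, path_dt = 0.5) {
  eqs <- find_equilibria(p, b = b)
  E <- as.matrix(eqs[, c("u1", "v1", "u2", "v2")])
  sym <- c(p$gamma, p$c * p$gamma / p$e, p$gamma, p$c * p$gamma / p$e)
  i2 <- which.min(apply(E, 1, function(s) max(abs(s - sym))))
  if (max(abs(E[i2, ] - sym)) > 1e-6) {
    stop("symmetric threshold equilibrium not found at this b")
  }
  J <- ode4_jacobian(sym, p, b)
  ed <- eigen(J)
  unstable <- which(Re(ed$values) > 1e-10)
  if (!length(unstable)) stop("threshold state has no unstable direction")

  stable_idx <- which(eqs$label == "stable")
  rows <- list(); paths <- list()
  every <- max(1L, as.integer(round(path_dt / dt)))
  for (d in seq_along(unstable)) {
    w <- Re(ed$vectors[, unstable[d]])
    w <- w / sqrt(sum(w^2))
    for (sgn in c(1, -1)) {
      s <- sym + sgn * delta * w
      t <- 0; settled <- FALSE; limit <- NA
      path <- list(c(0, s))
      nstep <- as.integer(ceiling(t_max / dt))
      for (k in seq_len(nstep)) {
        k1 <- ode4_rhs(s, p, b)
        k2 <- ode4_rhs(s + dt / 2 * k1, p, b)
        k3 <- ode4_rhs(s + dt / 2 * k2, p, b)
        k4 <- ode4_rhs(s + dt * k3, p, b)
        s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        t <- t + dt
        if (k %% every == 0) path[[length(path) + 1]] <- c(t, s)
        if (k %% 10 == 0 && length(stable_idx)) {
          dists <- apply(E[stable_idx, , drop = FALSE], 1,
                         function(q) max(abs(q - s)))
          if (min(dists) < settle_tol) {
            settled <- TRUE
            limit <- stable_idx[which.min(dists)]
            break
          }
        }
      }
      if (!settled) {
        dists <- apply(E, 1, function(q) max(abs(q - s)))
        limit <- which.min(dists)
        settled <- dists[limit] < settle_tol
      }
      rows[[length(rows) + 1]] <- data.frame(
        direction = d, sign = sgn,
        u1 = E[limit, 1], v1 = E[limit, 2], u2 = E[limit, 3], v2 = E[limit, 4],
        limit_label = eqs$label[limit], resolved = settled)
      pm <- do.call(rbind, path)
      colnames(pm) <- c("t", "u1", "v1", "u2", "v2")
      paths[[length(paths) + 1]] <- pm
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "paths") <- paths
  attr(out, "equilibria") <- eqs
  out
}
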