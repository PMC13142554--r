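#' Synthetic frame-pair fixtures with known chemoattractant
#'
#' Generates self-contained test problems for the inverse solver; the real
#' microscopy frames behind the data-driven reconstruction are not publicly
#' deposited, so every consumer of [solve_v()] is exercised on synthetic
#' data with a known answer.
#'
#' * `"gaussian-bumps"`: a smooth strictly positive density
#'   `u = 0.2 + mixture of Gaussian bumps`, a mean-zero ground-truth field
#'   `v*` built as the difference of two Gaussian bumps, and
#'   `u_next = u + frame_dt * (f(u) - b div(u grad v*) + du lap(u))` — one
#'   exact forward Euler step, so the elliptic solve must recover `v*` to
#'   solver tolerance.
#' * `"simulated-network"`: two consecutive snapshots of a short
#'   network-regime (`gamma = 0.25`) forward simulation plus the simulator's
#'   chemoattractant field at the first snapshot. Here the pair only
#'   approximately satisfies the one-step relation (the simulator uses RK4
#'   and `v` evolves), so reconstructions are qualitative, not exact.
#'
#' Bump centers and widths are drawn from the seeded RNG; a fixed seed gives
#' bit-identical fixtures.
#'
#' @param kind `"gaussian-bumps"` or `"simulated-network"`.
#' @param seed RNG seed.
#' @param params A [ks_params()] object.
#' @param nx,ny Grid size (default 64 x 64).
#' @param frame_dt Time between the frames (default 0.05 — small enough to
#'   keep the Euler-updated density positive).
#' @param n_bumps Number of density bumps for `"gaussian-bumps"`
#'   (default 3).
#' @return A list with `pair` (a [frame_pair()]), `v_true` (mean-zero matrix;
#'   for `"simulated-network"` the simulator's `v` with its mean removed),
#'   and `kind`.
#' @export
make_fixture_framepair <- function(kind = c("gaussian-bumps", "simulated-network"),
                                   seed = 1L, params = ks_params(),
                                   nx = 64, ny = 64, frame_dt = 0.05,
                                   n_bumps = 3) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "gaussian-bumps") {
    xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
    ys <- matrix(rep(seq_len(ny), nx), ny, nx)
    bump <- function(cx, cy, s, amp) amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
    u <- matrix(0.2, ny, nx)
    for (k in seq_len(n_bumps)) {
      u <- u + bump(runif(1, 0.2, 0.8) * nx, runif(1, 0.2, 0.8) * ny,
                    runif(1, 0.08, 0.15) * nx, runif(1, 0.3, 0.6))
    }
    v <- bump(runif(1, 0.25, 0.45) * nx, runif(1, 0.25, 0.45) * ny,
              runif(1, 0.1, 0.18) * nx, 1) -
         bump(runif(1, 0.55, 0.75) * nx, runif(1, 0.55, 0.75) * ny,
              runif(1, 0.1, 0.18) * nx, 1)
    v <- v - mean(v)
    p <- params
    u_next <- u + frame_dt * (reaction_f(u, p) -
                                p$b * cpp_chemotaxis_div(u, v, p$h) +
                                p$du * cpp_laplacian(u, p$h))
    list(pair = frame_pair(u, u_next, p, frame_dt), v_true = v, kind = kind)
  } else {
    p <- params
    p$gamma <- 0.25
    cfg <- sim_config(p, nx = nx, ny = ny,
                      t_end = 5 + frame_dt,
                      snapshot_times = c(5, 5 + frame_dt), seed = seed)
    traj <- simulate_ks(cfg)
    u1 <- pmax(traj$u[[1]], 1e-3)
    u2 <- traj$u[[2]]
    v1 <- traj$v[[1]]
    list(pair = frame_pair(u1, u2, p, frame_dt),
         v_true = v1 - mean(v1), kind = kind)
  }
}
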