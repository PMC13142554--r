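#' Frame pair for the inverse problem
#'
#' Bundles two consecutive cell-density frames with the model parameters.
#' Given frames `u(t)` and `u(t+dt)`, the unknown chemoattractant field
#' satisfies the elliptic equation
#' `-div(u grad v) = (1/b) [ (u(t+dt) - u(t))/dt - f(u(t)) - du lap(u(t)) ]`,
#' solvable up to an additive constant provided `u > 0` everywhere.
#'
#' @param u_t,u_next Numeric matrices, matching shapes; `u_t` must be
#'   strictly positive (preprocess raw images with [preprocess_frame()]).
#' @param params A [ks_params()] object.
#' @param frame_dt Time between the frames in model units (default 1, the
#'   unit step of the discrete-time formulation).
#' @return An object of class `ks_frame_pair`.
#' @export
frame_pair <- function(u_t, u_next, params = ks_params(), frame_dt = 1) {
  check_field(u_t); check_same_shape(u_t, u_next)
  stopifnot(inherits(params, "ks_params"), frame_dt > 0)
  if (min(u_t) <= 0) {
    stop("u_t must be strictly positive (ellipticity); floor it via preprocess_frame()")
  }
  structure(list(u_t = u_t, u_next = u_next, params = params,
                 frame_dt = frame_dt),
            class = "ks_frame_pair")
}

#' Prepare a grayscale raster as a density field
#'
#' Min-max rescales an image to \[0, 1\], optionally applies a separable
#' Gaussian blur (mirrored at the boundary, matching the zero-flux
#' convention), then floors the result at `floor` so the field is strictly
#' positive as the elliptic solve requires.
#'
#' @param image Numeric matrix (any range); constant images are rejected.
#' @param floor Positivity floor (default 1e-3).
#' @param smooth_sigma Gaussian standard deviation in cells; 0 (default)
#'   disables smoothing.
#' @return A strictly positive numeric matrix with values in `[floor, 1]`.
#' @export
preprocess_frame <- function(image, floor = 1e-3, smooth_sigma = 0) {
  if (!is.matrix(image) || !is.numeric(image)) stop("image must be a numeric matrix")
  rng <- range(image)
  if (diff(rng) == 0) stop("constant image: degenerate rescale")
  x <- (image - rng[1]) / (rng[2] - rng[1])
  if (smooth_sigma > 0) x <- gaussian_blur(x, smooth_sigma)
  pmax(x, floor)
}

# separable Gaussian blur with mirrored (replicated edge) boundary
gaussian_blur <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {   # along rows (down columns)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in seq(-r, r)) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- out + k[o + r + 1] * m[idx, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(x))))
}

#' Right-hand side of the elliptic inverse problem
#'
#' Assembles `r = (1/b) [ (u_next - u_t)/frame_dt - f(u_t) - du lap(u_t) ]`
#' and removes its mean, the compatibility condition for an operator whose
#' nullspace is the constants.
#'
#' @param pair A [frame_pair()].
#' @return Numeric matrix with mean exactly zero (to round-off).
#' @export
assemble_rhs <- function(pair) {
  stopifnot(inherits(pair, "ks_frame_pair"))
  p <- pair$params
  r <- ((pair$u_next - pair$u_t) / pair$frame_dt -
          reaction_f(pair$u_t, p) -
          p$du * cpp_laplacian(pair$u_t, p$h)) / p$b
  r - mean(r)
}

#' Sparse elliptic operator of the inverse problem
#'
#' Builds the symmetric positive semi-definite 5-point operator
#' `A v = -div(u grad v)` in conservative form: each interior face carries
#' conductance `mean(u_left, u_right)/h^2` and boundary faces are dropped
#' (zero flux). For `u > 0` the kernel is exactly the constant fields.
#' With `u = 1` the operator is the negated zero-flux Laplacian.
#'
#' @param u Strictly positive numeric matrix.
#' @param h Grid spacing (default 1).
#' @return A `dgCMatrix` of dimension `(nr*nc) x (nr*nc)` acting on fields
#'   flattened column-major (`as.vector`).
#' @export
assemble_operator <- function(u, h = 1) {
  check_field(u)
  if (min(u) <= 0) stop("u must be strictly positive")
  nr <- nrow(u); nc <- ncol(u)
  id <- matrix(seq_len(nr * nc), nr, nc)
  ih2 <- 1 / h^2

  # vertical faces (between rows i, i+1)
  a1 <- id[-nr, ]; b1 <- id[-1, ]
  w1 <- (u[-nr, ] + u[-1, ]) / 2 * ih2
  # horizontal faces (between columns j, j+1)
  a2 <- id[, -nc]; b2 <- id[, -1]
  w2 <- (u[, -nc] + u[, -1]) / 2 * ih2

  i <- c(as.vector(a1), as.vector(b1), as.vector(a1), as.vector(b1),
         as.vector(a2), as.vector(b2), as.vector(a2), as.vector(b2))
  j <- c(as.vector(a1), as.vector(b1), as.vector(b1), as.vector(a1),
         as.vector(a2), as.vector(b2), as.vector(b2), as.vector(a2))
  w <- c(as.vector(w1), as.vector(w1), -as.vector(w1), -as.vector(w1),
         as.vector(w2), as.vector(w2), -as.vector(w2), -as.vector(w2))
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(nr * nc, nr * nc))
}

#' Reconstruct the chemoattractant field from a frame pair
#'
#' Solves `A v = r` by a Krylov minimal-residual iteration, where
#' `A = -div(u grad v)` from [assemble_operator()] and `r` from
#' [assemble_rhs()]. Because the conservative discretization is symmetric,
#' the default solver is [minres()] (restart-free, short recurrence);
#' restarted [gmres()] is available as an option. The solution is only
#' defined up to an additive constant; the gauge is fixed by projecting the
#' right-hand side and the solution to mean zero. Starting from a zero (or
#' any constant-shifted) initial guess, the Krylov iterates remain mean-zero
#' automatically; a final projection removes round-off drift.
#'
#' @param pair A [frame_pair()].
#' @param tol Relative-residual tolerance (default 1e-8).
#' @param max_iter Maximum matrix-vector products (default 5000).
#' @param restart GMRES restart length (default 50; ignored by MINRES).
#' @param method `"minres"` (default) or `"gmres"`.
#' @return An object of class `ks_reconstruction`: list with `v` (mean-zero
#'   matrix), `relres`, `iterations`, `converged`.
#' @examples
#' fx <- make_fixture_framepair("gaussian-bumps", seed = 1, nx = 24, ny = 24)
#' rec <- solve_v(fx$pair, tol = 1e-10)
#' max(abs(rec$v - fx$v_true)) / max(abs(fx$v_true))
#' @export
solve_v <- function(pair, tol = 1e-8, max_iter = 5000, restart = 50,
                    method = c("minres", "gmres")) {
  method <- match.arg(method)
  stopifnot(inherits(pair, "ks_frame_pair"))
  r <- assemble_rhs(pair)
  A <- assemble_operator(pair$u_t, pair$params$h)
  sol <- if (method == "minres") {
    minres(A, as.vector(r), tol = tol, max_iter = max_iter)
  } else {
    gmres(A, as.vector(r), tol = tol, restart = restart,
          max_iter = max_iter)
  }
  v <- matrix(sol$x, nrow(r), ncol(r))
  v <- v - mean(v)
  structure(list(v = v, relres = sol$relres, iterations = sol$iterations,
                 converged = sol$converged),
            class = "ks_reconstruction")
}

#' @export
print.ks_reconstruction <- function(x, ...) {
  cat(sprintf("Chemoattractant reconstruction: %dx%d, relres=%.3g, %d matvecs, %s\n",
              nrow(x$v), ncol(x$v), x$relres, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Reconstruct a whole frame sequence
#'
#' Applies [solve_v()] to every consecutive pair of an ordered frame list;
#' per-pair failures are recorded in the returned metadata rather than
#' aborting the sequence.
#'
#' @param frames List of >= 2 strictly positive matrices of equal shape.
#' @param params A [ks_params()] object.
#' @param frame_dt Time between consecutive frames (default 1).
#' @param ... Passed to [solve_v()].
#' @return A list of `ks_reconstruction` objects of length
#'   `length(frames) - 1`.
#' @export
reconstruct_sequence <- function(frames, params = ks_params(), frame_dt = 1,
                                 ...) {
  stopifnot(is.list(frames), length(frames) >= 2)
  lapply(seq_len(length(frames) - 1), function(k) {
    tryCatch(
      solve_v(frame_pair(frames[[k]], frames[[k + 1]], params, frame_dt), ...),
      error = function(e) {
        structure(list(v = NULL, relres = NA_real_, iterations = NA_integer_,
                       converged = FALSE, error = conditionMessage(e)),
                  class = "ks_reconstruction")
      })
  })
}
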