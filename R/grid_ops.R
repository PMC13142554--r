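#' Discrete spatial operators with zero-flux boundaries
#'
#' Cell-centered 5-point finite-difference operators on a rectangular grid.
#' Zero-flux (Neumann) boundaries are imposed by mirrored ghost cells: the
#' ghost value beyond a boundary cell equals the boundary cell itself, which
#' preserves the summation-by-parts structure of the stencils, so
#' `sum(laplacian(f))` and `sum(chemotaxis_div(u, v))` vanish exactly
#' (to round-off) for any field.
#'
#' * `laplacian(f)`: `(f[i+1,j] + f[i-1,j] + f[i,j+1] + f[i,j-1] - 4 f[i,j]) / h^2`.
#' * `grad_dot(f, g)`: pointwise inner product of the central-difference
#'   gradients of `f` and `g`.
#' * `chemotaxis_div(u, v)`: the conservative discretization of
#'   `div(u grad v)`; each face carries flux
#'   `mean(u_left, u_right) * (v_right - v_left) / h`, and boundary faces
#'   carry none. With constant `u = k` it reduces exactly to
#'   `k * laplacian(v)`.
#'
#' @param f,g,u,v Numeric matrices of identical dimensions, at least 3 in
#'   each direction.
#' @param h Grid spacing (default 1).
#' @return A numeric matrix of the same shape.
#' @examples
#' f <- matrix(rnorm(25), 5, 5)
#' sum(laplacian(f))          # 0 to round-off
#' @export
laplacian <- function(f, h = 1) {
  check_field(f)
  cpp_laplacian(f, h)
}

#' @rdname laplacian
#' @export
grad_dot <- function(f, g, h = 1) {
  check_field(f)
  check_same_shape(f, g)
  cpp_grad_dot(f, g, h)
}

#' @rdname laplacian
#' @param scheme Face-density scheme for `chemotaxis_div`: `"arithmetic"`
#'   (default, second-order) or `"upwind"` (donor cell against the drift
#'   direction `b grad v`; first-order but positivity-robust near sharp
#'   fronts).
#' @export
chemotaxis_div <- function(u, v, h = 1, scheme = c("arithmetic", "upwind")) {
  scheme <- match.arg(scheme)
  check_field(u)
  check_same_shape(u, v)
  cpp_chemotaxis_div(u, v, h, upwind = as.integer(scheme == "upwind"))
}

check_field <- function(f) {
  if (!is.matrix(f) || !is.numeric(f)) stop("field must be a numeric matrix")
  if (nrow(f) < 3 || ncol(f) < 3) stop("field must be at least 3 x 3")
  if (!all(is.finite(f))) stop("field contains non-finite entries")
  invisible(f)
}

check_same_shape <- function(a, b) {
  if (!is.matrix(b) || !all(dim(a) == dim(b))) {
    stop("fields must be numeric matrices with matching dimensions")
  }
  if (!all(is.finite(b))) stop("field contains non-finite entries")
  invisible(b)
}
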