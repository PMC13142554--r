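#' Model parameters
#'
#' Container for the scalar constants of the modified Keller-Segel system
#' and its reductions. The defaults are the reference parameter set used
#' throughout the package: `a = 7`, `b = 10`, `c = 3`, `e = 2`, `du = 1`,
#' `dv = 10`, with unit grid spacing.
#'
#' @param a Reaction amplitude of the bistable cubic `f(u) = a u (1-u)(u-gamma)`
#'   (dimensionless, > 0).
#' @param b Chemotactic sensitivity (> 0); scales the transport term
#'   `-b div(u grad v)`.
#' @param c Chemoattractant production rate (> 0).
#' @param e Chemoattractant decay rate (> 0); must be positive so the
#'   stationary chemoattractant level `c u / e` is defined.
#' @param du Cell diffusivity (>= 0).
#' @param dv Chemoattractant diffusivity (>= 0).
#' @param gamma Unstable root of the reaction cubic, in (0, 1). Separates the
#'   basins of the rest states `u = 0` and `u = 1`.
#' @param h Grid spacing (length, > 0, default 1).
#'
#' @return An object of class `ks_params`: a named list with the eight
#'   validated constants.
#' @examples
#' p <- ks_params(gamma = 0.25)
#' p$a
#' @export
ks_params <- function(a = 7, b = 10, c = 3, e = 2, du = 1, dv = 10,
                      gamma = 0.25, h = 1) {
  p <- list(a = a, b = b, c = c, e = e, du = du, dv = dv,
            gamma = gamma, h = h)
  validate_ks_params(p)
}

validate_ks_params <- function(p) {
  need <- c("a", "b", "c", "e", "du", "dv", "gamma", "h")
  if (!all(need %in% names(p))) {
    stop("missing parameter field(s): ",
         paste(setdiff(need, names(p)), collapse = ", "))
  }
  p <- p[need]
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) stop("all parameters must be finite scalars")
  if (p$gamma <= 0 || p$gamma >= 1) stop("gamma must lie strictly in (0, 1)")
  if (p$a <= 0 || p$b <= 0 || p$c <= 0) stop("a, b, c must be positive")
  if (p$e <= 0) stop("e must be positive (v-equilibria are c*u/e)")
  if (p$du < 0 || p$dv < 0) stop("diffusivities du, dv must be nonnegative")
  if (p$h <= 0) stop("grid spacing h must be positive")
  structure(p, class = "ks_params")
}

#' @export
print.ks_params <- function(x, ...) {
  cat("Modified Keller-Segel parameters:\n")
  cat(sprintf("  a=%g b=%g c=%g e=%g du=%g dv=%g gamma=%g h=%g\n",
              x$a, x$b, x$c, x$e, x$du, x$dv, x$gamma, x$h))
  invisible(x)
}

#' Read or write a parameter set as JSON
#'
#' The file holds exactly the keys `a, b, c, e, du, dv, gamma, h`; unknown
#' keys are rejected and missing keys are filled from the defaults of
#' [ks_params()].
#'
#' @param path File path.
#' @param p A `ks_params` object.
#' @return `read_params()` returns a validated `ks_params`;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(raw), c("a", "b", "c", "e", "du", "dv", "gamma", "h"))
  if (length(extra)) stop("unknown parameter key(s): ", paste(extra, collapse = ", "))
  do.call(ks_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "ks_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
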