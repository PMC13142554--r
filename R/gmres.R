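#' Restarted GMRES
#'
#' Generalized Minimal Residual iteration with restarts, implemented with
#' Arnoldi orthogonalization (modified Gram-Schmidt) and Givens rotations on
#' the Hessenberg factor. Written for the elliptic chemoattractant solve but
#' usable with any square operator supplied as a matrix, a sparse
#' `Matrix`, or a matrix-vector product function.
#'
#' @param A Square matrix, sparse matrix or `function(x)` returning `A x`.
#' @param b Right-hand side vector.
#' @param x0 Initial guess (default zero).
#' @param tol Convergence tolerance on the relative residual
#'   `||b - A x|| / ||b||` (default 1e-8).
#' @param restart Krylov subspace dimension between restarts (default 50).
#' @param max_iter Maximum total matrix-vector products (default 5000).
#' @return A list with `x`, `relres` (achieved relative residual),
#'   `iterations` (matvec count), `converged`, and `resvec` (relative
#'   residual after each restart cycle).
#' @export
gmres <- function(A, b, x0 = NULL, tol = 1e-8, restart = 50, max_iter = 5000) {
  matvec <- if (is.function(A)) A else function(x) as.vector(A %*% x)
  n <- length(b)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(list(x = numeric(n), relres = 0, iterations = 0L,
                converged = TRUE, resvec = numeric(0)))
  }
  iter <- 0L
  resvec <- numeric(0)
  converged <- FALSE

  while (iter < max_iter && !converged) {
    r <- b - matvec(x)
    beta <- sqrt(sum(r^2))
    if (beta / bnorm <= tol) { converged <- TRUE; break }
    m <- min(restart, max_iter - iter)
    V <- matrix(0, n, m + 1)
    H <- matrix(0, m + 1, m)
    cs <- numeric(m); sn <- numeric(m)
    g <- numeric(m + 1); g[1] <- beta
    V[, 1] <- r / beta
    k_used <- 0L
    for (k in seq_len(m)) {
      w <- matvec(V[, k])
      iter <- iter + 1L
      for (i in seq_len(k)) {          # modified Gram-Schmidt
        H[i, k] <- sum(w * V[, i])
        w <- w - H[i, k] * V[, i]
      }
      H[k + 1, k] <- sqrt(sum(w^2))
      if (H[k + 1, k] > 0) V[, k + 1] <- w / H[k + 1, k]
      # apply previous Givens rotations to the new column
      if (k > 1) for (i in seq_len(k - 1)) {
        t1 <- cs[i] * H[i, k] + sn[i] * H[i + 1, k]
        H[i + 1, k] <- -sn[i] * H[i, k] + cs[i] * H[i + 1, k]
        H[i, k] <- t1
      }
      # new rotation annihilating H[k+1, k]
      denom <- sqrt(H[k, k]^2 + H[k + 1, k]^2)
      if (denom == 0) { cs[k] <- 1; sn[k] <- 0 } else {
        cs[k] <- H[k, k] / denom; sn[k] <- H[k + 1, k] / denom
      }
      H[k, k] <- cs[k] * H[k, k] + sn[k] * H[k + 1, k]
      H[k + 1, k] <- 0
      g[k + 1] <- -sn[k] * g[k]
      g[k] <- cs[k] * g[k]
      k_used <- k
      if (abs(g[k + 1]) / bnorm <= tol) { converged <- TRUE; break }
      if (H[k + 1, k] == 0 && abs(g[k + 1]) > 0 && k < m) break  # breakdown
    }
    if (k_used > 0) {
      y <- backsolve(H[seq_len(k_used), seq_len(k_used), drop = FALSE],
                     g[seq_len(k_used)])
      x <- x + V[, seq_len(k_used), drop = FALSE] %*% y
      x <- as.vector(x)
    }
    relres <- sqrt(sum((b - matvec(x))^2)) / bnorm
    resvec <- c(resvec, relres)
    if (relres <= tol) converged <- TRUE
  }
  relres <- sqrt(sum((b - matvec(x))^2)) / bnorm
  list(x = x, relres = relres, iterations = iter,
       converged = converged || relres <= tol, resvec = resvec)
}

#' MINRES for symmetric (possibly singular) systems
#'
#' Minimal-residual iteration of Paige-Saunders type: the Lanczos
#' three-term recurrence replaces Arnoldi, so no restart is needed and
#' memory stays O(n). For a symmetric positive semi-definite operator with
#' a consistent right-hand side (the elliptic chemoattractant solve) this
#' converges where short-restart GMRES stagnates, while minimizing the same
#' residual norm per Krylov dimension.
#'
#' @inheritParams gmres
#' @return Same structure as [gmres()]: list with `x`, `relres`,
#'   `iterations`, `converged`, `resvec` (relative residual per iteration).
#' @export
minres <- function(A, b, x0 = NULL, tol = 1e-8, max_iter = 5000) {
  matvec <- if (is.function(A)) A else function(x) as.vector(A %*% x)
  n <- length(b)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(list(x = numeric(n), relres = 0, iterations = 0L,
                converged = TRUE, resvec = numeric(0)))
  }
  r <- b - matvec(x)
  beta <- sqrt(sum(r^2))
  if (beta / bnorm <= tol) {
    return(list(x = x, relres = beta / bnorm, iterations = 0L,
                converged = TRUE, resvec = numeric(0)))
  }
  v_prev <- numeric(n)
  v <- r / beta
  w0 <- numeric(n); w1 <- numeric(n)
  c0 <- 1; s0 <- 0; c1 <- 1; s1 <- 0
  eta <- beta
  resvec <- numeric(0)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    Av <- matvec(v)
    alpha <- sum(v * Av)
    Av <- Av - alpha * v - beta * v_prev
    beta_new <- sqrt(sum(Av^2))
    # apply the two previous Givens rotations to the new tridiagonal column
    rho1 <- c1 * alpha - c0 * s1 * beta
    rho2 <- s1 * alpha + c0 * c1 * beta
    rho3 <- s0 * beta
    # new rotation annihilating beta_new
    denom <- sqrt(rho1^2 + beta_new^2)
    if (denom == 0) break
    cc <- rho1 / denom; ss <- beta_new / denom
    w <- (v - rho2 * w1 - rho3 * w0) / denom
    x <- x + (cc * eta) * w
    eta <- -ss * eta
    resvec <- c(resvec, abs(eta) / bnorm)
    if (abs(eta) / bnorm <= tol) { converged <- TRUE; break }
    if (beta_new == 0) break   # invariant subspace exhausted
    w0 <- w1; w1 <- w
    v_prev <- v; v <- Av / beta_new
    c0 <- c1; s0 <- s1; c1 <- cc; s1 <- ss
    beta <- beta_new
  }
  relres <- sqrt(sum((b - matvec(x))^2)) / bnorm
  list(x = x, relres = relres, iterations = iter,
       converged = converged || relres <= tol, resvec = resvec)
}
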