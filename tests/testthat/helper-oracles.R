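# Independent reference implementations used as oracles. These are written
# against the mathematical definitions (ghost-padded arrays, dense algebra)
# and deliberately share no code with the package internals.

# pad a matrix with mirrored ghost cells (ghost equals the boundary cell)
pad_mirror <- function(f) {
  f2 <- rbind(f[1, , drop = FALSE], f, f[nrow(f), , drop = FALSE])
  cbind(f2[, 1, drop = FALSE], f2, f2[, ncol(f2), drop = FALSE])
}

ref_laplacian <- function(f, h = 1) {
  g <- pad_mirror(f)
  n <- nrow(f); m <- ncol(f)
  i <- 2:(n + 1); j <- 2:(m + 1)
  (g[i - 1, j] + g[i + 1, j] + g[i, j - 1] + g[i, j + 1] - 4 * g[i, j]) / h^2
}

ref_grad_dot <- function(f, g, h = 1) {
  gx <- function(m) {
    q <- pad_mirror(m); n <- nrow(m); mm <- ncol(m)
    (q[2:(n + 1), 3:(mm + 2)] - q[2:(n + 1), 1:mm]) / (2 * h)
  }
  gy <- function(m) {
    q <- pad_mirror(m); n <- nrow(m); mm <- ncol(m)
    (q[3:(n + 2), 2:(mm + 1)] - q[1:n, 2:(mm + 1)]) / (2 * h)
  }
  gx(f) * gx(g) + gy(f) * gy(g)
}

ref_chemotaxis_div <- function(u, v, h = 1) {
  nr <- nrow(u); nc <- ncol(u)
  d <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (nb[1] < 1 || nb[1] > nr || nb[2] < 1 || nb[2] > nc) next
      w <- (u[i, j] + u[nb[1], nb[2]]) / 2
      acc <- acc + w * (v[nb[1], nb[2]] - v[i, j])
    }
    d[i, j] <- acc / h^2
  }
  d
}

# Brute-force enumeration of 4D equilibria: damped-free Newton from a dense
# lattice of seeds, vectorized across seeds (unpivoted 4x4 elimination;
# seeds that hit a bad pivot or diverge are dropped, which is harmless for
# a search).
brute_force_equilibria <- function(p, b, n_lattice = 20, lo = -0.1, hi = 1.6,
                                   max_iter = 40) {
  g <- seq(lo, hi, length.out = n_lattice)
  S <- as.matrix(expand.grid(u1 = g, v1 = g, u2 = g, v2 = g))
  fp <- function(u) reaction_f_prime(u, p)
  for (it in seq_len(max_iter)) {
    u1 <- S[, 1]; v1 <- S[, 2]; u2 <- S[, 3]; v2 <- S[, 4]
    R <- ode4_rhs(S, p, b)
    a11 <- fp(u1) - b * (v2 - v1) - p$du; a12 <- b * u1
    a13 <- rep(p$du, length(u1));        a14 <- -b * u1
    a21 <- rep(p$c, length(u1)); a22 <- rep(-(p$e + p$dv), length(u1))
    a23 <- rep(0, length(u1));   a24 <- rep(p$dv, length(u1))
    a31 <- a13; a32 <- -b * u2
    a33 <- fp(u2) - b * (v1 - v2) - p$du; a34 <- b * u2
    a41 <- a23; a42 <- a24; a43 <- a21; a44 <- a22
    b1 <- R[, 1]; b2 <- R[, 2]; b3 <- R[, 3]; b4 <- R[, 4]
    # unpivoted Gaussian elimination, vectorized over seeds
    m <- a21 / a11
    a22 <- a22 - m * a12; a23 <- a23 - m * a13; a24 <- a24 - m * a14
    b2 <- b2 - m * b1
    m <- a31 / a11
    a32 <- a32 - m * a12; a33 <- a33 - m * a13; a34 <- a34 - m * a14
    b3 <- b3 - m * b1
    m <- a41 / a11
    a42 <- a42 - m * a12; a43 <- a43 - m * a13; a44 <- a44 - m * a14
    b4 <- b4 - m * b1
    m <- a32 / a22
    a33 <- a33 - m * a23; a34 <- a34 - m * a24; b3 <- b3 - m * b2
    m <- a42 / a22
    a43 <- a43 - m * a23; a44 <- a44 - m * a24; b4 <- b4 - m * b2
    m <- a43 / a33
    a44 <- a44 - m * a34; b4 <- b4 - m * b3
    x4 <- b4 / a44
    x3 <- (b3 - a34 * x4) / a33
    x2 <- (b2 - a23 * x3 - a24 * x4) / a22
    x1 <- (b1 - a12 * x2 - a13 * x3 - a14 * x4) / a11
    S <- S - cbind(x1, x2, x3, x4)
    bad <- !is.finite(S[, 1]) | !is.finite(S[, 2]) |
           !is.finite(S[, 3]) | !is.finite(S[, 4]) |
           apply(abs(S), 1, max) > 10
    if (any(bad)) S <- S[!bad, , drop = FALSE]
    if (!nrow(S)) break
  }
  if (!nrow(S)) return(S)
  res <- apply(abs(ode4_rhs(S, p, b)), 1, max)
  S <- S[res < 1e-10, , drop = FALSE]
  # greedy de-duplication at 1e-6
  uniq <- list()
  for (k in seq_len(nrow(S))) {
    s <- S[k, ]
    if (!any(vapply(uniq, function(q) max(abs(q - s)) < 1e-6, logical(1)))) {
      uniq[[length(uniq) + 1]] <- s
    }
  }
  out <- do.call(rbind, uniq)
  out[order(out[, 1], out[, 3]), , drop = FALSE]
}
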