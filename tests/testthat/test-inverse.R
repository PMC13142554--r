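p_ref <- ks_params()

test_that("frame preprocessing rescales, floors and rejects degenerate input", {
  set.seed(31)
  img <- matrix(runif(64, 10, 250), 8, 8)
  out <- preprocess_frame(img)
  expect_equal(range(out), c(1e-3, 1), tolerance = 1e-10)
  # an image already spanning [0, 1] comes back unchanged (no smoothing)
  img01 <- (img - min(img)) / diff(range(img))
  expect_equal(preprocess_frame(img01), pmax(img01, 1e-3), tolerance = 1e-12)
  # binary mask maps onto the two-point set {floor, 1}
  mask <- matrix(rep(c(0, 1), 18), 6, 6)
  expect_setequal(unique(as.vector(preprocess_frame(mask, floor = 1e-3))),
                  c(1e-3, 1))
  expect_error(preprocess_frame(matrix(5, 4, 4)), "constant image")
  # smoothing keeps the field positive and the shape unchanged
  sm <- preprocess_frame(img, smooth_sigma = 1)
  expect_identical(dim(sm), dim(img))
  expect_gte(min(sm), 1e-3)
})

test_that("elliptic right-hand side: pure reaction update gives zero, affine in u_next", {
  u <- matrix(0.6, 8, 8)
  u_next <- u + 1 * reaction_f(u, p_ref)
  pr <- frame_pair(u, u_next, p_ref, frame_dt = 1)
  expect_equal(assemble_rhs(pr), matrix(0, 8, 8), tolerance = 1e-14)

  set.seed(32)
  u <- matrix(runif(64, 0.2, 1), 8, 8)
  un <- matrix(runif(64, 0.2, 1), 8, 8)
  r1 <- assemble_rhs(frame_pair(u, un, p_ref, frame_dt = 2))
  r2 <- assemble_rhs(frame_pair(u, un + 0.3, p_ref, frame_dt = 2))
  # adding a constant to u_next adds delta/(b dt) minus its mean: no change
  expect_equal(r1, r2, tolerance = 1e-13)
  expect_lt(abs(mean(r1)), 1e-15)
})

test_that("3x3 worked instance matches hand-evaluated stencil formulas", {
  u <- matrix(c(0.5, 0.6, 0.7,
                0.4, 0.5, 0.6,
                0.3, 0.4, 0.5), 3, 3, byrow = TRUE)
  un <- u + 0.1
  pr <- frame_pair(u, un, p_ref, frame_dt = 1)
  raw <- (0.1 - reaction_f(u, p_ref) - p_ref$du * ref_laplacian(u)) / p_ref$b
  expect_equal(assemble_rhs(pr), raw - mean(raw), tolerance = 1e-14)
})

test_that("elliptic operator: nullspace, Laplacian limit, symmetry, spectral gap", {
  u1 <- matrix(1, 6, 5)
  A <- assemble_operator(u1)
  n <- 30
  expect_lt(max(abs(A %*% rep(2.3, n))), 1e-14)
  # u = 1: A equals the negated zero-flux Laplacian, entry by entry
  L <- vapply(seq_len(n), function(k) {
    e <- matrix(0, 6, 5); e[k] <- 1
    as.vector(laplacian(e))
  }, numeric(n))
  expect_equal(as.matrix(A), -L, tolerance = 1e-13, ignore_attr = TRUE)

  set.seed(33)
  u <- matrix(runif(48, 0.2, 2), 8, 6)
  A <- assemble_operator(u, h = 0.5)
  expect_lt(max(abs(A - Matrix::t(A))), 1e-14)
  # kernel is exactly the constants: second-smallest eigenvalue positive
  ev <- eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(abs(ev[48]), 1e-12)
  expect_gt(ev[47], 1e-6)
  expect_error(assemble_operator(u - 1), "strictly positive")
})

test_that("operator action matches the conservative divergence stencil", {
  set.seed(34)
  u <- matrix(runif(63, 0.3, 1.5), 9, 7)
  v <- matrix(rnorm(63), 9, 7)
  A <- assemble_operator(u)
  expect_equal(matrix(as.vector(A %*% as.vector(v)), 9, 7),
               -chemotaxis_div(u, v), tolerance = 1e-12)
})

test_that("gmres solves SPD systems to tolerance and respects max_iter", {
  set.seed(35)
  M <- crossprod(matrix(rnorm(400), 20, 20)) + diag(20)
  b <- rnorm(20)
  sol <- gmres(M, b, tol = 1e-12, restart = 8)
  expect_true(sol$converged)
  expect_equal(sol$x, solve(M, b), tolerance = 1e-8)
  lim <- gmres(M, b, tol = 1e-14, restart = 2, max_iter = 3)
  expect_false(lim$converged)
  expect_lte(lim$iterations, 3L)
})

test_that("minres matches direct solves and is gauge-invariant on the singular operator", {
  set.seed(38)
  M <- crossprod(matrix(rnorm(625), 25, 25)) + diag(25)
  b <- rnorm(25)
  sol <- minres(M, b, tol = 1e-12)
  expect_true(sol$converged)
  expect_equal(sol$x, solve(M, b), tolerance = 1e-8)

  u <- matrix(runif(15 * 15, 0.3, 1.2), 15, 15)
  A <- assemble_operator(u)
  v_true <- as.vector(outer(sin(seq_len(15)), cos(seq_len(15)) / 2))
  v_true <- v_true - mean(v_true)
  rhs <- as.vector(A %*% v_true)
  s0 <- minres(A, rhs, tol = 1e-12)
  s1 <- minres(A, rhs, x0 = rep(7.3, 225), tol = 1e-12)
  dezero <- function(x) x - mean(x)
  expect_equal(dezero(s0$x), v_true, tolerance = 1e-8)
  expect_equal(dezero(s1$x), dezero(s0$x), tolerance = 1e-8)
})

test_that("manufactured chemoattractant is recovered to 1e-6 relative error", {
  fx <- make_fixture_framepair("gaussian-bumps", seed = 2, nx = 32, ny = 32)
  rec <- solve_v(fx$pair, tol = 1e-10)
  expect_true(rec$converged)
  expect_lt(max(abs(rec$v - fx$v_true)) / max(abs(fx$v_true)), 1e-6)
  expect_lt(abs(mean(rec$v)), 1e-12)
})

test_that("zero right-hand side returns the zero field", {
  u <- matrix(0.7, 10, 10)
  pr <- frame_pair(u, u + reaction_f(u, p_ref), p_ref)
  rec <- solve_v(pr)
  expect_equal(rec$v, matrix(0, 10, 10), tolerance = 1e-12)
})

test_that("transposing both frames transposes the reconstruction", {
  fx <- make_fixture_framepair("gaussian-bumps", seed = 4, nx = 20, ny = 28)
  r1 <- solve_v(fx$pair, tol = 1e-10)
  pr_t <- frame_pair(t(fx$pair$u_t), t(fx$pair$u_next), p_ref,
                     fx$pair$frame_dt)
  r2 <- solve_v(pr_t, tol = 1e-10)
  expect_equal(t(r1$v), r2$v, tolerance = 1e-9)
})

test_that("sequence reconstruction handles frozen fields and per-pair failures", {
  set.seed(36)
  nx <- 24
  fx <- make_fixture_framepair("gaussian-bumps", seed = 6, nx = nx, ny = nx)
  v_star <- fx$v_true
  dt <- 0.02
  frames <- list(fx$pair$u_t)
  for (k in 1:3) {
    u <- frames[[k]]
    frames[[k + 1]] <- u + dt * (reaction_f(u, p_ref) -
                                   p_ref$b * chemotaxis_div(u, v_star) +
                                   p_ref$du * laplacian(u))
  }
  recs <- reconstruct_sequence(frames, p_ref, frame_dt = dt, tol = 1e-10)
  expect_length(recs, 3)
  for (r in recs) {
    expect_true(r$converged)
    expect_lt(max(abs(r$v - v_star)) / max(abs(v_star)), 1e-6)
  }
  # identical frames at a uniform equilibrium reconstruct the zero field
  uu <- matrix(1, 12, 12)
  recs0 <- reconstruct_sequence(list(uu, uu, uu), p_ref)
  expect_length(recs0, 2)
  for (r in recs0) expect_equal(r$v, matrix(0, 12, 12), tolerance = 1e-12)
  # an invalid frame fails the pair it leads but not the rest
  bad <- frames
  bad[[2]][1, 1] <- 0   # violates ellipticity when used as u_t of pair 2
  recs_b <- reconstruct_sequence(bad, p_ref, frame_dt = dt)
  expect_false(recs_b[[2]]$converged)
  expect_match(recs_b[[2]]$error, "positive")
  expect_true(recs_b[[3]]$converged)
})
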