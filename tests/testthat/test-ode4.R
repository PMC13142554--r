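p_ref <- ks_params()   # gamma = 0.25; b is overridden per call

test_that("4D vector field vanishes at the symmetric equilibria and is swap-equivariant", {
  expect_equal(ode4_rhs(c(0, 0, 0, 0), p_ref), rep(0, 4))
  expect_equal(ode4_rhs(c(1, 1.5, 1, 1.5), p_ref), rep(0, 4))
  set.seed(41)
  for (b in c(10, 18, 25)) {
    S <- matrix(rnorm(40, 0.5, 0.6), 10, 4)
    expect_identical(ode4_rhs(swap_state(S), p_ref, b),
                     swap_state(ode4_rhs(S, p_ref, b)))
  }
})

test_that("alpha coefficients solve the stationary chemoattractant system", {
  ap <- alphas(p_ref)
  expect_equal(ap$alpha1, 9 / 11)    # c(e+dv)/((e+dv)^2 - dv^2) at c=3,e=2,dv=10
  expect_equal(ap$alpha2, 15 / 22)
  expect_gt(ap$alpha1, ap$alpha2)
  expect_gt(ap$alpha2, 0)
  # decoupled limit
  ap0 <- alphas(ks_params(dv = 0))
  expect_equal(ap0$alpha1, 1.5)
  expect_equal(ap0$alpha2, 0)
  # defining identity: v-equations vanish for v built from alphas
  set.seed(42)
  for (i in 1:20) {
    u1 <- runif(1, 0, 2); u2 <- runif(1, 0, 2)
    v1 <- ap$alpha1 * u1 + ap$alpha2 * u2
    v2 <- ap$alpha1 * u2 + ap$alpha2 * u1
    expect_equal(p_ref$c * u1 - p_ref$e * v1 + p_ref$dv * (v2 - v1), 0,
                 tolerance = 1e-13)
    expect_equal(p_ref$c * u2 - p_ref$e * v2 + p_ref$dv * (v1 - v2), 0,
                 tolerance = 1e-13)
  }
})

test_that("fixed-point map: reaction roots are fixed, singular abscissa flagged, stationarity holds", {
  expect_equal(phi(c(0, 0.25, 1), p_ref, b = 25), c(0, 0.25, 1))
  # denominator vanishes at du/(b (alpha1 - alpha2)) = 22/75 at b = 25
  expect_true(is.na(phi(22 / 75, p_ref, b = 25, tol = 1e-8)))
  # for regular u1, the state (u1, phi(u1)) with stationary v kills equation 1
  ap <- alphas(p_ref)
  set.seed(43)
  for (b in c(10, 25)) {
    for (u1 in runif(10, 0, 1.8)) {
      u2 <- phi(u1, p_ref, b = b)
      if (!is.finite(u2)) next
      s <- c(u1, ap$alpha1 * u1 + ap$alpha2 * u2,
             u2, ap$alpha1 * u2 + ap$alpha2 * u1)
      expect_equal(ode4_rhs(s, p_ref, b)[1], 0, tolerance = 1e-9)
    }
  }
})

test_that("equilibrium counts step 3 -> 5 -> 9 across the sensitivity range", {
  eq10 <- find_equilibria(p_ref, b = 10)
  expect_identical(nrow(eq10), 3L)
  expect_equal(eq10$u1, c(0, 0.25, 1))
  expect_equal(eq10$v1, c(0, 0.375, 1.5))
  expect_equal(eq10$label, c("stable", "unstable", "stable"))

  eq15 <- find_equilibria(p_ref, b = 15)
  expect_identical(nrow(eq15), 5L)
  asym <- eq15[abs(eq15$u1 - eq15$u2) > 1e-8, ]
  expect_identical(nrow(asym), 2L)
  expect_true(all(asym$label == "unstable"))

  eq25 <- find_equilibria(p_ref, b = 25)
  expect_identical(nrow(eq25), 9L)
  expect_identical(sum(eq25$label == "stable"), 4L)
  expect_true(all(eq25$resid < 1e-10))
  # the asymmetric stable pair brackets u = 1: gamma < u2 < 1 < u1
  st_asym <- eq25[eq25$label == "stable" & abs(eq25$u1 - eq25$u2) > 1e-6, ]
  expect_identical(nrow(st_asym), 2L)
  hi <- st_asym[which.max(st_asym$u1), ]
  expect_gt(hi$u1, 1)
  expect_gt(hi$u2, p_ref$gamma)
  expect_lt(hi$u2, 1)
})

test_that("stability labels: origin stable, threshold state unstable, swap partners share spectra", {
  for (b in c(10, 17.5, 25)) {
    expect_identical(classify_stability(c(0, 0, 0, 0), p_ref, b)$label, "stable")
    sym <- c(0.25, 0.375, 0.25, 0.375)
    expect_identical(classify_stability(sym, p_ref, b)$label, "unstable")
  }
  eq25 <- find_equilibria(p_ref, b = 25)
  for (k in seq_len(nrow(eq25))) {
    s <- as.numeric(eq25[k, c("u1", "v1", "u2", "v2")])
    c1 <- classify_stability(s, p_ref, 25)
    c2 <- classify_stability(swap_state(s), p_ref, 25)
    expect_equal(c1$re, c2$re, tolerance = 1e-9)
    expect_identical(c1$label, c2$label)
  }
})

test_that("fixed-point enumeration agrees with brute-force Newton from a 20^4 lattice", {
  for (b in c(10, 15, 25)) {
    mine <- as.matrix(find_equilibria(p_ref, b = b)[, c("u1", "v1", "u2", "v2")])
    brute <- brute_force_equilibria(p_ref, b)
    # restrict brute force to the scan box of the fixed-point route
    brute <- brute[brute[, 1] >= -1e-9 & brute[, 1] <= 2 &
                     brute[, 3] >= -1e-9 & brute[, 3] <= 2, , drop = FALSE]
    expect_identical(nrow(mine), nrow(brute))
    o <- order(mine[, 1], mine[, 3])
    ob <- order(brute[, 1], brute[, 3])
    expect_equal(unname(mine[o, ]), unname(brute[ob, ]), tolerance = 1e-6)
  }
})

test_that("bifurcation scan counts are piecewise constant and non-decreasing", {
  scan <- bifurcation_scan(p_ref, b_grid = c(10, 12, 15, 20, 25))
  expect_equal(scan$n_eq[scan$b == 10], 3L)
  expect_equal(scan$n_eq[scan$b == 15], 5L)
  expect_equal(scan$n_eq[scan$b == 25], 9L)
  expect_equal(scan$n_stable[scan$b == 10], 2L)
  expect_equal(scan$n_stable[scan$b == 25], 4L)
  expect_true(all(diff(scan$n_eq) >= 0))
  expect_true(all(scan$n_marginal == 0L))
})

test_that("positive orthant is invariant for random positive states", {
  set.seed(44)
  S <- cbind(runif(100, 0, 1.5), runif(100, 0, 1.5),
             runif(100, 0, 1.5), runif(100, 0, 1.5))
  for (b in c(10, 25)) {
    ST <- rk4_integrate(function(s) ode4_rhs(s, p_ref, b), S,
                        t_end = 100, dt = 0.01)
    expect_gte(min(ST), -1e-9)
  }
})

test_that("heteroclinic orbits from the threshold state reach the three stable fates", {
  orb <- heteroclinic_orbits(p_ref, b = 25)
  expect_true(all(orb$resolved))
  limits <- unique(round(orb[, c("u1", "v1", "u2", "v2")], 6))
  # origin, confluent state, and at least one asymmetric stable state occur
  expect_true(any(abs(limits$u1) < 1e-5 & abs(limits$u2) < 1e-5))
  expect_true(any(abs(limits$u1 - 1) < 1e-5 & abs(limits$u2 - 1) < 1e-5))
  asym <- limits[abs(limits$u1 - limits$u2) > 1e-3, ]
  expect_gte(nrow(asym), 1L)
  expect_true(all(orb$limit_label == "stable"))

  # halving the displacement does not change the set of fates
  orb2 <- heteroclinic_orbits(p_ref, b = 25, delta = 5e-7)
  key <- function(d) sort(paste(round(d$u1, 4), round(d$u2, 4)))
  expect_identical(key(orb), key(orb2))

  # swap symmetry: the mirrored launch converges to the mirrored limit
  asym_row <- orb[abs(orb$u1 - orb$u2) > 1e-3, ][1, ]
  sym <- c(0.25, 0.375, 0.25, 0.375)
  ed <- eigen(ksnet:::ode4_jacobian(sym, p_ref, 25))
  w <- Re(ed$vectors[, which(Re(ed$values) > 1e-10)[asym_row$direction]])
  w <- w / sqrt(sum(w^2))
  s0 <- sym + asym_row$sign * 1e-6 * w
  lim_mirror <- rk4_integrate(function(s) ode4_rhs(s, p_ref, 25),
                              swap_state(s0), t_end = 300, dt = 0.01)
  expect_equal(lim_mirror,
               swap_state(as.numeric(asym_row[c("u1", "v1", "u2", "v2")])),
               tolerance = 1e-5)
})

test_that("opposite displacements near the threshold state split between an asymmetric state and the origin", {
  # mixing the antisymmetric unstable direction with a bias toward the empty
  # state reproduces the observed pair of fates: one trajectory settles at
  # an asymmetric stable equilibrium, its opposite at the origin
  b <- 25
  sym <- c(0.25, 0.375, 0.25, 0.375)
  ev <- eigen(ksnet:::ode4_jacobian(sym, p_ref, b))
  W <- Re(ev$vectors[, Re(ev$values) > 1e-10, drop = FALSE])
  w1 <- W[, 1] / sqrt(sum(W[, 1]^2))   # symmetric direction
  w2 <- W[, 2] / sqrt(sum(W[, 2]^2))   # antisymmetric direction
  w <- w2 - 0.3 * w1
  w <- w / sqrt(sum(w^2))
  lim <- function(s0) rk4_integrate(function(s) ode4_rhs(s, p_ref, b), s0,
                                    t_end = 400, dt = 0.01)
  lp <- lim(sym + 1e-4 * w)
  lm <- lim(sym - 1e-4 * w)
  fates <- rbind(lp, lm)
  is_origin <- apply(abs(fates), 1, max) < 1e-5
  is_asym <- abs(fates[, 1] - fates[, 3]) > 1e-3
  expect_identical(sum(is_origin), 1L)
  expect_identical(sum(is_asym), 1L)
})
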