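test_that("degenerate histograms give the expected potentials", {
  # all samples in one bin: P = 1 there, U = 0, everything else undefined
  tr <- make_traj(rep(5, 100), rep(5, 100))
  g <- estimate_pss(tr, bins = 10, range = list(r1 = c(0, 10), r2 = c(0, 10)))
  expect_equal(sum(g$P), 1)
  expect_equal(sum(g$visited), 1)
  expect_equal(g$U[g$visited], 0)
  expect_true(all(is.na(g$U[!g$visited])))
  # uniform over M bins: U = ln M everywhere
  mids <- seq(0.5, 9.5, by = 1)
  tr2 <- make_traj(rep(mids, each = 10), rep(mids, times = 10))
  g2 <- estimate_pss(tr2, bins = 10, range = list(r1 = c(0, 10), r2 = c(0, 10)))
  expect_equal(sum(g2$visited), 100)
  expect_true(all(abs(g2$U[g2$visited] - log(100)) < 1e-12))
})

test_that("out-of-grid samples are clipped with a warning", {
  tr <- make_traj(c(5, 15), c(5, 5))
  expect_warning(
    g <- estimate_pss(tr, bins = 10, range = list(r1 = c(0, 10), r2 = c(0, 10))),
    "clipped")
  expect_equal(sum(g$counts), 2)
  expect_equal(sum(g$counts[10, ]), 1)  # clipped into the edge bin
})

test_that("OU surrogate potential is quadratic in the displacement", {
  sp <- langevin_spec("linear_rotational", D = 0.5, dt = 0.01,
                      duration = 8000, seed = 4, params = list(k = 1, omega = 0))
  tr <- simulate_langevin(sp)
  g <- estimate_pss(tr, bins = 30)
  well <- g$counts >= 30
  d2 <- outer((g$mid1 - 20)^2, (g$mid2 - 20)^2, "+")
  fit <- lm(g$U[well] ~ d2[well])
  expect_gt(summary(fit)$r.squared, 0.95)
  # slope = 1 / (2 sigma^2) with sigma^2 = (D/k) scale^2
  expect_equal(unname(coef(fit)[2]), 1 / (2 * 0.5 * 64), tolerance = 0.15)
})

test_that("convergence sigma behaves as a relative L2 distance", {
  U <- matrix(c(0, NA, NA, 0), 2, 2)
  a <- toy_grid(U)
  expect_equal(convergence_sigma(a, a), 0)
  # 2-bin hand example: uniform (0.5, 0.5) vs concentrated (1, 0)
  b <- a; b$P <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(convergence_sigma(a, b), 1)
  # scale-free: P is normalized, so repeating the sample set changes nothing
  tr <- make_traj(runif(200, 0, 10), runif(200, 0, 10))
  tr3 <- make_traj(rep(tr$r1, 3), rep(tr$r2, 3))
  rng <- list(r1 = c(0, 10), r2 = c(0, 10))
  g1 <- estimate_pss(tr, bins = 5, range = rng)
  g3 <- estimate_pss(tr3, bins = 5, range = rng)
  ref <- estimate_pss(make_traj(runif(200, 0, 10), runif(200, 0, 10)),
                      bins = 5, range = rng)
  expect_equal(convergence_sigma(ref, g1), convergence_sigma(ref, g3))
  # grid mismatch is rejected
  g_other <- estimate_pss(tr, bins = 6, range = rng)
  expect_error(convergence_sigma(g1, g_other), "grid")
})

test_that("sigma decreases as a surrogate trajectory grows", {
  sp <- langevin_spec("linear_rotational", D = 0.5, dt = 0.01,
                      duration = 16000, seed = 9, params = list(k = 1, omega = 0))
  tr <- simulate_langevin(sp)
  rng <- list(r1 = c(-10, 50), r2 = c(-10, 50))
  cuts <- c(0.125, 0.25, 0.5, 1) * max(tr$t)
  gs <- lapply(cuts, function(ct)
    estimate_pss(tr[tr$t <= ct, ], bins = 25, range = rng))
  s_early <- convergence_sigma(gs[[1]], gs[[2]])
  s_late <- convergence_sigma(gs[[3]], gs[[4]])
  expect_lt(s_late, s_early)
})

test_that("minima detection finds wells and prunes noise islands", {
  # single parabolic well
  x <- seq(-2, 2, length.out = 21)
  U <- outer(x^2, x^2, "+")
  g <- toy_grid(U)
  m <- find_minima(g, smooth = 0, high_rate = 100)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$i, m$j), c(11, 11))
  expect_equal(m$label, "SS")
  # a shallow dimple below the persistence threshold is pruned
  U2 <- U
  U2[5, 5] <- U2[5, 5] - 0.3   # persistence ~0.3 < 0.5
  m2 <- suppressWarnings(find_minima(toy_grid(U2), smooth = 0, high_rate = 100))
  expect_equal(nrow(m2), 1)
  # a deep secondary well survives
  U3 <- U
  U3[5, 5] <- U3[5, 5] - 3
  m3 <- suppressWarnings(find_minima(toy_grid(U3), smooth = 0, high_rate = 100))
  expect_equal(nrow(m3), 2)
  # an isolated single-bin island is not an attractor
  U4 <- U
  U4[1, 21] <- NA; U4[2, 21] <- NA; U4[1, 20] <- NA; U4[2, 20] <- NA
  U4[1, 21] <- 9  # re-create as isolated bin (neighbours NA)
  m4 <- suppressWarnings(find_minima(toy_grid(U4), smooth = 0, high_rate = 100))
  expect_equal(nrow(m4), 1)
})

test_that("double-well surrogate yields two labelled minima at the wells", {
  sp <- langevin_spec("double_well", D = 0.25, dt = 0.005, duration = 12000,
                      seed = 6)
  tr <- simulate_langevin(sp)
  g <- estimate_pss(tr, bins = 30)
  m <- find_minima(g, high_rate = 20)
  expect_equal(nrow(m), 2)
  # wells at x = +/-1 map to r1 = 20 +/- 8
  expect_equal(sort(m$r1), c(12, 28), tolerance = 0.1)
  expect_equal(m$r2, c(20, 20), tolerance = 0.1)
})

test_that("saddle search matches exhaustive path enumeration", {
  set.seed(33)
  for (rep in 1:6) {
    U <- matrix(runif(20, 0, 10), 4, 5)
    U[sample(20, 3)] <- NA
    g <- toy_grid(U)
    vis <- which(!is.na(U), arr.ind = TRUE)
    if (nrow(vis) < 2) next
    a <- list(i = vis[1, 1], j = vis[1, 2])
    b <- list(i = vis[nrow(vis), 1], j = vis[nrow(vis), 2])
    got <- find_saddle(g, a, b, smooth = 0)
    want <- brute_minimax(U, c(a$i, a$j), c(b$i, b$j))
    if (is.finite(want)) {
      expect_true(got$connected)
      expect_equal(got$U_saddle, want)
    } else {
      expect_false(got$connected)
    }
  }
})

test_that("barrier metrics reproduce hand arithmetic and symmetry", {
  # line of potentials 0, 5, 1: BH1 = 5, BH2 = 4, RB1 = 1
  U <- matrix(NA_real_, 3, 3)
  U[1, 2] <- 0; U[2, 2] <- 5; U[3, 2] <- 1
  g <- toy_grid(U, mid1 = c(5, 15, 25), mid2 = c(5, 15, 25))
  att <- data.frame(label = c("DS1", "DS2"), r1 = c(5, 25), r2 = c(15, 15),
                    U = c(0, 1), i = c(1, 3), j = c(2, 2))
  bm <- barrier_metrics(g, att, "DS1", "DS2", smooth = 0)
  expect_equal(bm$BH_from, 5)
  expect_equal(bm$BH_to, 4)
  expect_equal(bm$RB, 1)
  expect_error(barrier_metrics(g, att, "SS", "DS1"), "SS")
  # symmetric double well: saddle on the symmetry axis, BH1 = BH2
  x <- seq(-1.6, 1.6, length.out = 17)
  Us <- outer((x^2 - 1)^2, x^2, "+")
  gs <- toy_grid(Us)
  ms <- suppressWarnings(find_minima(gs, smooth = 0, high_rate = 100))
  expect_equal(nrow(ms), 2)
  bms <- barrier_metrics(gs, transform(ms, label = c("DS1", "DS2")),
                         "DS1", "DS2", smooth = 0)
  expect_equal(bms$BH_from, bms$BH_to, tolerance = 1e-12)
  expect_equal(bms$RB, 0, tolerance = 1e-12)
})

test_that("swapping r1 and r2 swaps decision labels and negates RB", {
  # tilted double well placed on the anti-diagonal of the rate plane, so
  # the two wells read as the two decision states
  sp <- langevin_spec("double_well", D = 0.25, dt = 0.005, duration = 12000,
                      seed = 14, params = list(h = 0.25),
                      origin = c(0, 0), scale = 1)
  nat <- simulate_langevin(sp)
  u <- nat$r1; v <- nat$r2
  tr <- make_traj(20 + 8 * u + 3 * v, 20 - 8 * u + 3 * v)
  swapped <- make_traj(tr$r2, tr$r1)
  rng <- list(r1 = c(0, 45), r2 = c(0, 45))
  g1 <- estimate_pss(tr, bins = 30, range = rng)
  g2 <- estimate_pss(swapped, bins = 30, range = rng)
  m1 <- find_minima(g1, high_rate = 16)
  m2 <- find_minima(g2, high_rate = 16)
  expect_setequal(m1$label, c("DS1", "DS2"))
  expect_setequal(m2$label, c("DS1", "DS2"))
  b1 <- barrier_metrics(g1, m1, "DS1", "DS2")
  b2 <- barrier_metrics(g2, m2, "DS1", "DS2")
  expect_equal(b1$RB, -b2$RB, tolerance = 1e-9)
  expect_gt(abs(b1$RB), 0.1)  # the tilt produces a real asymmetry
})
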