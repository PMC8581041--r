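test_that("coarse graining assigns samples to boxes and clips outliers", {
  tr <- make_traj(rep(3, 10), rep(7, 10))
  cg <- coarse_grain(tr, 4, 4, domain = list(r1 = c(0, 8), r2 = c(0, 8)))
  expect_true(all(cg$i1 == 2) && all(cg$i2 == 4))
  expect_warning(
    coarse_grain(make_traj(c(1, 99), c(1, 1)), 4, 4,
                 domain = list(r1 = c(0, 8), r2 = c(0, 8))),
    "clipped")
  expect_error(coarse_grain(make_traj(numeric(0), numeric(0)), 4, 4), "empty")
  expect_error(coarse_grain(tr, 1, 4))
})

test_that("box occupancy matches the landscape histogram on the same grid", {
  sp <- langevin_spec("linear_rotational", D = 0.5, duration = 2000, seed = 2)
  tr <- simulate_langevin(sp)
  dom <- list(r1 = c(-10, 50), r2 = c(-10, 50))
  cg <- coarse_grain(tr, 15, 15, domain = dom)
  occ <- table(factor(cg$i1, levels = 1:15), factor(cg$i2, levels = 1:15))
  g <- estimate_pss(tr, bins = 15, range = dom)
  expect_equal(unclass(unname(occ)), unclass(g$counts), ignore_attr = TRUE)
})

test_that("face crossings are tallied with linear interpolation", {
  dom <- list(r1 = c(0, 4), r2 = c(0, 4))
  # one box to the right: exactly one +r1 tally
  tal <- count_transitions(coarse_grain(make_traj(c(0.5, 1.5), c(0.5, 0.5)),
                                        4, 4, dom))
  expect_equal(sum(tal$xp), 1)
  expect_equal(tal$xp[1, 1], 1L)
  expect_equal(sum(tal$xm) + sum(tal$yp) + sum(tal$ym), 0)
  # two boxes right in one step: two successive +r1 crossings (interpolated)
  tal2 <- count_transitions(coarse_grain(make_traj(c(0.5, 2.5), c(0.5, 0.5)),
                                         4, 4, dom))
  expect_equal(sum(tal2$xp), 2)
  expect_equal(tal2$xp[1, 1] + tal2$xp[2, 1], 2L)
  # diagonal jump across a corner: one +r1 and one +r2 crossing, ordered
  tal3 <- count_transitions(coarse_grain(make_traj(c(0.9, 1.6), c(0.7, 1.2)),
                                         4, 4, dom))
  expect_equal(sum(tal3$xp), 1)
  expect_equal(sum(tal3$yp), 1)
  # the x line (t = 0.14) is crossed while still in row 1
  expect_equal(tal3$xp[1, 1], 1L)
  # the y line (t = 0.6) is crossed after moving to column 2
  expect_equal(tal3$yp[2, 1], 1L)
  # same box: nothing
  tal4 <- count_transitions(coarse_grain(make_traj(c(0.2, 0.8), c(0.2, 0.8)),
                                         4, 4, dom))
  expect_equal(sum(unlist(tal4)), 0)
})

test_that("a deterministic cycle gives the hand-counted flux", {
  # clockwise-in-index square loop over the 4 boxes of a 2x2 grid, C cycles
  C <- 5
  pts <- do.call(rbind, replicate(C, rbind(
    c(0.5, 0.5), c(1.5, 0.5), c(1.5, 1.5), c(0.5, 1.5)), simplify = FALSE))
  tr <- make_traj(pts[, 1], pts[, 2], dt = 1000)  # 1 s per hop
  dom <- list(r1 = c(0, 2), r2 = c(0, 2))
  cg <- coarse_grain(tr, 2, 2, dom)
  tal <- count_transitions(cg)
  t_total <- diff(range(tr$t)) / 1000
  ff <- flux_field(tal, t_total, cg)
  # each face is crossed once per cycle (the last return leg is C-1 times)
  expect_equal(tal$xp[1, 1], C)        # bottom edge, rightward
  expect_equal(tal$yp[2, 1], C)        # right edge, upward
  expect_equal(tal$xm[1, 2], C)        # top edge, leftward
  expect_equal(tal$ym[1, 1], C - 1)    # left edge, downward (loop not closed)
  # net rates: wx on bottom = +C/t, wy on right = +C/t, wx on top = -C/t
  expect_equal(ff$wx[1, 1], C / t_total)
  expect_equal(ff$wx[1, 2], -C / t_total)
  expect_equal(ff$wy[2, 1], C / t_total)
  # J averages the two faces per direction, boundary faces count zero
  expect_equal(ff$Jx[1, 1], C / (2 * t_total))
  expect_equal(ff$Jy[2, 2], C / (2 * t_total))
  # circulation is consistently clockwise-in-(r1,r2)?? counter-clockwise:
  # (0.5,0.5)->(1.5,0.5)->(1.5,1.5)->(0.5,1.5) turns left: CCW
  cd <- curl_direction(ff, center = c(1, 1), noise_mult = 0)
  expect_equal(cd$frac_positive, 1)
})

test_that("time reversal negates every net rate and flux vector", {
  set.seed(8)
  n <- 400
  tr <- make_traj(cumsum(rnorm(n)) / 3 + 10, cumsum(rnorm(n)) / 3 + 10)
  dom <- list(r1 = c(0, 20), r2 = c(0, 20))
  f_fwd <- estimate_flux(tr, 6, 6, domain = dom, n_blocks = 0)
  f_bwd <- estimate_flux(reverse_trajectory(tr), 6, 6, domain = dom,
                         n_blocks = 0)
  expect_equal(f_bwd$wx, -f_fwd$wx)
  expect_equal(f_bwd$wy, -f_fwd$wy)
  expect_equal(f_bwd$Jx, -f_fwd$Jx)
  expect_equal(f_bwd$Jy, -f_fwd$Jy)
})

test_that("gradient dynamics carry no net flux; rotation is detected with its sense", {
  sp <- langevin_spec("double_well", D = 0.25, dt = 0.005, duration = 8000,
                      seed = 16)
  tr <- simulate_langevin(sp)
  ff <- estimate_flux(tr, 12, 12)
  mag <- sqrt(ff$Jx^2 + ff$Jy^2)
  se <- sqrt(ff$SEx^2 + ff$SEy^2)
  expect_lt(mean(mag), 3 * mean(se[se > 0]))
  # rotational OU: curl sign follows sign(omega)
  for (om in c(1.5, -1.5)) {
    spo <- langevin_spec("linear_rotational", D = 0.5, dt = 0.01,
                         duration = 8000, seed = 17,
                         params = list(k = 1, omega = om))
    tro <- simulate_langevin(spo)
    ffo <- estimate_flux(tro, 12, 12)
    cd <- curl_direction(ffo, center = c(20, 20))
    expect_gt(cd$n_boxes, 10)
    if (om > 0) expect_gt(cd$frac_positive, 0.9)
    else expect_lt(cd$frac_positive, 0.1)
  }
})

test_that("flux magnitude grows with the rotational coefficient", {
  mags <- vapply(c(0.5, 2), function(om) {
    spo <- langevin_spec("linear_rotational", D = 0.5, dt = 0.01,
                         duration = 6000, seed = 21,
                         params = list(k = 1, omega = om))
    ffo <- estimate_flux(simulate_langevin(spo), 10, 10, n_blocks = 0)
    mean(sqrt(ffo$Jx^2 + ffo$Jy^2))
  }, numeric(1))
  expect_gt(mags[2], 2 * mags[1])
})
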