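test_that("attractor regions are built per minimum and overlap is rejected", {
  att <- data.frame(label = c("DS1", "DS2"), r1 = c(30, 5), r2 = c(5, 30))
  regs <- define_regions(att, 5)
  expect_named(regs, c("DS1", "DS2"))
  expect_true(inside_region(regs$DS1, 31, 6))
  expect_false(inside_region(regs$DS1, 30, 11))
  expect_error(define_regions(att, 20), "overlap")
  att3 <- data.frame(label = c("SS", "DS1", "DS2"),
                     r1 = c(3, 30, 5), r2 = c(3, 5, 30))
  expect_length(define_regions(att3, 5), 3)
  # per-label semi-axes
  regs2 <- define_regions(att3, list(SS = 2, DS1 = c(4, 3), DS2 = 5))
  expect_equal(regs2$DS1$semi, c(4, 3))
})

test_that("first-passage sampling follows the arm/record/re-arm protocol", {
  A <- structure(list(label = "A", center = c(0, 0), semi = c(1, 1)),
                 class = "attractor_region")
  B <- structure(list(label = "B", center = c(10, 0), semi = c(1, 1)),
                 class = "attractor_region")
  # straight passage: one sample equal to the crossing time
  tr <- make_traj(c(0, 2, 5, 8, 10), rep(0, 5), dt = 1000)
  fpt <- first_passage_times(tr, A, B)
  expect_equal(fpt$K, 1)
  expect_equal(fpt$MFPT, 4)  # armed at t=1s, arrives t=5s
  # A -> B -> A -> B yields two samples; ending mid-transit censors
  tr2 <- make_traj(c(0, 10, 0, 10, 0, 5), rep(0, 6), dt = 1000)
  fpt2 <- first_passage_times(tr2, A, B)
  expect_equal(fpt2$K, 2)
  expect_equal(fpt2$samples, c(1, 1))
  expect_equal(fpt2$n_censored, 1)
  expect_match(fpt2$note, "censored")
  # zero observed transitions: explicit empty result, never fabricated
  fpt3 <- first_passage_times(make_traj(c(0, 0), c(0, 0), dt = 1000), A, B)
  expect_equal(fpt3$K, 0)
  expect_true(is.na(fpt3$MFPT))
})

test_that("transition paths obey the last-exit / first-entry delimitation", {
  A <- structure(list(label = "A", center = c(0, 0), semi = c(1, 1)),
                 class = "attractor_region")
  B <- structure(list(label = "B", center = c(10, 0), semi = c(1, 1)),
                 class = "attractor_region")
  # excursion that dips back into A before finally crossing: the path
  # restarts from the new exit
  r1 <- c(0, 3, 0.5, 4, 7, 10, 12)
  tr <- make_traj(r1, rep(0, length(r1)), dt = 10)
  ps <- extract_transition_paths(tr, A, B)
  expect_equal(ps$K, 1)
  expect_equal(ps$paths[[1]]$r1, c(0.5, 4, 7, 10))
  # start inside A, end at first point inside B, no interior point in B
  expect_true(inside_region(A, ps$paths[[1]]$r1[1], 0))
  expect_true(inside_region(B, tail(ps$paths[[1]]$r1, 1), 0))
  expect_false(any(inside_region(B, ps$paths[[1]]$r1[-4], 0)))
  # no transitions -> empty set is a valid result
  expect_equal(extract_transition_paths(make_traj(c(0, 3), c(0, 0)), A, B)$K, 0)
})

test_that("path averaging resamples by index and respects symmetry", {
  A <- structure(list(label = "A", center = c(0, 0), semi = c(1, 1)),
                 class = "attractor_region")
  B <- structure(list(label = "B", center = c(10, 10), semi = c(1, 1)),
                 class = "attractor_region")
  p1 <- data.frame(t = 0:4 * 10, r1 = c(0, 2, 6, 9, 10), r2 = c(0, 1, 3, 8, 10))
  p2 <- data.frame(t = 0:4 * 10, r1 = p1$r2, r2 = p1$r1)  # mirror about r1=r2
  ps <- structure(list(paths = list(p1), K = 1L, from = "A", to = "B",
                       psi = NULL), class = "transition_path_set")
  avg1 <- average_path(ps, n_points = 9)
  # K = 1: psi is the resampled path itself
  expect_equal(avg1$psi$r1, approx(1:5, p1$r1, n = 9)$y)
  ps2 <- structure(list(paths = list(p1, p2), K = 2L, from = "A", to = "B",
                        psi = NULL), class = "transition_path_set")
  avg2 <- average_path(ps2, n_points = 21)
  expect_equal(avg2$psi$r1, avg2$psi$r2)  # mirror pair averages onto diagonal
  expect_equal(nrow(avg2$psi), 21)
  # endpoint contract: psi starts in A and ends in B
  expect_true(inside_region(A, avg2$psi$r1[1], avg2$psi$r2[1]))
  expect_true(inside_region(B, tail(avg2$psi$r1, 1), tail(avg2$psi$r2, 1)))
  expect_error(average_path(extract_transition_paths(
    make_traj(c(0, 0), c(0, 0)), A, B)), "no transition")
})

test_that("forward paths of a reversed trajectory are reversed backward paths", {
  set.seed(5)
  n <- 2000
  tr <- make_traj(pmin(pmax(cumsum(rnorm(n, 0, 0.8)), -2), 14) + 2,
                  rep(2, n), dt = 5)
  A <- structure(list(label = "A", center = c(0, 2), semi = c(1.5, 1.5)),
                 class = "attractor_region")
  B <- structure(list(label = "B", center = c(14, 2), semi = c(1.5, 1.5)),
                 class = "attractor_region")
  fwd_rev <- extract_transition_paths(reverse_trajectory(tr), A, B)
  bwd <- extract_transition_paths(tr, B, A)
  expect_equal(fwd_rev$K, bwd$K)
  if (fwd_rev$K > 0) {
    got <- lapply(fwd_rev$paths, function(p) rev(p$r1))
    want <- lapply(rev(bwd$paths), function(p) p$r1)
    expect_equal(got, want)
  }
})

test_that("double-well escape times match the quadrature reference", {
  sp <- langevin_spec("double_well", D = 0.35, dt = 0.002, duration = 20000,
                      seed = 19, origin = c(0, 0), scale = 1)
  tr <- simulate_langevin(sp)
  regA <- structure(list(label = "A", center = c(-1, 0), semi = c(0.3, 6)),
                    class = "attractor_region")
  regB <- structure(list(label = "B", center = c(1, 0), semi = c(0.3, 6)),
                    class = "attractor_region")
  fpt <- first_passage_times(tr, regA, regB)
  ref <- mfpt_quadrature(sp, x_from = -0.7, x_to = 0.7)
  expect_gt(fpt$K, 50)
  expect_equal(fpt$MFPT * 1000, ref, tolerance = 0.3)
})
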