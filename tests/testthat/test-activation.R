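test_that("frame classification applies strict thresholds to both markers", {
  cases <- list(
    list(d = 18.0, theta = 50.0, active = TRUE),
    list(d = 19.0, theta = 50.0, active = FALSE),  # boundary is strict
    list(d = 18.0, theta = 45.0, active = FALSE),  # boundary is strict
    list(d = 25.0, theta = 10.0, active = FALSE)
  )
  for (cs in cases) {
    mf <- marker_frame(cs$d, cs$theta)
    out <- classify_frames(mf$trajectory, mf$topology, mf$criteria)
    expect_equal(out$distance, cs$d, tolerance = 1e-9)
    expect_equal(out$angle, cs$theta, tolerance = 1e-9)
    expect_identical(out$active, cs$active)
  }
})

test_that("the OR combination accepts frames that satisfy either marker", {
  mf <- marker_frame(18.0, 10.0)
  crit_or <- activation_criteria(c(1L, 2L), c(3L, 4L, 5L), combine = "or")
  expect_false(classify_frames(mf$trajectory, mf$topology, mf$criteria)$active)
  expect_true(classify_frames(mf$trajectory, mf$topology, crit_or)$active)
})

test_that("active fraction counts retained frames", {
  mk <- function(d, theta) marker_frame(d, theta)$trajectory$coords[[1]]
  mf <- marker_frame(18, 50)
  tr <- trajectory(list(mk(18, 50), mk(18.5, 55), mk(21, 50), mk(18, 40)))
  af <- active_fraction(tr, mf$topology, mf$criteria)
  expect_equal(af$fraction, 0.5)
  expect_identical(tidy(af)$active, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(tidy(af)), 4L)

  all_active <- trajectory(rep(list(mk(17, 55)), 3))
  expect_equal(active_fraction(all_active, mf$topology, mf$criteria)$fraction, 1)
})

test_that("unresolvable marker selections fail loudly", {
  mf <- marker_frame(18, 50)
  bad <- activation_criteria(c(1L, 99L), c(3L, 4L, 5L))
  expect_error(classify_frames(mf$trajectory, mf$topology, bad), "not found")
})

test_that("pooled fractions are frame-weighted with the unweighted mean alongside", {
  p <- pooled_fraction(c(0.2, 0.4), c(100, 100))
  expect_equal(p$pooled, 0.3)
  expect_equal(p$mean_unweighted, 0.3)
  expect_identical(pooled_fraction(0.7, 500)$pooled, 0.7)
  p <- pooled_fraction(c(0.0, 1.0), c(1, 3))
  expect_equal(p$pooled, 0.75)
  expect_equal(p$mean_unweighted, 0.5)
  expect_error(pooled_fraction(c(0.1, 0.2), 10), "equal length")
  expect_error(pooled_fraction(0.5, 0), "positive")
})

test_that("recovered fraction matches the planted Bernoulli states", {
  en <- generate_ensemble(synthetic_spec(2000, 0.3, seed = 101))
  af <- active_fraction(en$trajectory, en$topology, en$criteria)
  expect_equal(af$fraction, mean(en$states))  # zero mislabels at 5-sigma margins
  expect_true(within_binomial_ci(af$fraction, 0.3, 2000))
})

test_that("the active fraction is monotone in both thresholds", {
  en <- generate_ensemble(synthetic_spec(500, 0.5, seed = 55))
  base <- en$criteria
  frac <- function(dthr, athr) {
    crit <- activation_criteria(base$distance_residues, base$angle_residues,
                                distance_threshold = dthr,
                                angle_threshold = athr, chain = "A")
    active_fraction(en$trajectory, en$topology, crit)$fraction
  }
  dsweep <- vapply(seq(15, 25, by = 1), frac, numeric(1), athr = 45)
  expect_true(all(diff(dsweep) >= 0))   # relaxing distance upward
  asweep <- vapply(seq(30, 60, by = 2.5), function(a) frac(19, a), numeric(1))
  expect_true(all(diff(asweep) <= 0))   # tightening angle upward
})

test_that("classification is invariant under rigid transforms and rewrapping", {
  box <- c(200, 200, 200)
  en <- generate_ensemble(synthetic_spec(100, 0.5, seed = 77, box = box))
  ref <- classify_frames(en$trajectory, en$topology, en$criteria)

  rot <- withr::with_seed(6, random_rotation())
  moved <- trajectory(lapply(en$trajectory$coords, function(x)
    sweep(x %*% rot, 2, c(40, -60, 10), FUN = "+")),
    times = en$trajectory$times, box = NULL)
  got <- classify_frames(moved, en$topology, en$criteria)
  expect_identical(got$active, ref$active)
  expect_equal(got$distance, ref$distance, tolerance = 1e-9)
  expect_equal(got$angle, ref$angle, tolerance = 1e-9)

  rewrapped <- trajectory(lapply(en$trajectory$coords, function(x)
    sweep(x, 2, box, FUN = "%%")),
                          times = en$trajectory$times, box = box)
  got <- classify_frames(rewrapped, en$topology, en$criteria)
  expect_identical(got$active, ref$active)
  expect_equal(got$distance, ref$distance, tolerance = 1e-9)
})
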