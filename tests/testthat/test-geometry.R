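test_that("minimum-image displacement wraps, is antisymmetric, and falls back", {
  box <- c(80, 80, 80)
  d <- min_image_displacement(c(1, 0, 0), c(79, 0, 0), box)
  expect_equal(abs(d[1]), 2)
  expect_equal(d, -min_image_displacement(c(79, 0, 0), c(1, 0, 0), box))
  expect_equal(min_image_displacement(c(5, 5, 5), c(5, 5, 5), box), c(0, 0, 0))
  expect_equal(sqrt(sum(min_image_displacement(c(0, 0, 0), c(3, 4, 0))^2)), 5)
})

test_that("atom distances match a naive no-wrap oracle when the box is huge", {
  coords <- withr::with_seed(11, matrix(runif(200 * 3, 0, 50), ncol = 3))
  box <- c(1e6, 1e6, 1e6)
  withr::with_seed(12, {
    for (k in 1:1000) {
      ij <- sample(200, 2)
      naive <- sqrt(sum((coords[ij[1], ] - coords[ij[2], ])^2))
      expect_equal(atom_distance(coords, ij[1], ij[2], box), naive)
      expect_equal(atom_distance(coords, ij[2], ij[1], box), naive)
    }
  })
  wrapped <- rbind(c(1, 0, 0), c(79, 0, 0))
  expect_equal(atom_distance(wrapped, 1, 2, c(80, 80, 80)), 2)
  expect_equal(atom_distance(rbind(c(0, 0, 0), c(1, 0, 0)), 1, 2), 1)
})

test_that("angles cover collinear, right-angle and degenerate cases", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(atom_angle(coords, 1, 2, 3), 180)
  coords <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  expect_equal(atom_angle(coords, 1, 2, 3), 90)
  coords <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(atom_angle(coords, 1, 2, 3), "degenerate")
})

test_that("center of mass is the weighted mean and unwraps across boundaries", {
  top <- toy_topology(4, mass = c(1, 1, 1, 3))
  coords <- rbind(c(5, 5, 5), c(0, 0, 0), c(2, 0, 0), c(4, 0, 0))
  expect_equal(center_of_mass(coords, 1L, top), c(5, 5, 5))
  expect_equal(center_of_mass(coords, 2:3, top), c(1, 0, 0))
  expect_equal(center_of_mass(coords, c(2L, 4L), top), c(3, 0, 0))
  # two atoms straddling the x boundary of an 80 A box: images at 79 and 81
  straddle <- rbind(c(79, 0, 0), c(1, 0, 0), c(0, 0, 0), c(0, 0, 0))
  com <- center_of_mass(straddle, 1:2, toy_topology(4), box = c(80, 80, 80))
  expect_equal(com[1] %% 80, 0)
})

test_that("Kabsch recovers identity and known rigid transforms", {
  pts <- withr::with_seed(5, matrix(rnorm(15), ncol = 3))
  fit <- kabsch_superpose(pts, pts)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  th <- pi / 2
  rot90 <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(pts %*% rot90, 2, c(3, -2, 7), FUN = "+")
  fit <- kabsch_superpose(moved, pts)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, t(rot90), tolerance = 1e-9)
  expect_equal(apply_superposition(moved, fit), pts, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch beats a random-rotation search and rejects degeneracy", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      ref <- matrix(rnorm(12), ncol = 3)
      mob <- ref + matrix(rnorm(12, sd = 0.3), ncol = 3)
      fit <- kabsch_superpose(mob, ref)
      cm <- colMeans(mob); cr <- colMeans(ref)
      p <- sweep(mob, 2, cm); q <- sweep(ref, 2, cr)
      best <- min(vapply(1:2000, function(k) {
        sqrt(mean(rowSums((p %*% random_rotation() - q)^2)))
      }, numeric(1)))
      expect_lte(fit$rmsd, best + 1e-12)
    }
  })
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line + 0.1, line), "degenerate reference")
})

test_that("a static trajectory has zero RMSF everywhere", {
  sc <- build_scaffold()
  en <- generate_ensemble(synthetic_spec(5, 0, noise_sigma = 0, seed = 1))
  res <- rmsf(en$trajectory, en$topology,
              select_atoms(en$topology, group = "receptor"))
  expect_lt(max(tidy(res)$rmsf), 1e-12)
  expect_lt(glance(res)$selection_sum, 1e-10)
})

test_that("RMSF sum is additive over a selection with equal per-atom RMSF", {
  en <- generate_ensemble(synthetic_spec(400, 0, noise_sigma = 0.1, seed = 9))
  sel5 <- select_atoms(en$topology, residues = 1:5, group = "receptor")
  sel10 <- select_atoms(en$topology, residues = 1:10, group = "receptor")
  align <- select_atoms(en$topology, residues = 31:40, group = "receptor")
  r5 <- rmsf(en$trajectory, en$topology, sel5, align_selection = align)
  r10 <- rmsf(en$trajectory, en$topology, sel10, align_selection = align)
  # equal planted noise: doubling the selection ~doubles the sum
  expect_equal(glance(r10)$selection_sum / glance(r5)$selection_sum, 2,
               tolerance = 0.1)
  expect_identical(tidy(r5)$rmsf, tidy(r10)$rmsf[1:5])
})

test_that("RMSF requires at least two retained frames", {
  en <- generate_ensemble(synthetic_spec(1, 0, noise_sigma = 0, seed = 1))
  expect_error(rmsf(en$trajectory, en$topology, 1:5), "at least 2")
})

test_that("distances, angles and RMSF are invariant under rigid transforms", {
  en <- generate_ensemble(synthetic_spec(30, 0.5, seed = 14))
  rot <- withr::with_seed(3, random_rotation())
  shift <- c(12, -7, 30)
  coords <- en$trajectory$coords[[1]]
  moved1 <- sweep(coords %*% rot, 2, shift, FUN = "+")
  expect_equal(atom_distance(moved1, 10, 30), atom_distance(coords, 10, 30),
               tolerance = 1e-9)
  expect_equal(atom_angle(moved1, 15, 20, 25), atom_angle(coords, 15, 20, 25),
               tolerance = 1e-9)

  moved <- trajectory(lapply(en$trajectory$coords, function(x)
    sweep(x %*% rot, 2, shift, FUN = "+")), times = en$trajectory$times)
  sel <- select_atoms(en$topology, group = "receptor")
  r0 <- rmsf(en$trajectory, en$topology, sel)
  r1 <- rmsf(moved, en$topology, sel)
  expect_equal(tidy(r1)$rmsf, tidy(r0)$rmsf, tolerance = 1e-6)
})
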