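test_that("pair energies match closed forms at canonical distances", {
  huge <- nonbonded_config(cutoff = 1e6)
  # +1/-1 e at 10 A: the CODATA-derived Coulomb constant over 1 nm
  e <- pair_energy(1, -1, 0.3, 0.3, 0, 0, r = 10, config = huge)
  expect_equal(e$coulomb, -138.935458, tolerance = 1e-12)
  expect_equal(e$lj, 0)

  # LJ minimum: sigma_ij = 3 A, r = 2^(1/6) * 3 -> exactly -epsilon
  e <- pair_energy(0, 0, 0.3, 0.3, 1, 1, r = 2^(1 / 6) * 3, config = huge)
  expect_equal(e$lj, -1, tolerance = 1e-12)
  # zero crossing at r = sigma_ij
  e <- pair_energy(0, 0, 0.3, 0.3, 1, 1, r = 3, config = huge)
  expect_equal(e$lj, 0, tolerance = 1e-12)

  # plain truncation just beyond the cutoff
  cfg <- nonbonded_config(cutoff = 10)
  e <- pair_energy(1, -1, 0.3, 0.3, 1, 1, r = 10.001, config = cfg)
  expect_identical(c(e$coulomb, e$lj), c(0, 0))

  expect_error(pair_energy(1, -1, 0.3, 0.3, 1, 1, r = 0), "singularity")
})

test_that("a single cross-group pair reduces to pair_energy", {
  pl <- plant_energy_trajectory(10, q = c(1, -1), epsilon = c(0.5, 0.5))
  got <- group_interaction_energy(pl$trajectory$coords[[1]], pl$topology)
  ref <- pair_energy(1, -1, 0.3, 0.3, 0.5, 0.5, r = 10)
  expect_equal(got$coulomb, ref$coulomb, tolerance = 1e-12)
  expect_equal(got$lj, ref$lj, tolerance = 1e-12)
  expect_equal(got$coulomb, -138.935458, tolerance = 1e-9)
})

test_that("empty and overlapping groups are handled", {
  top <- toy_topology(6)
  coords <- cbind(1:6, 0, 0)
  expect_equal(group_interaction_energy(coords, top, integer(0), 3:6),
               list(coulomb = 0, lj = 0))
  expect_error(group_interaction_energy(coords, top, 1:3, 3:6), "overlap")
})

test_that("group energy equals the naive double-loop oracle on random systems", {
  for (seed in 1:10) {
    sys <- random_system(seed, n_atoms = 60)
    cfg <- nonbonded_config(cutoff = 12)
    got <- group_interaction_energy(sys$coords, sys$topology,
                                    config = cfg, box = sys$box)
    ref <- naive_group_energy(sys$coords, sys$topology, sys$box, cutoff = 12)
    expect_equal(got$coulomb, ref$coulomb, tolerance = 1e-9)
    expect_equal(got$lj, ref$lj, tolerance = 1e-9)
  }
})

test_that("per-residue decomposition conserves the group total on both sides", {
  for (seed in 1:5) {
    sys <- random_system(seed, n_atoms = 45)
    tot <- group_interaction_energy(sys$coords, sys$topology, box = sys$box)
    for (side in c("ligand", "receptor")) {
      dec <- residue_decomposition(sys$coords, sys$topology, side = side,
                                   box = sys$box)
      expect_equal(sum(dec$coulomb), tot$coulomb, tolerance = 1e-12)
      expect_equal(sum(dec$lj), tot$lj, tolerance = 1e-12)
      expect_equal(sum(dec$total), tot$coulomb + tot$lj, tolerance = 1e-12)
    }
  }
})

test_that("a residue with zero charge and zero epsilon contributes nothing", {
  atoms <- toy_atoms(6, residue_index = c(1, 1, 2, 2, 3, 3),
                     charge = c(1, -0.5, 0, 0, 0.3, -0.3),
                     lj_epsilon = c(0.5, 0.5, 0, 0, 0.2, 0.2))
  atoms$chain_id <- rep(c("L", "A"), each = 3)
  top <- topology(atoms, groups = list(ligand = 1:3, receptor = 4:6))
  coords <- cbind(seq(0, 12.5, by = 2.5), 0, 0)
  dec <- residue_decomposition(coords, top, side = "ligand",
                               config = nonbonded_config(cutoff = 1e5))
  # ligand residue 2 holds atoms 3 (q=0, eps=0) only on the ligand side
  row <- dec[dec$residue_index == 2, ]
  expect_equal(row$coulomb, 0)
  expect_equal(row$lj, 0)
})

test_that("all energies vanish for a chargeless, epsilon-free topology", {
  sys <- random_system(31, n_atoms = 30)
  atoms <- as.data.frame(sys$topology)[-1]
  atoms$charge <- 0
  atoms$lj_epsilon <- 0
  top <- topology(atoms, topology_groups(sys$topology))
  e <- group_interaction_energy(sys$coords, top, box = sys$box)
  expect_identical(c(e$coulomb, e$lj), c(0, 0))
})

test_that("energies are invariant under rigid rotation and translation", {
  sys <- random_system(8, n_atoms = 40)
  e0 <- group_interaction_energy(sys$coords, sys$topology)
  rot <- withr::with_seed(4, random_rotation())
  moved <- sweep(sys$coords %*% rot, 2, c(100, -50, 3), FUN = "+")
  e1 <- group_interaction_energy(moved, sys$topology)
  expect_equal(e1$coulomb, e0$coulomb, tolerance = 1e-9)
  expect_equal(e1$lj, e0$lj, tolerance = 1e-9)
})

test_that("trajectory series reproduces closed-form means and honours discard", {
  # constant geometry: sd 0, mean equals the single-frame value
  pl <- plant_energy_trajectory(rep(10, 5))
  eb <- trajectory_energy_series(pl$trajectory, pl$topology)
  s <- glance(eb)
  expect_equal(s$coulomb_sd, 0)
  expect_equal(s$coulomb_mean, pl$analytic$coulomb[1], tolerance = 1e-12)
  expect_equal(s$total_mean, s$coulomb_mean + s$lj_mean, tolerance = 1e-12)

  # alternating separations: mean equals the average of the two closed forms
  pl <- plant_energy_trajectory(rep(c(5, 7), 10))
  eb <- trajectory_energy_series(pl$trajectory, pl$topology)
  expect_equal(glance(eb)$total_mean, mean(pl$analytic$total), tolerance = 1e-12)
  expect_equal(tidy(eb)$total, pl$analytic$total, tolerance = 1e-12)

  # series crossing the cutoff has exact zeros beyond it
  pl <- plant_energy_trajectory(c(8, 9, 11, 12))
  eb <- trajectory_energy_series(pl$trajectory, pl$topology)
  expect_identical(tidy(eb)$total[3:4], c(0, 0))

  # discard window and stride subset the frames deterministically
  pl <- plant_energy_trajectory(c(5, 5, 7, 7, 7, 7))
  tr <- pl$trajectory
  tr$discard_before <- 2
  eb <- trajectory_energy_series(tr, pl$topology)
  expect_equal(glance(eb)$n_frames, 4L)
  expect_equal(glance(eb)$coulomb_sd, 0)
  eb2 <- trajectory_energy_series(tr, pl$topology, stride = 2)
  expect_equal(tidy(eb2)$frame, c(3L, 5L))

  tr$discard_before <- 100
  expect_error(trajectory_energy_series(tr, pl$topology), "zero retained")
})

test_that("two frames with energies E and -E average to zero", {
  # charges arranged so frame 2 flips the sign: swap which receptor atom
  # sits near the ligand charge
  atoms <- toy_atoms(3, residue_index = c(1, 1, 2),
                     charge = c(1, -1, 1), lj_epsilon = 0)
  atoms$chain_id <- c("L", "A", "A")
  top <- topology(atoms, groups = list(ligand = 1L, receptor = 2:3))
  f1 <- rbind(c(0, 0, 0), c(5, 0, 0), c(100, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(100, 0, 0), c(5, 0, 0))
  tr <- trajectory(list(f1, f2))
  eb <- trajectory_energy_series(tr, top, nonbonded_config(cutoff = 10))
  expect_equal(glance(eb)$coulomb_mean, 0, tolerance = 1e-12)
})
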