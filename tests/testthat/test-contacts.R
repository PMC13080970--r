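test_that("the 3 A cutoff straddle is inclusive at the boundary", {
  atoms <- toy_atoms(3, residue_index = c(1, 1, 2),
                     residue_name = c("LIG", "PHE", "SER"))
  atoms$chain_id <- c("L", "A", "A")
  top <- topology(atoms, groups = list(ligand = 1L, receptor = 2:3))
  coords <- rbind(c(0, 0, 0), c(2.9, 0, 0), c(3.1, 0, 0))
  cc <- contact_census(trajectory(list(coords)), top)
  per <- tidy(cc)
  expect_equal(per$occupancy[per$residue_index == 1], 1)
  expect_equal(per$occupancy[per$residue_index == 2], 0)
  expect_identical(cc$n_census, 1L)
  # exactly at the cutoff counts as contact
  coords[3, ] <- c(3.0, 0, 0)
  cc <- contact_census(trajectory(list(coords)), top)
  expect_identical(cc$n_census, 2L)
})

test_that("a static repeated frame yields occupancies of exactly 0 or 1", {
  en <- generate_ensemble(synthetic_spec(10, 1, noise_sigma = 0, seed = 2))
  cc <- contact_census(en$trajectory, en$topology, cutoff = 12)
  expect_true(all(tidy(cc)$occupancy %in% c(0, 1)))
  expect_equal(cc$mean_contact_count, cc$n_census)
})

test_that("census matches the exhaustive all-pairs oracle on random frames", {
  for (seed in 1:10) {
    sys <- random_system(seed, n_atoms = 40, box = c(18, 18, 18))
    cutoff <- withr::with_seed(seed + 100, runif(1, 2, 6))
    cc <- contact_census(trajectory(list(sys$coords), box = sys$box),
                         sys$topology, cutoff = cutoff)
    per <- tidy(cc)
    got <- sprintf("%s:%d", per$chain_id[per$occupancy == 1],
                   per$residue_index[per$occupancy == 1])
    ref <- naive_contact_set(sys$coords, sys$topology, sys$box, cutoff)
    expect_setequal(got, ref)
  }
})

test_that("growing the cutoff never shrinks the contact set", {
  sys <- random_system(77, n_atoms = 50, box = c(20, 20, 20))
  tr <- trajectory(list(sys$coords), box = sys$box)
  sets <- lapply(c(2, 3, 4, 6, 8), function(cut) {
    per <- tidy(contact_census(tr, sys$topology, cutoff = cut))
    per$residue_index[per$occupancy >= 0.5]
  })
  for (k in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
  }
})

test_that("side-chain classes follow the table with TYR hydrophobic", {
  expect_identical(classify_residue("TYR"), "hydrophobic")
  expect_identical(classify_residue("ASP"), "charged")
  expect_identical(classify_residue("SER"), "polar_uncharged")
  expect_identical(classify_residue("XYZ"), "other")
  expect_identical(classify_residue(c("trp", "GLU")), c("hydrophobic", "charged"))
  # the shipped JSON table equals the built-in default
  tab <- read_class_table(system.file("extdata", "default_class_table.json",
                                      package = "gpcrmd"))
  expect_identical(tab, default_class_table())
})

test_that("census class counts cover exactly the occupancy-selected residues", {
  en <- generate_ensemble(synthetic_spec(20, 0.5, seed = 5))
  cc <- contact_census(en$trajectory, en$topology, cutoff = 15)
  expect_identical(sum(cc$class_counts$n), cc$n_census)
  expect_gte(cc$n_census, 1L)
})

test_that("COM distance series reproduces planted geometries", {
  atoms <- toy_atoms(4, residue_index = c(1, 1, 2, 2), mass = c(1, 3, 2, 2))
  atoms$chain_id <- c("L", "L", "A", "A")
  top <- topology(atoms, groups = list(ligand = 1:2, receptor = 3:4))

  # masses 1 and 3 at x = 0 and 4 -> COM at x = 3; receptor COM at x = 6
  f <- rbind(c(0, 0, 0), c(4, 0, 0), c(5, 0, 0), c(7, 0, 0))
  out <- com_distance_series(trajectory(list(f)), top,
                             list("L", 1), list("A", 2))
  expect_equal(out$distance, 3)

  # same residue against itself is identically zero
  out <- com_distance_series(trajectory(list(f)), top,
                             list("L", 1), list("L", 1))
  expect_equal(out$distance, 0)

  # alternating planted separations 5 and 7 -> mean 6
  f5 <- rbind(c(0, 0, 0), c(0, 0, 0), c(5, 0, 0), c(5, 0, 0))
  f7 <- rbind(c(0, 0, 0), c(0, 0, 0), c(7, 0, 0), c(7, 0, 0))
  out <- com_distance_series(trajectory(rep(list(f5, f7), 5)), top,
                             list("L", 1), list("A", 2))
  expect_equal(attr(out, "mean_distance"), 6)
  expect_equal(unique(out$distance), c(5, 7))
})

test_that("penetration deltas carry the b-minus-a sign convention", {
  a <- c(trp4_phe272 = 8.0, trp4_tyr273 = 9.0, phe1_phe294 = 10.0)
  expect_true(all(penetration_report(a, a)$delta == 0))

  b <- a + 2
  rep2 <- penetration_report(a, b, labels = c("dota", "dotp"))
  expect_equal(rep2$delta, rep(2, 3))
  expect_identical(names(rep2), c("pair", "dota", "dotp", "delta"))

  mixed <- a + c(1, -1, 0)
  rep3 <- penetration_report(a, mixed)
  expect_equal(rep3$delta[match(c("trp4_phe272", "trp4_tyr273", "phe1_phe294"),
                                rep3$pair)], c(1, -1, 0))
  expect_error(penetration_report(a, b[-1]), "same residue pairs")
})
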