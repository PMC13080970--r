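# Shared fixtures and independent oracles. Oracles are deliberately
# written as plain scalar loops / closed forms, never by calling the
# package's vectorised implementations.

toy_atoms <- function(n, residue_index = seq_len(n), chain = "A",
                      residue_name = "ALA", charge = 0, lj_sigma = 0.3,
                      lj_epsilon = 0, mass = 12) {
  tibble::tibble(
    atom_name = "CA", element = "C",
    residue_index = as.integer(residue_index),
    residue_name = residue_name, chain_id = chain,
    charge = charge, lj_sigma = lj_sigma,
    lj_epsilon = lj_epsilon, mass = mass
  )
}

toy_topology <- function(n = 10, n_ligand = 2, ...) {
  topology(toy_atoms(n, ...),
           groups = list(ligand = seq_len(n_ligand),
                         receptor = (n_ligand + 1):n))
}

# random charged/LJ system split into two groups, coordinates in a box
random_system <- function(seed, n_atoms = 60, box = c(30, 30, 30)) {
  withr::with_seed(seed, {
    n_lig <- sample(2:max(3, n_atoms %/% 4), 1)
    atoms <- tibble::tibble(
      atom_name = "CA", element = "C",
      residue_index = as.integer(ceiling(seq_len(n_atoms) / 3)),
      residue_name = sample(c("ALA", "ASP", "SER", "PHE", "ARG"),
                            n_atoms, replace = TRUE),
      chain_id = rep(c("L", "A"), c(n_lig, n_atoms - n_lig)),
      charge = round(runif(n_atoms, -1, 1), 3),
      lj_sigma = round(runif(n_atoms, 0.25, 0.4), 3),
      lj_epsilon = round(runif(n_atoms, 0, 1), 3),
      mass = round(runif(n_atoms, 1, 30), 2)
    )
    top <- topology(atoms, groups = list(ligand = seq_len(n_lig),
                                         receptor = (n_lig + 1):n_atoms))
    coords <- cbind(runif(n_atoms, 0, box[1]),
                    runif(n_atoms, 0, box[2]),
                    runif(n_atoms, 0, box[3]))
    list(topology = top, coords = coords, box = box)
  })
}

# scalar double-loop nonbonded oracle with the same minimum-image rule
naive_group_energy <- function(coords, top, box, cutoff = 10,
                               kc = 1389.35458) {
  grp <- topology_groups(top)
  coul <- 0; lj <- 0
  for (i in grp$ligand) {
    for (j in grp$receptor) {
      d <- coords[j, ] - coords[i, ]
      if (!is.null(box)) {
        for (k in 1:3) d[k] <- d[k] - box[k] * round(d[k] / box[k])
      }
      r <- sqrt(sum(d^2))
      if (r <= cutoff) {
        coul <- coul + kc * top$charge[i] * top$charge[j] / r
        s <- 10 * (top$lj_sigma[i] + top$lj_sigma[j]) / 2
        e <- sqrt(top$lj_epsilon[i] * top$lj_epsilon[j])
        lj <- lj + 4 * e * ((s / r)^12 - (s / r)^6)
      }
    }
  }
  list(coulomb = coul, lj = lj)
}

# exhaustive contact-set oracle: residues of the receptor whose minimum
# atom-atom minimum-image distance to any ligand atom is <= cutoff
naive_contact_set <- function(coords, top, box, cutoff) {
  grp <- topology_groups(top)
  keys <- character(0)
  for (j in grp$receptor) {
    hit <- FALSE
    for (i in grp$ligand) {
      d <- coords[j, ] - coords[i, ]
      if (!is.null(box)) {
        for (k in 1:3) d[k] <- d[k] - box[k] * round(d[k] / box[k])
      }
      if (sqrt(sum(d^2)) <= cutoff) { hit <- TRUE; break }
    }
    if (hit) keys <- c(keys, paste0(top$chain_id[j], ":", top$residue_index[j]))
  }
  unique(keys)
}

# single frame with the five marker atoms at exact distance/angle values;
# returns trajectory + topology + criteria for boundary tests
marker_frame <- function(d, theta_deg, n_frames = 1) {
  top <- topology(toy_atoms(6),
                  groups = list(ligand = 6L, receptor = 1:5))
  coords <- matrix(0, 6, 3)
  coords[1, ] <- c(50, 0, 0)           # distance residue 1
  coords[2, ] <- c(50 + d, 0, 0)       # distance residue 2
  th <- theta_deg * pi / 180
  coords[3, ] <- c(10, 50, 0)          # arm a
  coords[4, ] <- c(0, 50, 0)           # vertex
  coords[5, ] <- c(10 * cos(th), 50 + 10 * sin(th), 0)  # arm c
  coords[6, ] <- c(0, 0, 30)           # ligand pseudo-atom
  crit <- activation_criteria(c(1L, 2L), c(3L, 4L, 5L))
  list(trajectory = trajectory(rep(list(coords), n_frames),
                               times = seq_len(n_frames) - 1),
       topology = top, criteria = crit)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# two-sided 99% binomial CI half-width check
within_binomial_ci <- function(estimate, p, n, level = 0.99) {
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  abs(estimate - p) <= max(half, 1e-12)
}
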