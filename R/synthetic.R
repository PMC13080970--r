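#' Pocket layout for the synthetic scaffold
#'
#' Describes the pseudo-ligand planted next to the receptor scaffold: each
#' ligand atom carries explicit charge, Lennard-Jones parameters, mass and
#' an offset (angstrom) from the pocket residue's Calpha. The default is
#' the minimal closed-form fixture: one +1 e ligand atom placed 10
#' angstrom from a -1 e pocket Calpha, every other atom neutral and
#' epsilon-free, so the planted group interaction energy is exactly the
#' single-pair Coulomb term plus one Lennard-Jones term.
#'
#' @param pocket_residue Receptor residue hosting the pocket (default 1).
#' @param pocket_charge Charge planted on the pocket Calpha (e).
#' @param pocket_epsilon Lennard-Jones epsilon of the pocket Calpha
#'   (kJ/mol); other receptor atoms have epsilon 0.
#' @param ligand_atoms Tibble with one row per ligand atom: `atom_name`,
#'   `residue_index`, `residue_name`, `charge`, `lj_sigma` (nm),
#'   `lj_epsilon` (kJ/mol), `mass` (amu), `dx`, `dy`, `dz` (angstrom
#'   offsets from the pocket Calpha).
#' @return A list of class `pocket_spec`.
#' @export
pocket_spec <- function(pocket_residue = 1L, pocket_charge = -1,
                        pocket_epsilon = 0.5, ligand_atoms = NULL) {
  if (is.null(ligand_atoms)) {
    ligand_atoms <- tibble(
      atom_name = "C1", residue_index = 1L, residue_name = "LIG",
      charge = 1, lj_sigma = 0.3, lj_epsilon = 0.5, mass = 100,
      dx = 10, dy = 0, dz = 0
    )
  }
  structure(list(pocket_residue = as.integer(pocket_residue),
                 pocket_charge = pocket_charge,
                 pocket_epsilon = pocket_epsilon,
                 ligand_atoms = as_tibble(ligand_atoms)),
            class = "pocket_spec")
}

# closed-form energies of the default pocket (single ligand atom vs pocket
# Calpha at 10 A) — used by tests as the planted expectation
pocket_planted_energy <- function(pocket = pocket_spec(),
                                  receptor_sigma = 0.34,
                                  config = nonbonded_config()) {
  la <- pocket$ligand_atoms
  r <- sqrt(la$dx^2 + la$dy^2 + la$dz^2)
  within <- r <= config$cutoff
  coul <- sum(ifelse(within, config$coulomb_constant * la$charge * pocket$pocket_charge / r, 0))
  sig <- 10 * (la$lj_sigma + receptor_sigma) / 2
  eps <- sqrt(la$lj_epsilon * pocket$pocket_epsilon)
  sr6 <- (sig / r)^6
  lj <- sum(ifelse(within, 4 * eps * (sr6^2 - sr6), 0))
  list(coulomb = coul, lj = lj)
}

#' Build a two-state synthetic receptor scaffold
#'
#' Constructs a compact Calpha-only receptor scaffold (one atom per
#' residue on a helical arc) with two reference conformations that differ
#' only in the activation-marker geometry: the active reference plants the
#' marker distance/angle at 17.0 angstrom / 55 degrees, the inactive one
#' at 21.0 angstrom / 35 degrees — bracketing the 19.0 angstrom / 45
#' degree thresholds with margins of 2 angstrom and 10 degrees, far
#' outside the default noise amplitude. A pseudo-ligand with known
#' charges and Lennard-Jones parameters is placed in a pocket at stated
#' distances (see [pocket_spec()]), so every downstream analysis has a
#' closed-form expectation.
#'
#' @param n_residues Number of receptor residues (default 40; must cover
#'   the marker residues).
#' @param pocket A [pocket_spec()].
#' @param marker_distance_residues,marker_angle_residues Marker residue
#'   numbers (defaults 10/30 and 15-20-25, vertex 20).
#' @param active_marker,inactive_marker Length-2 numeric `(distance
#'   angstrom, angle degrees)` planted in the two references.
#' @return List of class `synthetic_scaffold` with `topology`,
#'   `active_ref` / `inactive_ref` (N x 3 matrices), `criteria` (an
#'   [activation_criteria()] consistent with the scaffold numbering) and
#'   `pocket`.
#' @export
build_scaffold <- function(n_residues = 40, pocket = pocket_spec(),
                           marker_distance_residues = c(10L, 30L),
                           marker_angle_residues = c(15L, 20L, 25L),
                           active_marker = c(17.0, 55.0),
                           inactive_marker = c(21.0, 35.0)) {
  markers <- c(marker_distance_residues, marker_angle_residues)
  if (anyDuplicated(markers)) abort("marker residues must be distinct")
  if (n_residues < max(markers)) {
    abort("`n_residues` must cover the largest marker residue index")
  }
  if (pocket$pocket_residue %in% markers) {
    abort("pocket residue must not be a marker residue")
  }

  # helical arc for non-marker residues; markers are placed explicitly in
  # two clusters well away from the helix so reference geometry is exact
  i <- seq_len(n_residues)
  base <- cbind(8 * cos(i * 100 * pi / 180),
                8 * sin(i * 100 * pi / 180),
                1.5 * i)
  place_markers <- function(coords, d, theta_deg) {
    coords[marker_distance_residues[1], ] <- c(60, 0, 0)
    coords[marker_distance_residues[2], ] <- c(60 + d, 0, 0)
    vertex <- c(0, 60, 0)
    th <- theta_deg * pi / 180
    coords[marker_angle_residues[2], ] <- vertex
    coords[marker_angle_residues[1], ] <- vertex + c(10, 0, 0)
    coords[marker_angle_residues[3], ] <- vertex + 10 * c(cos(th), sin(th), 0)
    coords
  }
  active_rec <- place_markers(base, active_marker[1], active_marker[2])
  inactive_rec <- place_markers(base, inactive_marker[1], inactive_marker[2])

  la <- pocket$ligand_atoms
  pocket_ca <- base[pocket$pocket_residue, ]
  lig_xyz <- cbind(pocket_ca[1] + la$dx, pocket_ca[2] + la$dy,
                   pocket_ca[3] + la$dz)

  res_names <- rep(c("ALA", "SER", "ASP", "LEU", "THR", "ARG", "PHE",
                     "GLN", "LYS", "VAL"), length.out = n_residues)
  charges <- rep(0, n_residues)
  charges[pocket$pocket_residue] <- pocket$pocket_charge
  eps <- rep(0, n_residues)
  eps[pocket$pocket_residue] <- pocket$pocket_epsilon
  atoms <- bind_rows(
    tibble(atom_name = "CA", element = "C",
           residue_index = i, residue_name = res_names, chain_id = "A",
           charge = charges, lj_sigma = 0.34, lj_epsilon = eps, mass = 12.011),
    tibble(atom_name = la$atom_name, element = "C",
           residue_index = la$residue_index, residue_name = la$residue_name,
           chain_id = "L", charge = la$charge, lj_sigma = la$lj_sigma,
           lj_epsilon = la$lj_epsilon, mass = la$mass)
  )
  top <- topology(atoms,
                  groups = list(receptor = seq_len(n_residues),
                                ligand = n_residues + seq_len(nrow(la))))
  criteria <- activation_criteria(
    distance_residues = marker_distance_residues,
    angle_residues = marker_angle_residues,
    distance_threshold = 19.0, angle_threshold = 45.0, chain = "A"
  )
  structure(list(topology = top,
                 active_ref = rbind(active_rec, lig_xyz),
                 inactive_ref = rbind(inactive_rec, lig_xyz),
                 criteria = criteria,
                 pocket = pocket,
                 active_marker = active_marker,
                 inactive_marker = inactive_marker),
            class = "synthetic_scaffold")
}

#' Parameterisation of a planted two-state ensemble
#'
#' Full description of the synthetic study conditions: frame count,
#' planted active-frame fraction, per-residue isotropic Gaussian noise
#' amplitude, the two reference marker geometries, box and seed.
#' Construction fails when the marker margins are not at least five times
#' the noise-induced standard deviation of the corresponding marker
#' (distance sd ~ sigma*sqrt(2); angle sd ~ sigma*sqrt(2)/arm in radians),
#' so planted states are recoverable essentially without mislabels.
#'
#' @param n_frames Number of frames.
#' @param f_active Planted active-frame fraction in `[0, 1]`.
#' @param noise_sigma Isotropic Gaussian sigma per coordinate (angstrom,
#'   default 0.10). Either a scalar applied to every atom or a vector with
#'   one value per atom of the scaffold topology (receptor atoms first,
#'   then ligand atoms), which allows e.g. a rigid alignment subset
#'   (sigma 0) with noisy measured residues.
#' @param seed Integer seed; all generator randomness flows from it.
#' @param scaffold A [build_scaffold()] result (default scaffold if NULL).
#' @param box Optional orthorhombic box (angstrom).
#' @param dt Frame spacing in ps (default 1).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_frames, f_active, noise_sigma = 0.10,
                           seed = 1L, scaffold = NULL, box = NULL, dt = 1) {
  if (f_active < 0 || f_active > 1) abort("`f_active` must be in [0, 1]")
  if (n_frames < 1) abort("`n_frames` must be positive")
  if (any(noise_sigma < 0)) abort("`noise_sigma` must be non-negative")
  if (is.null(scaffold)) scaffold <- build_scaffold()
  n_atoms <- nrow(scaffold$topology)
  if (!length(noise_sigma) %in% c(1L, n_atoms)) {
    abort("`noise_sigma` must be a scalar or one value per scaffold atom")
  }
  sigma_atom <- rep_len(noise_sigma, n_atoms)
  crit <- scaffold$criteria
  marker_atoms <- unlist(resolve_criteria(scaffold$topology, crit))
  marker_sigma <- max(sigma_atom[marker_atoms])
  margin_d <- min(abs(scaffold$active_marker[1] - crit$distance_threshold),
                  abs(scaffold$inactive_marker[1] - crit$distance_threshold))
  margin_a <- min(abs(scaffold$active_marker[2] - crit$angle_threshold),
                  abs(scaffold$inactive_marker[2] - crit$angle_threshold))
  sd_d <- marker_sigma * sqrt(2)
  sd_a <- marker_sigma * sqrt(2) / 10 * 180 / pi  # 10 A marker arms
  if (marker_sigma > 0 && (margin_d <= 5 * sd_d || margin_a <= 5 * sd_a)) {
    abort(paste0("marker margins (", margin_d, " A, ", margin_a,
                 " deg) must exceed 5x the noise-induced sd; ",
                 "reduce `noise_sigma`"))
  }
  structure(list(n_frames = as.integer(n_frames), f_active = f_active,
                 noise_sigma = noise_sigma, sigma_atom = sigma_atom,
                 seed = as.integer(seed),
                 scaffold = scaffold, box = box, dt = dt),
            class = "synthetic_spec")
}

#' Generate a planted two-state ensemble
#'
#' Draws each frame's state as an independent Bernoulli(`f_active`) pick
#' of the active or inactive reference conformation, then adds i.i.d.
#' isotropic Gaussian displacement of amplitude `noise_sigma` to every
#' atom coordinate. The same seed always yields the identical trajectory.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_ensemble` with `trajectory`,
#'   `topology`, `criteria`, `states` (logical vector of planted
#'   active-frame flags) and `spec`.
#' @export
generate_ensemble <- function(spec) {
  sc <- spec$scaffold
  n_atoms <- nrow(sc$topology)
  sigma <- spec$sigma_atom
  noisy <- any(sigma > 0)
  withr::with_seed(spec$seed, {
    states <- runif(spec$n_frames) < spec$f_active
    coords <- lapply(seq_len(spec$n_frames), function(t) {
      ref <- if (states[t]) sc$active_ref else sc$inactive_ref
      if (noisy) {
        ref + matrix(rnorm(3 * n_atoms, sd = sigma), nrow = n_atoms)
      } else {
        ref
      }
    })
  })
  traj <- trajectory(coords, times = spec$dt * (seq_len(spec$n_frames) - 1),
                     box = spec$box)
  structure(list(trajectory = traj, topology = sc$topology,
                 criteria = sc$criteria, states = states, spec = spec),
            class = "synthetic_ensemble")
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat("<synthetic_ensemble> ", x$spec$n_frames, " frames, planted f_active = ",
      x$spec$f_active, ", sigma = ", x$spec$noise_sigma, " A, seed ",
      x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Plant a two-atom trajectory with closed-form energies
#'
#' Builds a minimal two-atom system whose atoms sit at the given
#' separations along x, one frame per separation, and returns the exact
#' per-frame Coulomb and Lennard-Jones energies computed in closed form
#' alongside — an oracle fixture for the energetics stage.
#'
#' @param distances Positive separations in angstrom, one per frame.
#' @param q Length-2 charges (e).
#' @param sigma Length-2 Lennard-Jones sigma (nm).
#' @param epsilon Length-2 Lennard-Jones epsilon (kJ/mol).
#' @param mass Length-2 masses (amu).
#' @param box Optional orthorhombic box; separations must stay below half
#'   the smallest edge so the minimum image is the planted one.
#' @param config A [nonbonded_config()].
#' @return List with `trajectory`, `topology` and `analytic` (tibble of
#'   `time`, `coulomb`, `lj`, `total`).
#' @export
plant_energy_trajectory <- function(distances, q = c(1, -1),
                                    sigma = c(0.3, 0.3),
                                    epsilon = c(0.5, 0.5),
                                    mass = c(12, 12), box = NULL,
                                    config = nonbonded_config()) {
  if (any(!(distances > 0))) abort("separations must be positive")
  if (!is.null(box) && any(distances >= min(box) / 2)) {
    abort("separations must be below half the smallest box edge")
  }
  top <- topology(
    tibble(atom_name = c("Q1", "Q2"), element = "C",
           residue_index = c(1L, 1L), residue_name = c("LIG", "REC"),
           chain_id = c("L", "A"), charge = q, lj_sigma = sigma,
           lj_epsilon = epsilon, mass = mass),
    groups = list(ligand = 1L, receptor = 2L)
  )
  coords <- lapply(distances, function(d)
    rbind(c(0, 0, 0), c(d, 0, 0)))
  traj <- trajectory(coords, times = seq_along(distances) - 1, box = box)
  # closed form, written out independently of pair_energy()
  within <- distances <= config$cutoff
  coul <- ifelse(within, config$coulomb_constant * q[1] * q[2] / distances, 0)
  sig_ij <- 10 * (sigma[1] + sigma[2]) / 2
  eps_ij <- sqrt(epsilon[1] * epsilon[2])
  sr6 <- (sig_ij / distances)^6
  lj <- ifelse(within, 4 * eps_ij * (sr6 * sr6 - sr6), 0)
  list(trajectory = traj, topology = top,
       analytic = tibble(time = seq_along(distances) - 1,
                         coulomb = coul, lj = lj, total = coul + lj))
}
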