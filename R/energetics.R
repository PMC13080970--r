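#' Nonbonded evaluation settings
#'
#' Plain-truncated pairwise nonbonded model: Coulomb
#' \eqn{k q_i q_j / r} and 12-6 Lennard-Jones
#' \eqn{4\epsilon_{ij}[(\sigma_{ij}/r)^{12} - (\sigma_{ij}/r)^6]} with
#' Lorentz-Berthelot combination (arithmetic-mean sigma, geometric-mean
#' epsilon, the Amber-family convention) and both terms set to zero beyond
#' the cutoff. The default 10 angstrom cutoff matches common production-MD
#' practice for the short-range part. Note this is deliberately the
#' short-range decomposable pairwise model only — no Ewald/mesh long-range
#' electrostatics — because a per-group, per-residue decomposition is only
#' well defined for pairwise terms; absolute totals therefore differ from
#' an engine that adds a mesh term, while decompositions and comparisons
#' between ligands remain meaningful.
#'
#' @param cutoff Cutoff in angstrom (default 10).
#' @param coulomb_constant Coulomb prefactor in kJ mol^-1 angstrom e^-2;
#'   default 1389.35458 (the CODATA-derived 138.935458 kJ mol^-1 nm e^-2).
#' @return A list of class `nonbonded_config`.
#' @export
nonbonded_config <- function(cutoff = 10.0, coulomb_constant = 1389.35458) {
  if (!(cutoff > 0)) abort("`cutoff` must be positive")
  structure(list(cutoff = cutoff, coulomb_constant = coulomb_constant,
                 combination_rule = "Lorentz-Berthelot", truncation = "plain"),
            class = "nonbonded_config")
}

#' Nonbonded energy of a single atom pair
#'
#' @param q_i,q_j Partial charges (e).
#' @param sigma_i,sigma_j Lennard-Jones sigma (nm).
#' @param eps_i,eps_j Lennard-Jones epsilon (kJ/mol).
#' @param r Distance (angstrom), must be positive; vectorised over `r`.
#' @param config A [nonbonded_config()].
#' @return Named list with numeric `coulomb` and `lj` (kJ/mol); both zero
#'   beyond the cutoff.
#' @export
pair_energy <- function(q_i, q_j, sigma_i, sigma_j, eps_i, eps_j, r,
                        config = nonbonded_config()) {
  if (any(r == 0)) abort("singularity: pair distance r = 0")
  within <- r <= config$cutoff
  coulomb <- ifelse(within, config$coulomb_constant * q_i * q_j / r, 0)
  sig <- 10 * (sigma_i + sigma_j) / 2   # nm -> angstrom
  eps <- sqrt(eps_i * eps_j)
  sr6 <- (sig / r)^6
  lj <- ifelse(within, 4 * eps * (sr6^2 - sr6), 0)
  list(coulomb = coulomb, lj = lj)
}

# cross-group pair energy matrices for one frame; returns list of
# na x nb coulomb and lj matrices (zero beyond cutoff, minimum-image r)
pair_energy_matrices <- function(coords, topology, ia, ib, config, box) {
  na <- length(ia); nb <- length(ib)
  dx <- outer(coords[ia, 1], coords[ib, 1], "-")
  dy <- outer(coords[ia, 2], coords[ib, 2], "-")
  dz <- outer(coords[ia, 3], coords[ib, 3], "-")
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  r <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(r == 0)) abort("singularity: zero cross-group pair distance")
  within <- r <= config$cutoff
  coul <- matrix(0, na, nb); lj <- matrix(0, na, nb)
  if (any(within)) {
    qq <- outer(topology$charge[ia], topology$charge[ib])
    coul[within] <- config$coulomb_constant * qq[within] / r[within]
    sig <- 10 * outer(topology$lj_sigma[ia], topology$lj_sigma[ib], "+") / 2
    eps <- sqrt(outer(topology$lj_epsilon[ia], topology$lj_epsilon[ib]))
    sr6 <- (sig[within] / r[within])^6
    lj[within] <- 4 * eps[within] * (sr6^2 - sr6)
  }
  list(coulomb = coul, lj = lj)
}

#' Interaction energy between two atom groups in one frame
#'
#' Sum of [pair_energy()] over all cross-group pairs at minimum-image
#' distances. This is the per-frame ligand-receptor interaction energy.
#'
#' @param coords N x 3 coordinate matrix (angstrom).
#' @param topology An `md_topology`.
#' @param group_a,group_b Group names or integer atom-index vectors; must
#'   be disjoint.
#' @param config A [nonbonded_config()].
#' @param box Optional orthorhombic box (angstrom).
#' @return Named list with `coulomb` and `lj` totals (kJ/mol).
#' @export
group_interaction_energy <- function(coords, topology,
                                     group_a = "ligand", group_b = "receptor",
                                     config = nonbonded_config(), box = NULL) {
  ia <- as_group_indices(topology, group_a)
  ib <- as_group_indices(topology, group_b)
  if (length(intersect(ia, ib)) > 0) abort("groups overlap: interaction energy undefined")
  if (length(ia) == 0 || length(ib) == 0) return(list(coulomb = 0, lj = 0))
  em <- pair_energy_matrices(coords, topology, ia, ib, config, box)
  list(coulomb = sum(em$coulomb), lj = sum(em$lj))
}

as_group_indices <- function(topology, group) {
  if (is.character(group)) {
    g <- topology_groups(topology)[[group]]
    if (is.null(g)) abort(paste0("unknown group '", group, "'"))
    g
  } else {
    as.integer(group)
  }
}

#' Per-residue decomposition of the cross-group interaction energy
#'
#' Attributes every cross-group pair energy to the residue (on the chosen
#' side) owning the participating atom, so the per-residue Coulomb/LJ
#' contributions sum exactly to the group total (same pair list, a strict
#' conservation property).
#'
#' @inheritParams group_interaction_energy
#' @param side `"ligand"` or `"receptor"`: which side's residues to
#'   attribute energies to.
#' @return Tibble with `chain_id`, `residue_index`, `residue_name`,
#'   `coulomb`, `lj`, `total` (kJ/mol), one row per residue of that side.
#' @export
residue_decomposition <- function(coords, topology,
                                  side = c("ligand", "receptor"),
                                  config = nonbonded_config(), box = NULL) {
  side <- arg_match(side)
  ia <- as_group_indices(topology, "ligand")
  ib <- as_group_indices(topology, "receptor")
  em <- pair_energy_matrices(coords, topology, ia, ib, config, box)
  own <- if (side == "ligand") ia else ib
  if (side == "ligand") {
    coul <- rowSums(em$coulomb); lj <- rowSums(em$lj)
  } else {
    coul <- colSums(em$coulomb); lj <- colSums(em$lj)
  }
  key <- residue_id(topology, own)
  agg <- rowsum(cbind(coul, lj), group = key, reorder = FALSE)
  first <- !duplicated(key)
  tibble(
    chain_id = topology$chain_id[own][first],
    residue_index = topology$residue_index[own][first],
    residue_name = topology$residue_name[own][first],
    coulomb = unname(agg[, 1]), lj = unname(agg[, 2]),
    total = unname(agg[, 1] + agg[, 2])
  )
}

#' Interaction-energy series over a trajectory
#'
#' Evaluates the cross-group Coulomb and Lennard-Jones energy for every
#' retained frame (discard window honoured, deterministic stride from the
#' first retained frame) and summarises mean and standard deviation of the
#' per-frame values; the per-residue decomposition is averaged over the
#' same frames.
#'
#' @param traj An `md_trajectory`.
#' @param topology An `md_topology`.
#' @param config A [nonbonded_config()].
#' @param stride Frame stride (default 1).
#' @param side Side for the per-residue decomposition (default receptor).
#' @return Object of class `energy_breakdown`: `tidy()` returns the
#'   per-frame series (or per-residue means with `type = "residue"`),
#'   `glance()` the mean/sd summary.
#' @export
trajectory_energy_series <- function(traj, topology,
                                     config = nonbonded_config(), stride = 1,
                                     side = c("receptor", "ligand")) {
  side <- arg_match(side)
  idx <- retained_frames(traj, stride)
  box <- traj$box
  ia <- as_group_indices(topology, "ligand")
  ib <- as_group_indices(topology, "receptor")
  if (length(intersect(ia, ib)) > 0) abort("groups overlap")
  own <- if (side == "ligand") ia else ib
  key <- residue_id(topology, own)
  first <- !duplicated(key)

  coul <- numeric(length(idx)); lj <- numeric(length(idx))
  res_acc <- NULL
  for (t in seq_along(idx)) {
    em <- pair_energy_matrices(traj$coords[[idx[t]]], topology, ia, ib, config, box)
    coul[t] <- sum(em$coulomb); lj[t] <- sum(em$lj)
    rc <- if (side == "ligand") rowSums(em$coulomb) else colSums(em$coulomb)
    rl <- if (side == "ligand") rowSums(em$lj) else colSums(em$lj)
    agg <- rowsum(cbind(rc, rl), group = key, reorder = FALSE)
    res_acc <- if (is.null(res_acc)) agg else res_acc + agg
  }
  res_mean <- res_acc / length(idx)
  per_frame <- tibble(frame = idx, time = traj$times[idx],
                      coulomb = coul, lj = lj, total = coul + lj)
  per_residue <- tibble(
    chain_id = topology$chain_id[own][first],
    residue_index = topology$residue_index[own][first],
    residue_name = topology$residue_name[own][first],
    coulomb = unname(res_mean[, 1]), lj = unname(res_mean[, 2]),
    total = unname(res_mean[, 1] + res_mean[, 2])
  )
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  structure(list(
    per_frame = per_frame,
    per_residue = per_residue,
    side = side,
    summary = tibble(
      coulomb_mean = mean(coul), coulomb_sd = sd0(coul),
      lj_mean = mean(lj), lj_sd = sd0(lj),
      total_mean = mean(coul + lj), total_sd = sd0(coul + lj),
      n_frames = length(idx)
    )
  ), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  s <- x$summary
  cat("<energy_breakdown> ", s$n_frames, " frames\n", sep = "")
  cat(sprintf("  total:   %.2f +/- %.2f kJ/mol\n", s$total_mean, s$total_sd))
  cat(sprintf("  coulomb: %.2f +/- %.2f kJ/mol\n", s$coulomb_mean, s$coulomb_sd))
  cat(sprintf("  LJ:      %.2f +/- %.2f kJ/mol\n", s$lj_mean, s$lj_sd))
  invisible(x)
}

#' @rdname trajectory_energy_series
#' @param x An `energy_breakdown`.
#' @param type `"frame"` for the per-frame series, `"residue"` for the
#'   per-residue means.
#' @param ... Unused.
#' @method tidy energy_breakdown
#' @export
tidy.energy_breakdown <- function(x, type = c("frame", "residue"), ...) {
  type <- arg_match(type)
  if (type == "frame") x$per_frame else x$per_residue
}

#' @rdname trajectory_energy_series
#' @method glance energy_breakdown
#' @export
glance.energy_breakdown <- function(x, ...) x$summary
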