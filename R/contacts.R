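#' Default side-chain class table
#'
#' Maps each standard 3-letter residue name to one of `hydrophobic`,
#' `charged`, `polar_uncharged`. Tyrosine is placed with the hydrophobics
#' (its ring dominates pocket packing); glycine with the polar-uncharged
#' and histidine with the charged set — both conventions, and the whole
#' table is overridable (pass your own named vector, or a JSON file via
#' [read_class_table()]). Unknown codes classify as `"other"`.
#'
#' @return Named character vector: residue name to class.
#' @export
default_class_table <- function() {
  c(ALA = "hydrophobic", VAL = "hydrophobic", LEU = "hydrophobic",
    ILE = "hydrophobic", MET = "hydrophobic", PHE = "hydrophobic",
    TRP = "hydrophobic", PRO = "hydrophobic", TYR = "hydrophobic",
    ASP = "charged", GLU = "charged", LYS = "charged",
    ARG = "charged", HIS = "charged",
    SER = "polar_uncharged", THR = "polar_uncharged",
    ASN = "polar_uncharged", GLN = "polar_uncharged",
    CYS = "polar_uncharged", GLY = "polar_uncharged")
}

#' Side-chain class of a residue
#'
#' @param residue_name 3-letter residue code(s); vectorised.
#' @param class_table Named character vector (see [default_class_table()]).
#' @return Character vector of classes; unknown codes give `"other"`.
#' @export
classify_residue <- function(residue_name, class_table = default_class_table()) {
  cls <- unname(class_table[toupper(residue_name)])
  cls[is.na(cls)] <- "other"
  cls
}

#' Contact census of receptor residues around the ligand
#'
#' A receptor residue is in contact in a frame iff its minimum atom-atom
#' minimum-image distance to any ligand atom is at most `cutoff`
#' (inclusive). The census reports per-residue contact occupancy over
#' retained frames, the mean per-frame count of contacting residues, and —
#' for residues whose occupancy reaches `occupancy_threshold` — counts by
#' side-chain class. All atoms participate by default (set
#' `heavy_atoms_only = TRUE` to drop hydrogens on both sides).
#'
#' @param traj An `md_trajectory`.
#' @param topology An `md_topology`.
#' @param cutoff Contact distance in angstrom (default 3.0).
#' @param class_table Residue class table (see [default_class_table()]).
#' @param occupancy_threshold Minimum occupancy for census membership
#'   (default 0.5).
#' @param heavy_atoms_only Drop hydrogens before measuring (default FALSE).
#' @param stride Frame stride (default 1).
#' @return Object of class `contact_census`; `tidy()` is the per-residue
#'   occupancy table, `glance()` the counts.
#' @export
contact_census <- function(traj, topology, cutoff = 3.0,
                           class_table = default_class_table(),
                           occupancy_threshold = 0.5,
                           heavy_atoms_only = FALSE, stride = 1) {
  if (!(cutoff > 0)) abort("`cutoff` must be positive")
  grp <- topology_groups(topology)
  il <- grp$ligand; ir <- grp$receptor
  if (heavy_atoms_only) {
    hyd <- toupper(topology$element) == "H"
    il <- il[!hyd[il]]; ir <- ir[!hyd[ir]]
  }
  if (length(il) == 0) abort("empty ligand group")
  if (length(ir) == 0) abort("empty receptor group")
  idx <- retained_frames(traj, stride)
  box <- traj$box
  key <- residue_id(topology, ir)
  ukey <- unique(key)
  first <- ir[!duplicated(key)]

  hits <- matrix(0, nrow = length(ukey), ncol = length(idx),
                 dimnames = list(ukey, NULL))
  for (t in seq_along(idx)) {
    x <- traj$coords[[idx[t]]]
    dx <- outer(x[ir, 1], x[il, 1], "-")
    dy <- outer(x[ir, 2], x[il, 2], "-")
    dz <- outer(x[ir, 3], x[il, 3], "-")
    if (!is.null(box)) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      dz <- dz - box[3] * round(dz / box[3])
    }
    r2min <- apply(dx^2 + dy^2 + dz^2, 1, min)
    resmin <- tapply(r2min, key, min)[ukey]
    hits[, t] <- as.numeric(resmin <= cutoff^2)
  }
  occupancy <- rowMeans(hits)
  per_frame_count <- colSums(hits)

  per_residue <- tibble(
    chain_id = topology$chain_id[first],
    residue_index = topology$residue_index[first],
    residue_name = topology$residue_name[first],
    class = classify_residue(topology$residue_name[first], class_table),
    occupancy = unname(occupancy),
    in_census = unname(occupancy) >= occupancy_threshold
  )
  census <- per_residue[per_residue$in_census, ]
  class_counts <- table(factor(census$class,
    levels = c("hydrophobic", "charged", "polar_uncharged", "other")))
  structure(list(
    per_residue = per_residue,
    class_counts = as_tibble(class_counts, .name_repair = ~ c("class", "n")),
    n_census = nrow(census),
    mean_contact_count = mean(per_frame_count),
    cutoff = cutoff,
    occupancy_threshold = occupancy_threshold,
    n_frames = length(idx)
  ), class = "contact_census")
}

#' @export
print.contact_census <- function(x, ...) {
  cat("<contact_census> cutoff ", x$cutoff, " A, ", x$n_frames, " frames\n",
      "  residues with occupancy >= ", x$occupancy_threshold, ": ",
      x$n_census, " (mean per-frame contacts ",
      sprintf("%.2f", x$mean_contact_count), ")\n", sep = "")
  cc <- x$class_counts
  cat("  classes: ", paste(sprintf("%s %d", cc$class, cc$n), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname contact_census
#' @param x A `contact_census`.
#' @param ... Unused.
#' @method tidy contact_census
#' @export
tidy.contact_census <- function(x, ...) x$per_residue

#' @rdname contact_census
#' @method glance contact_census
#' @export
glance.contact_census <- function(x, ...) {
  cc <- setNames(as.list(x$class_counts$n), paste0("n_", x$class_counts$class))
  as_tibble(c(list(n_census = x$n_census,
                   mean_contact_count = x$mean_contact_count,
                   cutoff = x$cutoff,
                   occupancy_threshold = x$occupancy_threshold,
                   n_frames = x$n_frames), cc))
}

#' Center-of-mass distance series between two residues
#'
#' Per-frame minimum-image distance between the mass-weighted centers of
#' two residues — the pocket-penetration metric (e.g. ligand Trp4 against
#' receptor Phe272/Tyr273).
#'
#' @param traj An `md_trajectory`.
#' @param topology An `md_topology`.
#' @param residue_a,residue_b Residue selectors: either a residue number or
#'   a list/vector `c(chain, residue_index)` such as `list("L", 4)`.
#' @param stride Frame stride (default 1).
#' @return Tibble with columns `frame`, `time`, `distance` (angstrom) and
#'   attribute `mean_distance`.
#' @export
com_distance_series <- function(traj, topology, residue_a, residue_b,
                                stride = 1) {
  set_a <- resolve_residue_atoms(topology, residue_a)
  set_b <- resolve_residue_atoms(topology, residue_b)
  idx <- retained_frames(traj, stride)
  box <- traj$box
  d <- vapply(idx, function(t) {
    x <- traj$coords[[t]]
    ca <- center_of_mass(x, set_a, topology, box)
    cb <- center_of_mass(x, set_b, topology, box)
    sqrt(sum(min_image_displacement(ca, cb, box)^2))
  }, numeric(1))
  out <- tibble(frame = idx, time = traj$times[idx], distance = d)
  attr(out, "mean_distance") <- mean(d)
  out
}

resolve_residue_atoms <- function(topology, residue) {
  if (is.list(residue) || length(residue) == 2) {
    chain <- as.character(residue[[1]])
    rid <- as.integer(residue[[2]])
    idx <- which(topology$chain_id == chain & topology$residue_index == rid)
  } else {
    idx <- which(topology$residue_index == as.integer(residue))
    if (length(unique(topology$chain_id[idx])) > 1) {
      abort(paste0("residue ", residue, " is ambiguous across chains; ",
                   "pass c(chain, residue)"))
    }
  }
  if (length(idx) == 0) abort(paste0("residue not found: ", paste(unlist(residue), collapse = ":")))
  idx
}

#' Penetration-depth comparison between two systems
#'
#' Given per-pair center-of-mass mean distances from two systems, reports
#' the signed difference per residue pair. Sign convention:
#' `delta = mean(system_b) - mean(system_a)`, so a positive delta means the
#' pair sits farther apart (shallower penetration) in system B.
#'
#' @param means_a,means_b Named numeric vectors of mean COM distances
#'   (angstrom), same names = same residue pairs.
#' @param labels Optional length-2 system labels for the output.
#' @return Tibble with `pair`, the two means, and `delta`.
#' @export
penetration_report <- function(means_a, means_b,
                               labels = c("system_a", "system_b")) {
  if (!setequal(names(means_a), names(means_b))) {
    abort("the two systems must report the same residue pairs")
  }
  pairs <- names(means_a)
  out <- tibble(pair = pairs,
                a = unname(means_a[pairs]),
                b = unname(means_b[pairs]))
  out$delta <- out$b - out$a
  names(out)[2:3] <- labels
  out
}
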