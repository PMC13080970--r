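#' Build a topology from an atom table and group selections
#'
#' A topology is the static description of the simulated system that every
#' analysis stage consumes: per-atom identity, partial charge, Lennard-Jones
#' parameters and mass, plus named group selections. At minimum the groups
#' `"ligand"` and `"receptor"` must be present and disjoint; analyses ignore
#' any atoms (waters, lipids, ions) outside these two groups.
#'
#' Units follow the conventions of the source formats: coordinates and all
#' distances are in angstrom, `lj_sigma` is in nanometre (force-field
#' convention), `lj_epsilon` in kJ/mol, `charge` in elementary-charge units,
#' `mass` in amu. Atom indices are 1-based everywhere a user sees them.
#'
#' @param atoms Data frame with one row per atom and columns `atom_name`,
#'   `element`, `residue_index`, `residue_name`, `chain_id`, `charge`,
#'   `lj_sigma`, `lj_epsilon`, `mass`. Row order defines the atom index.
#' @param groups Named list of integer vectors of 1-based atom indices.
#'   Must contain `"ligand"` and `"receptor"`.
#' @param validate If `TRUE` (default), reject a topology with any
#'   invariant violation (see [validate_topology()]).
#' @return An object of class `md_topology`: the atom tibble (with an
#'   `atom_index` column) plus a `groups` attribute.
#' @seealso [validate_topology()], [resolve_atom()], [read_topology()]
#' @export
#' @examples
#' top <- topology(
#'   tibble::tibble(
#'     atom_name = c("C1", "CA"), element = c("C", "C"),
#'     residue_index = c(1L, 1L), residue_name = c("LIG", "ALA"),
#'     chain_id = c("L", "A"), charge = c(1, -1),
#'     lj_sigma = 0.3, lj_epsilon = 0.5, mass = 12
#'   ),
#'   groups = list(ligand = 1L, receptor = 2L)
#' )
topology <- function(atoms, groups, validate = TRUE) {
  required <- c("atom_name", "element", "residue_index", "residue_name",
                "chain_id", "charge", "lj_sigma", "lj_epsilon", "mass")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  atoms <- as_tibble(atoms)
  atoms$atom_index <- seq_len(nrow(atoms))
  atoms <- atoms[, c("atom_index", required)]
  atoms$residue_index <- as.integer(atoms$residue_index)
  groups <- lapply(groups, function(g) as.integer(sort(unique(g))))
  top <- structure(atoms, groups = groups,
                   class = c("md_topology", class(atoms)))
  if (validate) {
    v <- validate_topology(top)
    if (nrow(v) > 0) {
      abort(paste0("invalid topology:\n",
                   paste(paste0("- ", v$rule, ": ", v$detail), collapse = "\n")))
    }
  }
  top
}

#' @export
print.md_topology <- function(x, ...) {
  grp <- topology_groups(x)
  cat("<md_topology> ", nrow(x), " atoms, ",
      length(unique(residue_id(x))), " residues\n", sep = "")
  cat("groups: ",
      paste(sprintf("%s (%d)", names(grp), lengths(grp)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Group selections of a topology
#'
#' @param topology An `md_topology`.
#' @return Named list of integer atom-index vectors.
#' @export
topology_groups <- function(topology) {
  attr(topology, "groups")
}

# residue identity key "<chain>:<residue_index>"; author numbering preserved
residue_id <- function(topology, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(topology))
  paste0(topology$chain_id[idx], ":", topology$residue_index[idx])
}

#' Check topology invariants
#'
#' Reports (never raises) every violated invariant: non-negative
#' Lennard-Jones parameters, positive masses, presence and disjointness of
#' the `"ligand"`/`"receptor"` groups, and resolvability of every group
#' member. An empty result means the topology is valid.
#'
#' @param topology An `md_topology` (or an object with the same structure;
#'   construction-time checks are bypassed so violations can be reported).
#' @return Tibble with columns `rule` and `detail`, one row per violation.
#' @export
validate_topology <- function(topology) {
  out <- list()
  add <- function(rule, detail) {
    out[[length(out) + 1]] <<- tibble(rule = rule, detail = detail)
  }
  n <- nrow(topology)
  bad <- which(topology$lj_sigma < 0)
  for (i in bad) add("lj_sigma >= 0", paste0("atom ", i, " has lj_sigma ", topology$lj_sigma[i]))
  bad <- which(topology$lj_epsilon < 0)
  for (i in bad) add("lj_epsilon >= 0", paste0("atom ", i, " has lj_epsilon ", topology$lj_epsilon[i]))
  bad <- which(!(topology$mass > 0))
  for (i in bad) add("mass > 0", paste0("atom ", i, " has mass ", topology$mass[i]))

  grp <- topology_groups(topology)
  for (g in c("ligand", "receptor")) {
    if (is.null(grp[[g]])) add("required group", paste0("group '", g, "' is missing"))
  }
  for (g in names(grp)) {
    unresolved <- setdiff(grp[[g]], seq_len(n))
    if (length(unresolved) > 0) {
      add("unresolvable index",
          paste0("group '", g, "' references atom index ",
                 paste(unresolved, collapse = ", "), " outside 1..", n))
    }
  }
  if (!is.null(grp$ligand) && !is.null(grp$receptor)) {
    shared <- intersect(grp$ligand, grp$receptor)
    if (length(shared) > 0) {
      add("disjointness",
          paste0("ligand and receptor share atom(s) ",
                 paste(shared, collapse = ", ")))
    }
  }
  if (length(out) == 0) {
    tibble(rule = character(), detail = character())
  } else {
    bind_rows(out)
  }
}

#' Resolve a residue/atom-name selection to an atom index
#'
#' Binds a residue number plus PDB atom name (for example residue 218,
#' atom `"CA"`) to the unique matching atom, the way the geometric
#' activation markers are specified.
#'
#' @param topology An `md_topology`.
#' @param residue_index Author residue number as in the source PDB.
#' @param atom_name PDB atom name, e.g. `"CA"`.
#' @param chain Optional chain identifier for disambiguation.
#' @return The 1-based atom index (length-1 integer).
#' @export
resolve_atom <- function(topology, residue_index, atom_name, chain = NULL) {
  hit <- topology$residue_index == residue_index &
    topology$atom_name == atom_name
  if (!is.null(chain)) hit <- hit & topology$chain_id == chain
  idx <- which(hit)
  if (length(idx) == 0) {
    abort(paste0("atom not found: residue ", residue_index, ", atom '",
                 atom_name, "'", if (!is.null(chain)) paste0(", chain '", chain, "'")))
  }
  if (length(idx) > 1) {
    abort(paste0("ambiguous selection: residue ", residue_index, ", atom '",
                 atom_name, "' matches chains ",
                 paste(unique(topology$chain_id[idx]), collapse = ", "),
                 "; pass `chain` to disambiguate"))
  }
  idx
}

#' Select atoms by residue range, atom name, or group
#'
#' Convenience selector used to express things like "Calpha atoms of all
#' ECL2 residues" or "all receptor Calpha atoms".
#'
#' @param topology An `md_topology`.
#' @param residues Optional integer vector of residue numbers to keep.
#' @param atom_names Optional character vector of atom names to keep.
#' @param group Optional group name; restricts to that group's atoms.
#' @param chain Optional chain id.
#' @return Integer vector of 1-based atom indices (possibly empty).
#' @export
select_atoms <- function(topology, residues = NULL, atom_names = NULL,
                         group = NULL, chain = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(residues)) keep <- keep & topology$residue_index %in% residues
  if (!is.null(atom_names)) keep <- keep & topology$atom_name %in% atom_names
  if (!is.null(chain)) keep <- keep & topology$chain_id %in% chain
  if (!is.null(group)) {
    g <- topology_groups(topology)[[group]]
    if (is.null(g)) abort(paste0("unknown group '", group, "'"))
    keep <- keep & topology$atom_index %in% g
  }
  which(keep)
}

#' Construct a trajectory
#'
#' An ordered conformational ensemble: one coordinate matrix per frame,
#' strictly increasing time stamps, an optional orthorhombic box, and a
#' discard window excluding the initial equilibration from every analysis
#' (frames with `time < discard_before` are dropped by all stages).
#'
#' @param coords List of N x 3 numeric matrices (angstrom), equal N.
#' @param times Numeric vector of frame times in ps (default 0, 1, ...).
#' @param box Optional length-3 numeric vector of orthorhombic box edge
#'   lengths in angstrom; `NULL` means no periodic boundary.
#' @param discard_before Time in ps before which frames are excluded from
#'   analysis (default 0 = keep all).
#' @return An object of class `md_trajectory`.
#' @export
trajectory <- function(coords, times = NULL, box = NULL, discard_before = 0) {
  if (!is.list(coords) || length(coords) == 0) {
    abort("`coords` must be a non-empty list of N x 3 matrices")
  }
  ns <- vapply(coords, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    abort("ragged trajectory: frames have differing atom counts")
  }
  if (is.null(times)) times <- seq_along(coords) - 1
  if (length(times) != length(coords)) {
    abort("`times` length must equal the number of frames")
  }
  if (any(diff(times) <= 0)) abort("frame times must be strictly increasing")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!(box > 0))) {
      abort("`box` must be three positive edge lengths (orthorhombic)")
    }
  }
  if (!any(times >= discard_before)) {
    abort("zero retained frames: discard window excludes the whole trajectory")
  }
  structure(list(coords = coords, times = as.numeric(times), box = box,
                 discard_before = discard_before),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", length(x$coords), " frames x ",
      nrow(x$coords[[1]]), " atoms; t = ", x$times[1], "..",
      x$times[length(x$times)], " ps", sep = "")
  if (!is.null(x$box)) cat("; box ", paste(x$box, collapse = " x "), " A", sep = "")
  if (x$discard_before > 0) cat("; discard < ", x$discard_before, " ps", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `md_trajectory`.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Indices of frames retained after the discard window and stride
#'
#' @param traj An `md_trajectory`.
#' @param stride Keep every `stride`-th retained frame, starting from the
#'   first retained frame (default 1 = all).
#' @return Integer vector of frame indices; errors if empty.
#' @export
retained_frames <- function(traj, stride = 1) {
  if (stride < 1) abort("`stride` must be >= 1")
  idx <- which(traj$times >= traj$discard_before)
  if (length(idx) == 0) abort("zero retained frames after discard window")
  idx[seq(1, length(idx), by = as.integer(stride))]
}

#' Activation-state criteria for a class-A GPCR
#'
#' Two geometric markers define the active state: a Calpha-Calpha marker
#' distance that must fall *below* a threshold (capturing the TM5/TM7
#' rearrangement) and a three-Calpha marker angle that must rise *above* a
#' threshold (capturing the outward swing of TM6). Both comparisons are
#' strict; by default both must hold simultaneously (`combine = "and"`).
#' Residue numbers are structure-specific configuration, not constants:
#' the SSTR2 preset shipped with the package uses residues 218/306 for the
#' distance and 262/269/81 (vertex 269) for the angle, with thresholds
#' 19.0 angstrom and 45 degrees.
#'
#' @param distance_residues Length-2 integer vector: the two residues whose
#'   marker-atom distance is measured.
#' @param angle_residues Length-3 integer vector, vertex as middle element.
#' @param distance_threshold Distance threshold in angstrom; frames are
#'   active-compatible when distance < threshold.
#' @param angle_threshold Angle threshold in degrees; frames are
#'   active-compatible when angle > threshold.
#' @param atom_name Marker atom name (default `"CA"`).
#' @param combine `"and"` (default) or `"or"`: how the two marker verdicts
#'   combine into the frame verdict.
#' @param chain Optional chain id for marker resolution.
#' @return An object of class `activation_criteria`.
#' @seealso [read_criteria()], [classify_frames()]
#' @export
activation_criteria <- function(distance_residues, angle_residues,
                                distance_threshold = 19.0,
                                angle_threshold = 45.0,
                                atom_name = "CA",
                                combine = c("and", "or"),
                                chain = NULL) {
  combine <- arg_match(combine)
  if (length(distance_residues) != 2) abort("`distance_residues` must have length 2")
  if (length(angle_residues) != 3) abort("`angle_residues` must have length 3 (vertex in the middle)")
  if (!(distance_threshold > 0) || !(angle_threshold > 0)) {
    abort("thresholds must be positive")
  }
  structure(list(distance_residues = as.integer(distance_residues),
                 angle_residues = as.integer(angle_residues),
                 distance_threshold = distance_threshold,
                 angle_threshold = angle_threshold,
                 atom_name = atom_name, combine = combine, chain = chain),
            class = "activation_criteria")
}

#' @export
print.activation_criteria <- function(x, ...) {
  cat("<activation_criteria>\n")
  cat("  distance: ", x$atom_name, " of residues ",
      paste(x$distance_residues, collapse = "-"),
      " (active < ", x$distance_threshold, " A)\n", sep = "")
  cat("  angle:    ", x$atom_name, " of residues ",
      paste(x$angle_residues, collapse = "-"),
      " (active > ", x$angle_threshold, " deg, vertex ",
      x$angle_residues[2], ")\n", sep = "")
  cat("  combine:  ", x$combine, "\n", sep = "")
  invisible(x)
}

# resolve the five marker atoms once; errors propagate from resolve_atom
resolve_criteria <- function(topology, criteria) {
  list(
    d = vapply(criteria$distance_residues, function(r)
      resolve_atom(topology, r, criteria$atom_name, criteria$chain), integer(1)),
    a = vapply(criteria$angle_residues, function(r)
      resolve_atom(topology, r, criteria$atom_name, criteria$chain), integer(1))
  )
}
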