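# Topology sidecar JSON, schema version 1:
# {
#   "schema_version": 1,
#   "atoms": [ {"atom_name": "CA", "element": "C", "residue_index": 1,
#               "residue_name": "ALA", "chain_id": "A", "charge": -0.1,
#               "lj_sigma": 0.34, "lj_epsilon": 0.36, "mass": 12.011}, ... ],
#   "groups": {"ligand": [1, 2], "receptor": [3, 4]}
# }
# Group members are 1-based atom serials in file order. lj_sigma in nm,
# lj_epsilon in kJ/mol, charge in e, mass in amu.

TOPOLOGY_SCHEMA_VERSION <- 1L

#' Read a topology sidecar JSON
#'
#' Loads and validates the per-atom charge/Lennard-Jones/mass table and
#' group selections that accompany a coordinate trajectory. See the schema
#' sketch in the package source; [write_topology()] emits it.
#'
#' @param path Path to the JSON sidecar.
#' @return A validated `md_topology`.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != TOPOLOGY_SCHEMA_VERSION) {
    abort(paste0("topology schema mismatch: expected version ",
                 TOPOLOGY_SCHEMA_VERSION, ", got ",
                 obj$schema_version %||% "none"))
  }
  if (is.null(obj$atoms) || is.null(obj$groups)) {
    abort("topology sidecar must contain `atoms` and `groups`")
  }
  groups <- lapply(obj$groups, as.integer)
  for (g in c("ligand", "receptor")) {
    if (is.null(groups[[g]])) abort(paste0("topology sidecar lacks group '", g, "'"))
  }
  topology(as_tibble(obj$atoms), groups, validate = TRUE)
}

#' Write a topology sidecar JSON
#'
#' @param topology An `md_topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  obj <- list(
    schema_version = TOPOLOGY_SCHEMA_VERSION,
    atoms = as.data.frame(topology)[, c("atom_name", "element",
      "residue_index", "residue_name", "chain_id", "charge",
      "lj_sigma", "lj_epsilon", "mass")],
    groups = topology_groups(topology)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an activation-criteria preset JSON
#'
#' The package ships `sstr2_criteria.json` under `inst/extdata` with the
#' SSTR2 marker residues (distance 218-306, angle 262-269-81, thresholds
#' 19.0 angstrom / 45 degrees); use [system.file()] to locate it.
#'
#' @param path Path to the preset JSON.
#' @return An [activation_criteria()].
#' @export
read_criteria <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  activation_criteria(
    distance_residues = obj$distance$residues,
    angle_residues = obj$angle$residues,
    distance_threshold = obj$distance$threshold_angstrom,
    angle_threshold = obj$angle$threshold_degrees,
    atom_name = obj$atom_name %||% "CA",
    combine = obj$combine %||% "and",
    chain = obj$chain
  )
}

#' Write an activation-criteria preset JSON
#'
#' @param criteria An [activation_criteria()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_criteria <- function(criteria, path) {
  obj <- list(
    distance = list(residues = criteria$distance_residues,
                    threshold_angstrom = criteria$distance_threshold,
                    active_when = "below"),
    angle = list(residues = criteria$angle_residues,
                 threshold_degrees = criteria$angle_threshold,
                 active_when = "above"),
    atom_name = criteria$atom_name,
    combine = criteria$combine,
    chain = criteria$chain
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a residue class table JSON
#'
#' A flat JSON object mapping 3-letter residue codes to side-chain classes
#' (`hydrophobic`, `charged`, `polar_uncharged`, `other`).
#'
#' @param path Path to the JSON table.
#' @return Named character vector usable as `class_table`.
#' @export
read_class_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(obj)
}
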