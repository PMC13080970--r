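# Fixed-column PDB 3.3 layout for ATOM/HETATM records:
#   1-6 record, 7-11 serial, 13-16 name, 18-20 resName, 22 chainID,
#   23-26 resSeq, 31-38/39-46/47-54 x/y/z (%8.3f), 77-78 element.

#' Read a multi-model PDB trajectory
#'
#' Parses a MODEL/ENDMDL-delimited multi-model PDB (or a single implicit
#' model) into a trajectory plus an atom identity table. Parsing is strict
#' on the fixed column positions of the PDB 3.3 ATOM/HETATM layout;
#' HETATM records are accepted (chelator and ligand atoms are routinely
#' non-standard residues). A CRYST1 record sets the orthorhombic box when
#' all three angles are 90 degrees; otherwise the box is left unset with a
#' warning. The element is taken from columns 77-78, falling back to an
#' atom-name heuristic with a warning.
#'
#' @param path Path to the PDB file.
#' @param dt Time step between models in ps (default 1); frame times are
#'   `0, dt, 2*dt, ...` unless `times` is given.
#' @param times Optional explicit frame times (ps).
#' @param discard_before Discard window passed to [trajectory()].
#' @return List with `trajectory` (an `md_trajectory`) and `atoms` (tibble
#'   of `atom_name`, `element`, `residue_index`, `residue_name`,
#'   `chain_id` in file order, consistent across models).
#' @export
read_multimodel_pdb <- function(path, dt = 1, times = NULL,
                                discard_before = 0) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  box <- NULL
  cryst <- which(rec == "CRYST1")
  if (length(cryst) > 0) {
    l <- lines[cryst[1]]
    abc <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33)))
    ang <- as.numeric(c(substr(l, 34, 40), substr(l, 41, 47), substr(l, 48, 54)))
    if (any(is.na(abc)) || any(is.na(ang))) {
      abort(paste0("unparseable CRYST1 record at line ", cryst[1]))
    }
    if (all(abs(ang - 90) < 1e-3)) {
      box <- abc
    } else {
      warn("CRYST1 cell is not orthorhombic (angles != 90); box ignored")
    }
  }

  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_starts <- which(substr(rec, 1, 5) == "MODEL")
  if (length(model_starts) == 0) {
    frame_of <- ifelse(is_atom, 1L, NA_integer_)
  } else {
    model_no <- cumsum(substr(rec, 1, 5) == "MODEL")
    ends <- substr(rec, 1, 6) == "ENDMDL"
    open <- model_no - cumsum(ends)  # 1 while inside a model block
    frame_of <- ifelse(is_atom & open >= 1, model_no, NA_integer_)
    if (any(is_atom & open < 1)) {
      abort(paste0("ATOM record outside MODEL/ENDMDL at line ",
                   which(is_atom & open < 1)[1]))
    }
  }
  keep <- which(!is.na(frame_of))
  if (length(keep) == 0) abort("no ATOM/HETATM records found")
  al <- lines[keep]
  fidx <- frame_of[keep]

  x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    abort(paste0("unparseable ATOM/HETATM coordinates at line ", keep[bad[1]]))
  }
  resseq <- suppressWarnings(as.integer(substr(al, 23, 26)))
  if (anyNA(resseq)) {
    abort(paste0("unparseable residue number at line ", keep[which(is.na(resseq))[1]]))
  }

  nmod <- max(fidx)
  counts <- tabulate(fidx, nmod)
  if (length(unique(counts)) != 1) {
    abort(paste0("ragged trajectory: models contain differing atom counts (",
                 paste(unique(counts), collapse = ", "), ")"))
  }
  natom <- counts[1]
  first <- fidx == 1
  atom_name <- trimws(substr(al[first], 13, 16))
  element <- trimws(substr(al[first], 77, 78))
  if (any(element == "")) {
    warn("element column (77-78) empty for some atoms; inferred from atom name")
    guess <- toupper(sub("^[0-9]*([A-Za-z]).*", "\\1", atom_name))
    element[element == ""] <- guess[element == ""]
  }
  atoms <- tibble(
    atom_name = atom_name,
    element = element,
    residue_index = resseq[first],
    residue_name = trimws(substr(al[first], 18, 20)),
    chain_id = substr(al[first], 22, 22)
  )
  coords <- lapply(seq_len(nmod), function(m) {
    w <- fidx == m
    cbind(x[w], y[w], z[w])
  })
  if (is.null(times)) times <- dt * (seq_len(nmod) - 1)
  list(trajectory = trajectory(coords, times = times, box = box,
                               discard_before = discard_before),
       atoms = atoms)
}

#' Write a trajectory as a multi-model PDB
#'
#' Emits a CRYST1 record when the trajectory carries a box, then one
#' MODEL/ENDMDL block per frame with fixed-column ATOM/HETATM records
#' (coordinates at %8.3f, the PDB fixed-width precision). Output is
#' byte-deterministic for identical inputs.
#'
#' @param traj An `md_trajectory`.
#' @param atoms Atom identity table (as from [read_multimodel_pdb()] or an
#'   `md_topology`).
#' @param path Output path.
#' @param hetatm_chains Chains written as HETATM records (default `"L"`,
#'   the ligand convention used by the synthetic generator).
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, atoms, path, hetatm_chains = "L") {
  n <- nrow(atoms)
  if (n != nrow(traj$coords[[1]])) {
    abort("atom table and trajectory disagree on atom count")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- character(0)
  if (!is.null(traj$box)) {
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                          traj$box[1], traj$box[2], traj$box[3], 90, 90, 90))
  }
  name4 <- ifelse(nchar(atoms$atom_name) < 4,
                  sprintf(" %-3s", atoms$atom_name),
                  substr(atoms$atom_name, 1, 4))
  record <- ifelse(atoms$chain_id %in% hetatm_chains, "HETATM", "ATOM  ")
  serial <- seq_len(n) %% 100000
  for (m in seq_along(traj$coords)) {
    xyz <- traj$coords[[m]]
    out <- c(out, sprintf("MODEL     %4d", m),
             sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     record, serial, name4, atoms$residue_name,
                     atoms$chain_id, atoms$residue_index %% 10000,
                     xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
                     toupper(substr(atoms$element, 1, 2))),
             "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, con)
  invisible(path)
}
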