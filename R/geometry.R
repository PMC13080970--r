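#' Minimum-image displacement between two positions
#'
#' Displacement `b - a` wrapped into the primary image of an orthorhombic
#' box, so each component has magnitude at most half the box edge. With no
#' box it is the plain difference. All lengths in angstrom.
#'
#' @param a,b Length-3 numeric positions (angstrom).
#' @param box Optional length-3 orthorhombic edge lengths (angstrom).
#' @return Length-3 displacement vector.
#' @export
min_image_displacement <- function(a, b, box = NULL) {
  d <- b - a
  if (!is.null(box)) d <- d - box * round(d / box)
  d
}

# vectorised minimum image on an n x 3 displacement matrix
wrap_disp <- function(d, box) {
  if (is.null(box)) return(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Distance between two atoms in a frame
#'
#' Minimum-image atom-atom distance, the primitive behind the activation
#' marker "distance between the Calpha atoms of residues 218 and 306".
#'
#' @param coords N x 3 coordinate matrix of one frame (angstrom).
#' @param i,j Atom indices (1-based).
#' @param box Optional orthorhombic box (angstrom).
#' @return Non-negative distance in angstrom; symmetric in `i`, `j`.
#' @export
atom_distance <- function(coords, i, j, box = NULL) {
  sqrt(sum(min_image_displacement(coords[i, ], coords[j, ], box)^2))
}

#' Angle defined by three atoms
#'
#' Angle at the vertex atom between the two arms, in degrees; the marker
#' behind "the angle between the Calpha atoms of residues 262, 269 and 81"
#' (vertex = middle atom). Arms use minimum-image displacements.
#'
#' @param coords N x 3 coordinate matrix (angstrom).
#' @param a,vertex,c Atom indices; the angle is measured at `vertex`.
#' @param box Optional orthorhombic box.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
atom_angle <- function(coords, a, vertex, c, box = NULL) {
  u <- min_image_displacement(coords[vertex, ], coords[a, ], box)
  v <- min_image_displacement(coords[vertex, ], coords[c, ], box)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort("degenerate geometry: zero-length arm in angle computation")
  }
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Mass-weighted center of mass of an atom set
#'
#' When a box is given, atoms of the set are first unwrapped to the
#' periodic image nearest the set's first atom, so a residue straddling a
#' boundary gets a physically meaningful center.
#'
#' @param coords N x 3 coordinate matrix (angstrom).
#' @param atom_set Integer vector of atom indices (non-empty).
#' @param topology An `md_topology` supplying masses.
#' @param box Optional orthorhombic box.
#' @return Length-3 position in angstrom.
#' @export
center_of_mass <- function(coords, atom_set, topology, box = NULL) {
  if (length(atom_set) == 0) abort("`atom_set` must be non-empty")
  x <- coords[atom_set, , drop = FALSE]
  if (!is.null(box)) {
    ref <- x[1, ]
    d <- sweep(x, 2, ref)
    x <- sweep(wrap_disp(d, box), 2, ref, FUN = "+")
  }
  m <- topology$mass[atom_set]
  colSums(x * m) / sum(m)
}

#' Kabsch superposition of two point sets
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between `mobile` and `reference`. The transform maps a
#' row-vector coordinate matrix as `x %*% rotation + translation` (applied
#' by [apply_superposition()]).
#'
#' @param mobile,reference M x 3 matrices, M >= 3 non-collinear points.
#' @param weights Optional non-negative weights of length M (e.g. masses).
#' @return List with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3), and `rmsd` (weighted RMSD after superposition, angstrom).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  if (nrow(mobile) != nrow(reference)) abort("point sets must have equal size")
  m <- nrow(mobile)
  if (m < 3) abort("need at least 3 points for superposition")
  if (is.null(weights)) weights <- rep(1, m)
  if (any(weights < 0) || sum(weights) == 0) abort("weights must be non-negative, not all zero")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)
  # guard against degenerate (collinear/coincident) references
  qs <- svd(q * sqrt(w))
  if (qs$d[2] < 1e-8 * max(qs$d[1], 1e-30)) {
    abort("degenerate reference: points are collinear or coincident")
  }
  a <- t(p * w) %*% q
  s <- svd(a)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- p %*% rot
  rmsd <- sqrt(sum(w * rowSums((aligned - q)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% rot), rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#'
#' @param coords N x 3 matrix.
#' @param fit Result of [kabsch_superpose()].
#' @return Transformed N x 3 matrix.
#' @export
apply_superposition <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2, fit$translation, FUN = "+")
}

#' Root-mean-square fluctuation after iterative alignment
#'
#' Per-atom RMSF about the trajectory mean structure,
#' \eqn{RMSF_i = \sqrt{\langle |x_i(t) - \langle x_i \rangle|^2 \rangle_t}},
#' computed after every retained frame is Kabsch-aligned on
#' `align_selection` with a two-pass scheme: align to the first retained
#' frame, form the mean structure, re-align every frame to that mean, and
#' recompute the mean. This is the loop-flexibility statistic used to
#' quantify closure of extracellular loop 2 over a bound ligand (per-residue
#' Calpha RMSF and the sum over the loop selection).
#'
#' When the trajectory carries a box, every frame is first made whole by
#' placing each atom at its minimum-image position relative to the frame's
#' first atom, so re-wrapped periodic input gives the same fluctuations as
#' unwrapped input (this assumes the analysed assembly spans less than half
#' the box, which holds for a receptor in a standard simulation cell).
#'
#' @param traj An `md_trajectory` with at least 2 retained frames.
#' @param topology An `md_topology`.
#' @param selection Atom indices whose RMSF is reported (e.g. loop Calpha
#'   atoms); see [select_atoms()].
#' @param align_selection Atom indices used for superposition; defaults to
#'   all receptor Calpha atoms, falling back to `selection`.
#' @param stride Frame stride (default 1).
#' @return Object of class `rmsf_result`; `tidy()` gives the per-residue
#'   table, `glance()` the selection sum.
#' @export
rmsf <- function(traj, topology, selection,
                 align_selection = NULL, stride = 1) {
  if (length(selection) < 1) abort("`selection` resolves to no atoms")
  if (is.null(align_selection)) {
    align_selection <- select_atoms(topology, atom_names = "CA", group = "receptor")
    if (length(align_selection) < 3) align_selection <- selection
  }
  idx <- retained_frames(traj, stride)
  if (length(idx) < 2) abort("need at least 2 retained frames for RMSF")
  frames <- traj$coords[idx]
  if (!is.null(traj$box)) {
    frames <- lapply(frames, function(x) {
      ref <- x[1, ]
      sweep(wrap_disp(sweep(x, 2, ref), traj$box), 2, ref, FUN = "+")
    })
  }
  nsel <- length(selection)

  align_to <- function(frames, ref_align) {
    lapply(frames, function(x) {
      fit <- kabsch_superpose(x[align_selection, , drop = FALSE], ref_align)
      apply_superposition(x, fit)
    })
  }
  mean_coords <- function(frames) Reduce(`+`, frames) / length(frames)

  pass1 <- align_to(frames, frames[[1]][align_selection, , drop = FALSE])
  mref <- mean_coords(pass1)
  pass2 <- align_to(frames, mref[align_selection, , drop = FALSE])
  mfinal <- mean_coords(pass2)

  dev2 <- matrix(0, nrow = nsel, ncol = length(pass2))
  msel <- mfinal[selection, , drop = FALSE]
  for (t in seq_along(pass2)) {
    d <- pass2[[t]][selection, , drop = FALSE] - msel
    dev2[, t] <- rowSums(d^2)
  }
  per_atom <- sqrt(rowMeans(dev2))

  per_residue <- tibble(
    atom_index = selection,
    chain_id = topology$chain_id[selection],
    residue_index = topology$residue_index[selection],
    residue_name = topology$residue_name[selection],
    atom_name = topology$atom_name[selection],
    rmsf = per_atom
  )
  structure(list(per_residue = per_residue,
                 selection_sum = sum(per_atom),
                 n_frames = length(idx),
                 align_selection = align_selection),
            class = "rmsf_result")
}

#' @export
print.rmsf_result <- function(x, ...) {
  cat("<rmsf_result> ", nrow(x$per_residue), " atoms over ", x$n_frames,
      " frames; selection sum = ", format(x$selection_sum, digits = 4),
      " A\n", sep = "")
  invisible(x)
}

#' @rdname rmsf
#' @param x An `rmsf_result`.
#' @param ... Unused.
#' @method tidy rmsf_result
#' @export
tidy.rmsf_result <- function(x, ...) x$per_residue

#' @rdname rmsf
#' @method glance rmsf_result
#' @export
glance.rmsf_result <- function(x, ...) {
  tibble(selection_sum = x$selection_sum,
         n_atoms = nrow(x$per_residue),
         n_frames = x$n_frames)
}
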