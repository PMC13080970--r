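#' Classify every frame as active or inactive
#'
#' Measures the two activation markers (marker Calpha-Calpha distance and
#' marker Calpha angle) in every retained frame and applies the strict
#' threshold rule: a frame is active iff distance < distance_threshold and
#' angle > angle_threshold (with `combine = "or"` either marker suffices).
#' Boundary values are inactive by construction — the comparisons are
#' strict. Measured values are returned alongside the verdict for audit.
#'
#' @param traj An `md_trajectory`.
#' @param topology An `md_topology`.
#' @param criteria An [activation_criteria()].
#' @param stride Frame stride (default 1).
#' @return Tibble with columns `frame`, `time`, `distance`, `angle`,
#'   `active` for every retained frame.
#' @export
classify_frames <- function(traj, topology, criteria, stride = 1) {
  sel <- resolve_criteria(topology, criteria)
  idx <- retained_frames(traj, stride)
  box <- traj$box
  nf <- length(idx)
  # gather marker coordinates across frames: nf x 3 per marker atom
  marker <- function(atom) {
    t(vapply(idx, function(t) traj$coords[[t]][atom, ], numeric(3)))
  }
  p1 <- marker(sel$d[1]); p2 <- marker(sel$d[2])
  dist <- sqrt(rowSums(wrap_disp(p2 - p1, box)^2))
  a1 <- marker(sel$a[1]); av <- marker(sel$a[2]); a3 <- marker(sel$a[3])
  u <- wrap_disp(a1 - av, box); v <- wrap_disp(a3 - av, box)
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  if (any(nu == 0 | nv == 0)) abort("degenerate geometry: zero-length marker arm")
  cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
  ang <- acos(cosang) * 180 / pi
  d_ok <- dist < criteria$distance_threshold
  a_ok <- ang > criteria$angle_threshold
  active <- if (criteria$combine == "and") d_ok & a_ok else d_ok | a_ok
  tibble(frame = idx, time = traj$times[idx],
         distance = dist, angle = ang, active = active)
}

#' Active fraction of a trajectory
#'
#' Fraction of retained frames classified active under the given criteria,
#' with the per-frame audit series.
#'
#' @inheritParams classify_frames
#' @return Object of class `activation_result`; `glance()` gives the
#'   fraction and counts, `tidy()` the per-frame series.
#' @export
active_fraction <- function(traj, topology, criteria, stride = 1) {
  series <- classify_frames(traj, topology, criteria, stride)
  structure(list(series = series,
                 fraction = mean(series$active),
                 n_frames = nrow(series),
                 criteria = criteria),
            class = "activation_result")
}

#' @export
print.activation_result <- function(x, ...) {
  cat("<activation_result> ", x$n_frames, " frames; active fraction ",
      sprintf("%.4f (%.1f%%)", x$fraction, 100 * x$fraction), "\n", sep = "")
  invisible(x)
}

#' @rdname active_fraction
#' @param x An `activation_result`.
#' @param ... Unused.
#' @method tidy activation_result
#' @export
tidy.activation_result <- function(x, ...) x$series

#' @rdname active_fraction
#' @method glance activation_result
#' @export
glance.activation_result <- function(x, ...) {
  tibble(fraction = x$fraction,
         n_active = sum(x$series$active),
         n_frames = x$n_frames)
}

#' Pool active fractions over replicate trajectories
#'
#' Replicate simulations are pooled frame-weighted (total active frames
#' over total frames); the unweighted mean and the range across replicates
#' are reported alongside, since either convention may be wanted when
#' replicates have unequal lengths.
#'
#' @param fractions Numeric vector of per-replicate active fractions.
#' @param frame_counts Integer vector of retained-frame counts, same length.
#' @return One-row tibble with `pooled` (frame-weighted), `mean_unweighted`,
#'   `min`, `max`, `n_replicates`, `n_frames`.
#' @export
pooled_fraction <- function(fractions, frame_counts) {
  if (length(fractions) != length(frame_counts)) {
    abort("`fractions` and `frame_counts` must have equal length")
  }
  if (any(!(frame_counts > 0))) abort("frame counts must be positive")
  tibble(
    pooled = sum(fractions * frame_counts) / sum(frame_counts),
    mean_unweighted = mean(fractions),
    min = min(fractions), max = max(fractions),
    n_replicates = length(fractions),
    n_frames = sum(frame_counts)
  )
}
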