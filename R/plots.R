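#' Plot an activation-state series
#'
#' Marker distance and angle over time, coloured by the per-frame verdict,
#' with the thresholds drawn as dashed lines.
#'
#' @param object An `activation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot activation_result
#' @export
autoplot.activation_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$series, c("distance", "angle"),
                              names_to = "marker", values_to = "value")
  thr <- tibble(marker = c("distance", "angle"),
                threshold = c(object$criteria$distance_threshold,
                              object$criteria$angle_threshold))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$active)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~marker, scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = NULL, colour = "active",
                  title = sprintf("Active fraction %.1f%%", 100 * object$fraction))
}

#' Plot a per-residue energy decomposition
#'
#' Stacked per-residue Coulomb and Lennard-Jones contributions to the
#' ligand-receptor interaction energy.
#'
#' @param object An `energy_breakdown`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot energy_breakdown
#' @export
autoplot.energy_breakdown <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_residue, c("coulomb", "lj"),
                              names_to = "term", values_to = "energy")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$residue_index),
                                     y = .data$energy, fill = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "residue", y = "energy (kJ/mol)", fill = NULL,
                  title = sprintf("Mean interaction energy %.1f kJ/mol",
                                  object$summary$total_mean)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot per-residue RMSF
#'
#' @param object An `rmsf_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rmsf_result
#' @export
autoplot.rmsf_result <- function(object, ...) {
  ggplot2::ggplot(object$per_residue,
                  ggplot2::aes(x = .data$residue_index, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue", y = "RMSF (Å)",
                  title = sprintf("Selection sum %.2f Å", object$selection_sum))
}

#' Plot contact occupancies
#'
#' Per-residue contact occupancy coloured by side-chain class, with the
#' census membership threshold as a dashed line.
#'
#' @param object A `contact_census`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_census
#' @export
autoplot.contact_census <- function(object, ...) {
  df <- object$per_residue[object$per_residue$occupancy > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$residue_index),
                                   y = .data$occupancy, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$occupancy_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "residue", y = "contact occupancy", fill = NULL,
                  title = sprintf("%d residues in census at %.1f Å",
                                  object$n_census, object$cutoff)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
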