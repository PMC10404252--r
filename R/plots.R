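# ggplot2 views of the main result types

#' Bar plot of per-odor preference indices
#'
#' @param valence_calls Output of [classify_valence()].
#' @return A ggplot object.
#' @export
plot_preference_index <- function(valence_calls) {
  df <- dplyr::mutate(
    valence_calls,
    odor_id = factor(.data$odor_id,
                     levels = .data$odor_id[order(-.data$preference_index)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$odor_id, .data$preference_index,
                                   fill = .data$valence_class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(appetitive = "#2166ac",
                                          neutral = "grey60",
                                          unappetitive = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "Preference index", fill = "Valence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
autoplot.pn_trajectories <- function(object, valence = NULL, ...) {
  wide <- tidyr::pivot_wider(object$scores,
                             names_from = "component",
                             names_prefix = "PC",
                             values_from = "value")
  if (!is.null(valence)) {
    wide$valence <- valence[wide$odor_id]
    aes <- ggplot2::aes(.data$PC1, .data$PC2, group = .data$odor_id,
                        colour = .data$valence)
  } else {
    aes <- ggplot2::aes(.data$PC1, .data$PC2, group = .data$odor_id,
                        colour = .data$odor_id)
  }
  ggplot2::ggplot(wide, aes) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::labs(
      title = sprintf("Ensemble trajectories (%.0f%% variance captured)",
                      100 * sum(object$variance_explained))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.valence_loocv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Observed POR probability", y = "Predicted",
      title = sprintf("Leave-one-odor-out predictions (R² = %.2f)",
                      object$r2)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.por_prediction <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, c("observed", "predicted"),
                              names_to = "series", values_to = "separation")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$separation,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~odor_id, nrow = 1) +
    ggplot2::labs(x = "Time from odor onset (s)", y = "Palp separation") +
    ggplot2::theme_minimal()
}

#' Decoder and POR readout traces of the Hebbian network
#'
#' @param readout Output of [simulate_por_readout()].
#' @return A ggplot object.
#' @export
plot_por_readout <- function(readout) {
  long <- tidyr::pivot_longer(readout, c("dn1", "dn2", "por"),
                              names_to = "unit", values_to = "activity")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$activity,
                                     colour = .data$unit)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~odor_id, nrow = 1) +
    ggplot2::labs(x = "Time from odor onset (s)", y = "Activity") +
    ggplot2::theme_minimal()
}
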