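#' Plot a trajectory
#'
#' Time courses of selected species.
#'
#' @param object A `trajectory`.
#' @param species Species to show (default: all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory <- function(object, species = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(species)) df <- dplyr::filter(df, .data$species %in% !!species)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "concentration (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot phase proportions with the ergodic baseline
#'
#' @param object A `phase_proportions`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phase_proportions <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(.data$time, .data$fraction,
                               colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = object$ergodic,
                        ggplot2::aes(yintercept = .data$predicted,
                                     colour = .data$phase),
                        linetype = "dashed") +
    ggplot2::labs(x = "time (h)", y = "fraction of alive cells",
                  colour = "phase") +
    ggplot2::theme_minimal()
}

#' Plot an entrainment curve
#'
#' @param data Output of [entrainment_curve()].
#' @return A ggplot of dominant frequency versus coupling strength.
#' @export
plot_entrainment <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$value, .data$frequency)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~coupling, scales = "free_x") +
    ggplot2::labs(x = "coupling strength",
                  y = "dominant frequency (1/h)") +
    ggplot2::theme_minimal()
}

#' Plot a KL001 dose-response table
#'
#' @param data Output of [kl001_dose_response()].
#' @return A ggplot with period and relative amplitude panels.
#' @export
plot_dose_response <- function(data) {
  long <- tidyr::pivot_longer(
    dplyr::select(data, "factor", "period", "amplitude_rel"),
    -"factor", names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(.data$factor, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "KL001 factor", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-run lineage correlations
#'
#' Boxplots of per-run Pearson correlations by relation, in the style used
#' for run-ensemble summaries.
#'
#' @param correlations A tibble with `run_id`, `relation`, `r` (e.g. the
#'   `correlations` table of the `cmi` experiment).
#' @return A ggplot.
#' @export
plot_correlation_ensemble <- function(correlations) {
  ggplot2::ggplot(correlations,
                  ggplot2::aes(.data$relation, .data$r)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Pearson r (IMT)") +
    ggplot2::theme_minimal()
}
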