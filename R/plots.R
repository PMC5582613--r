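#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Concentration of every species against time, on a per-species free scale.
#'
#' @param object A `meiqx_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meiqx_trajectory
#' @export
autoplot.meiqx_trajectory <- function(object, ...) {
  trajectory_long(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time_h, .data$concentration_M * 1e6)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (µM)") +
    ggplot2::theme_minimal()
}

#' Stacked bioactivation/detoxification balance across doses
#'
#' Ensemble-mean percent of the dose ending in each fate, one bar per dose.
#'
#' @param balance A `meiqx_balance_table` from [dose_sweep()].
#' @return A ggplot.
#' @export
plot_balance <- function(balance) {
  balance_stats(balance) |>
    dplyr::select("dose_uM",
                  detoxified = "percent_detoxified_mean",
                  bioactivated = "percent_bioactivated_mean",
                  residual = "percent_residual_mean") |>
    tidyr::pivot_longer(-"dose_uM", names_to = "fate", values_to = "percent") |>
    ggplot2::ggplot(ggplot2::aes(factor(.data$dose_uM), .data$percent,
                                 fill = .data$fate)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      detoxified = "#2e7d32", bioactivated = "#c62828", residual = "grey70"
    )) +
    ggplot2::labs(x = "initial MeIQx dose (µM)",
                  y = "% of dose at horizon", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Ratio-versus-dose curves of an ensemble
#'
#' One line per model, faceted by evaluation time, on a log dose axis.
#'
#' @param ratio Output of [ratio_curve()].
#' @return A ggplot.
#' @export
plot_ratio_curve <- function(ratio) {
  ggplot2::ggplot(ratio, ggplot2::aes(.data$dose_uM, .data$ratio,
                                      group = .data$model_id)) +
    ggplot2::geom_line(alpha = 0.3, color = "steelblue") +
    ggplot2::stat_summary(ggplot2::aes(group = NULL), fun = median,
                          geom = "line", color = "black", linewidth = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~time_h, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "initial MeIQx dose (µM)",
                  y = "bioactivation / detoxification") +
    ggplot2::theme_minimal()
}

#' Distribution-coefficient curves of an ensemble
#'
#' @param curves Output of [coefficient_curves()].
#' @return A ggplot with one panel per coefficient.
#' @export
plot_coefficient_curves <- function(curves) {
  curves |>
    tidyr::pivot_longer(c("alpha", "beta"), names_to = "coefficient",
                        values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(.data$meiqx_uM, .data$value,
                                 group = .data$model_id)) +
    ggplot2::geom_line(alpha = 0.3, color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~coefficient, scales = "free_y") +
    ggplot2::labs(x = "MeIQx concentration (µM)",
                  y = "enzyme fraction") +
    ggplot2::theme_minimal()
}
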