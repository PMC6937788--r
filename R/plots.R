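#' Plot regional through-plane flow curves
#'
#' One line per region, positive flow apex to base (ejection up,
#' filling down).
#'
#' @param object A `flow_curves` object from [throughplane_flow()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flow_curves
#' @export
autoplot.flow_curves <- function(object, ...) {
  reg <- object$regions |>
    dplyr::filter(.data$region != "outside")
  ggplot2::ggplot(reg, ggplot2::aes(x = .data$time_s, y = .data$flow_lpm,
                                    colour = .data$region)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "through-plane flow (L/min)",
                  colour = "region",
                  title = "Regional through-plane flow",
                  subtitle = "positive = apex to base") +
    ggplot2::theme_minimal()
}

#' Plot compartment fractions
#'
#' Bar chart of the four flow-compartment percentages.
#'
#' @param object A `compartment_analysis` from [track_compartments()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot compartment_analysis
#' @export
autoplot.compartment_analysis <- function(object, ...) {
  f <- object$fractions
  d <- tibble::tibble(
    compartment = factor(c("direct", "retained", "delayed", "residual"),
                         levels = c("direct", "retained", "delayed",
                                    "residual")),
    pct = c(f$direct_pct, f$retained_pct, f$delayed_pct, f$residual_pct))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$compartment, y = .data$pct,
                                  fill = .data$compartment)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "% of end-diastolic blood volume",
                  title = "LV flow compartments",
                  subtitle = sprintf("%.1f%% of pathlines excluded (wall crossing)",
                                     f$excluded_pct)) +
    ggplot2::theme_minimal()
}

#' Plot the cavity volume curve
#'
#' @param object A `ventricular_function` from [cavity_volumes()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ventricular_function
#' @export
autoplot.ventricular_function <- function(object, ...) {
  ggplot2::ggplot(object$volume,
                  ggplot2::aes(x = .data$frame, y = .data$volume_ml)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$volume[c(object$ed_frame,
                                               object$es_frame), ],
                        colour = "red") +
    ggplot2::labs(x = "cardiac frame", y = "cavity volume (mL)",
                  title = sprintf("EDV %.1f mL, ESV %.1f mL, EF %.1f%%",
                                  object$edv_ml, object$esv_ml,
                                  object$ef_pct)) +
    ggplot2::theme_minimal()
}

#' Plot adjusted group effects with confidence intervals
#'
#' @param object Tibble from [group_effects()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_group_effects <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$delta_mi,
                               y = stats::reorder(.data$parameter,
                                                  .data$delta_mi))) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "adjusted AMI - control difference (95% CI)",
                  y = NULL, title = "Covariate-adjusted group effects") +
    ggplot2::theme_minimal()
}
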