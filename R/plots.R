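#' Plot a multistart fit
#'
#' `type = "landscape"` shows the final objective value reached from every
#' start point (log scale); horizontal bands correspond to families of local
#' minima. `type = "parity"` shows modeled vs measured solubility on
#' log-log axes, with flagged (excluded) records marked.
#'
#' @param object A [nrtlsac_fit()] result.
#' @param type `"landscape"` or `"parity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nrtlsac_fit <- function(object, type = c("landscape", "parity"), ...) {
  type <- match.arg(type)
  if (type == "landscape") {
    df <- export_landscape(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$sse)) +
      ggplot2::geom_point(alpha = 0.5, size = 0.8) +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "start point", y = "final SSE [(mol/mol)^2]",
                    title = "Multistart objective landscape") +
      ggplot2::theme_minimal()
  } else {
    df <- augment(object)
    df$flagged <- dataset_exclude_flags(df)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x_exp, y = .data$x_sat,
                                     colour = .data$solvent,
                                     shape = .data$flagged)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
      ggplot2::geom_point(size = 2) +
      ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "measured x_sat", y = "modeled x_sat",
                    shape = "excluded", title = "Parity plot") +
      ggplot2::theme_minimal()
  }
}

#' Plot solubility curves
#'
#' Model saturation mole fraction against temperature, one curve per
#' solvent, with measured points overlaid when a dataset is supplied.
#'
#' @param predictions Output of [predict_solubility()].
#' @param data Optional measured dataset (`solvent`, `t_k`, `x_exp`).
#' @return A ggplot object.
#' @export
plot_solubility_curves <- function(predictions, data = NULL) {
  p <- ggplot2::ggplot(predictions,
                       ggplot2::aes(x = .data$t_k, y = .data$x_sat,
                                    colour = .data$solvent)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "temperature [K]", y = "x_sat [mol/mol]",
                  colour = "solvent") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data,
      ggplot2::aes(x = .data$t_k, y = .data$x_exp, colour = .data$solvent),
      shape = 4, size = 2.5, inherit.aes = FALSE
    )
  }
  p
}
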