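#' @export
autoplot.transducer_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("force_mN", "commanded_length_mm"),
    names_to = "channel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Transducer record: force and commanded length")
}

#' Plot tension-versus-strain cycle curves
#'
#' @param curves Tibble from [build_cycle_curves()].
#' @param direction Directions to include.
#' @return A ggplot.
#' @export
plot_cycle_curves <- function(curves, direction = c("lengthen", "shorten")) {
  df <- dplyr::filter(curves, .data$direction %in% !!direction)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$strain, y = .data$tension,
    colour = factor(.data$cycle), linetype = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(strain ~ (L / L[0])),
                  y = expression(tension ~ (mN / mm^2)),
                  colour = "cycle", linetype = "direction")
}

#' @export
autoplot.cycle_decomposition <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$muscle_basal, component = "basal"),
    if (!is.null(object$muscle_induced)) {
      dplyr::mutate(object$muscle_induced, component = "induced")
    }
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strain, y = .data$tension,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(
      data = object$peaks,
      ggplot2::aes(xintercept = .data$peak_strain,
                   colour = .data$component),
      linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = expression(strain ~ (L / L[0])),
                  y = expression(muscle ~ tension ~ (mN / mm^2)),
                  title = "Smooth-muscle contribution by cycle subtraction")
}

#' Plot a compliance curve
#'
#' Undefined (zero-stiffness) regions are omitted from the line.
#'
#' @param compliance Tibble from [compliance_curve()].
#' @return A ggplot.
#' @export
plot_compliance <- function(compliance) {
  ggplot2::ggplot(dplyr::filter(compliance, .data$defined),
                  ggplot2::aes(x = .data$strain, y = .data$compliance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(strain ~ (L / L[0])),
                  y = "compliance (1 / stiffness)")
}

#' Volcano plot
#'
#' @param volcano Tibble from [volcano_table()].
#' @return A ggplot.
#' @export
plot_volcano <- function(volcano) {
  ggplot2::ggplot(volcano, ggplot2::aes(
    x = .data$log2_fold_change, y = .data$neg_log10_p_adjusted,
    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red3")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p")
}

#' @export
autoplot.panel_pca <- function(object, ...) {
  aes <- ggplot2::aes(x = .data$PC1, y = .data$PC2)
  if ("arm" %in% names(object$scores)) {
    aes <- ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$arm)
  }
  ggplot2::ggplot(object$scores, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$var_fraction[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$var_fraction[2]))
}
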