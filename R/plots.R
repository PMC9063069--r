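# ggplot2 views of the main result types.

#' Plot a standard curve
#'
#' Cq against log10(input quantity) with the fitted line.
#'
#' @param object A `standard_curve`.
#' @param standards Optional table of the wells used for the fit
#'   (`quantity_ng`, `cq`) to overlay as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.standard_curve <- function(object, standards = NULL, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10 input quantity (ng)", y = "Cq",
      title = sprintf("Standard curve%s: E = %.1f%%, r2 = %.3f",
                      if (is.na(object$target)) "" else paste0(" (", object$target, ")"),
                      object$efficiency, object$r_squared)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(standards)) {
    p <- p + ggplot2::geom_point(
      data = standards,
      ggplot2::aes(x = log10(.data$quantity_ng), y = .data$cq)
    )
  }
  p
}

#' Plot within-person LTL trajectories on the pseudo-GA scale
#'
#' @param ltl Per-sample LTL table with `subject_id`, `pseudo_ga` and the
#'   column named by `value`.
#' @param value LTL column (default `"reported_ts"`).
#' @return A ggplot object: one line per subject, loess trend overlaid.
#' @export
plot_trajectories <- function(ltl, value = "reported_ts") {
  ggplot2::ggplot(ltl, ggplot2::aes(x = .data$pseudo_ga, y = .data[[value]])) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.3, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "Pseudo-gestational age (weeks)", y = "T/S ratio") +
    ggplot2::theme_minimal()
}

#' Plot a stress-feature correlation network
#'
#' Nodes at their t-SNE coordinates, sized by -log10(p) of the LTL
#' association, coloured orange/blue for positive/negative associations at
#' p < 0.1, labels bold at p < 0.05; edges drawn thin for |r| >= 0.3 and
#' thick for |r| >= 0.7.
#'
#' @param object An `ltl_network`.
#' @param label Draw feature labels (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ltl_network <- function(object, label = TRUE, ...) {
  nodes <- object$nodes
  edges <- object$edges %>%
    left_join(select(nodes, "feature", xf = "x", yf = "y"),
              by = c(from = "feature")) %>%
    left_join(select(nodes, "feature", xt = "x", yt = "y"),
              by = c(to = "feature"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xf, y = .data$yf, xend = .data$xt, yend = .data$yt,
                   linewidth = .data$class),
      colour = "grey70", alpha = 0.6
    ) +
    ggplot2::scale_linewidth_manual(values = c(thin = 0.3, thick = 1.4)) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size,
                   colour = .data$color)
    ) +
    ggplot2::scale_colour_manual(
      values = c(none = "grey55", orange = "darkorange", blue = "steelblue")
    ) +
    ggplot2::labs(x = NULL, y = NULL, size = "-log10(p)", colour = "association") +
    ggplot2::theme_void()
  if (label) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$feature,
                   fontface = ifelse(.data$bold, "bold", "plain")),
      size = 2.4, vjust = -1
    )
  }
  p
}
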