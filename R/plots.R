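# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_rect
#'   geom_vline scale_x_log10 labs theme_minimal facet_wrap
#'   scale_color_gradient2 coord_fixed
#' @export
ggplot2::autoplot

#' Butterfly plot of a TRF model
#'
#' One line per channel over lag, with optional shaded component windows.
#'
#' @param object a `trf`.
#' @param windows optional windows tibble (as [component_windows()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.trf <- function(object, windows = NULL, ...) {
  td <- tidy(object)
  p <- ggplot(td, aes(x = .data$lag_ms, y = .data$weight,
                      group = .data$channel)) +
    geom_line(alpha = 0.4, linewidth = 0.3) +
    geom_vline(xintercept = 0, linetype = "dotted") +
    labs(x = "lag (ms)", y = "TRF weight (norm. units)",
         title = paste0("TRF", if (!is.null(object$condition))
           paste0(" - ", object$condition) else "")) +
    theme_minimal()
  if (!is.null(windows)) {
    p <- p + geom_rect(data = windows,
                       aes(xmin = .data$t_start, xmax = .data$t_end),
                       ymin = -Inf, ymax = Inf, alpha = 0.15,
                       fill = "steelblue", inherit.aes = FALSE)
  }
  p
}

#' Cross-validation curve of a lambda search
#'
#' @param object a `lambda_search`.
#' @param ... unused.
#' @return a ggplot of cv MSE against lambda (log scale) with the
#'   selected lambda marked.
#' @export
autoplot.lambda_search <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$lambda, y = .data$cv_mse)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = object$best_lambda, linetype = "dashed",
               color = "firebrick") +
    scale_x_log10() +
    labs(x = expression(lambda), y = "cross-validated MSE",
         title = sprintf("selected lambda = %g", object$best_lambda)) +
    theme_minimal()
}

#' GFP time courses by condition
#'
#' @param gfp_tbl stacked output of [gfp()] for several models/conditions.
#' @param clusters optional cluster tibble from [condition_gfp_test()] to
#'   shade.
#' @return a ggplot.
#' @export
plot_gfp <- function(gfp_tbl, clusters = NULL) {
  p <- ggplot(gfp_tbl, aes(x = .data$lag_ms, y = .data$gfp,
                           color = .data$condition,
                           group = interaction(.data$subject,
                                               .data$condition))) +
    geom_line(alpha = 0.5) +
    labs(x = "lag (ms)", y = "GFP (norm. units)") +
    theme_minimal()
  if (!is.null(clusters) && nrow(clusters) > 0) {
    p <- p + geom_rect(data = clusters,
                       aes(xmin = .data$t_start, xmax = .data$t_end),
                       ymin = -Inf, ymax = Inf, alpha = 0.15,
                       fill = "grey40", inherit.aes = FALSE)
  }
  p
}

#' Topographic dominance map
#'
#' Channels plotted at idealized scalp positions, colored by the paired-t
#' value; significant channels drawn larger.
#'
#' @param topo tibble from [topographic_dominance()].
#' @return a ggplot.
#' @export
plot_topomap <- function(topo) {
  pos <- montage_positions(topo$channel)
  d <- dplyr::left_join(topo, pos, by = "channel")
  ggplot(d, aes(x = .data$x, y = .data$y, color = .data$t,
                size = .data$sig)) +
    geom_point() +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 4)) +
    scale_color_gradient2(low = "blue", mid = "white", high = "red",
                          limits = c(-10, 10), oob = scales_squish) +
    coord_fixed() +
    labs(x = NULL, y = NULL, color = "t") +
    theme_minimal()
}

# minimal squish (avoids a scales dependency)
scales_squish <- function(x, range = c(-10, 10)) {
  pmin(pmax(x, range[1]), range[2])
}
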