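#' Plot a conditional-independence skeleton
#'
#' Nodes on a circle, edges as straight segments; node colour distinguishes
#' ceramides from dihydroceramides when the labels follow the `Cer`/`dhCer`
#' convention.
#'
#' @param object A [pc_skeleton()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot lipid_skeleton
#' @export
autoplot.lipid_skeleton <- function(object, ...) {
  nodes <- object$nodes
  k <- length(nodes)
  theta <- 2 * pi * (seq_len(k) - 1) / k
  layout <- tibble(node = nodes, x = cos(theta), y = sin(theta),
                   class = ifelse(grepl("^dhCer", nodes), "dhCer", "Cer"))
  edges <- object$edges |>
    dplyr::left_join(dplyr::rename(layout, from = "node",
                                   x0 = "x", y0 = "y")[, c("from", "x0", "y0")],
                     by = "from") |>
    dplyr::left_join(dplyr::rename(layout, to = "node",
                                   x1 = "x", y1 = "y")[, c("to", "x1", "y1")],
                     by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "grey55") +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(.data$x, .data$y, colour = .data$class),
                        size = 3) +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(.data$x * 1.15, .data$y * 1.15,
                                    label = .data$node), size = 3) +
    ggplot2::coord_equal(xlim = c(-1.35, 1.35), ylim = c(-1.35, 1.35)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL,
                  title = paste0("Conditional-independence skeleton (alpha = ",
                                 object$alpha, ")"))
}

#' Forest plot of the mutually adjusted joint model
#'
#' Hazard ratios (per 1 SD, log-scaled axis) with 95% CIs for the selected
#' direct effectors.
#'
#' @param object A [netcoupler()] result with a non-empty selection.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot netcoupler_result
#' @export
autoplot.netcoupler_result <- function(object, ...) {
  if (is.null(object$joint)) {
    abort("no metabolites selected; nothing to plot")
  }
  d <- dplyr::filter(object$joint$estimates, .data$exposure)
  ggplot2::ggplot(d, ggplot2::aes(.data$hr, stats::reorder(.data$term, .data$hr))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.15) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$log_hr > 0), size = 2,
                        show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio per 1 SD (95% CI)", y = NULL,
                  title = "Mutually adjusted direct effectors") +
    ggplot2::theme_minimal()
}

#' Heatmaps of pairwise and full partial correlations
#'
#' @param object A [panel_correlations()] result.
#' @param ... Ignored.
#' @return A ggplot object with one facet per correlation type.
#' @method autoplot lipid_cor
#' @export
autoplot.lipid_cor <- function(object, ...) {
  to_long <- function(m, label) {
    as_tibble(as.data.frame(m), rownames = "row") |>
      tidyr::pivot_longer(-"row", names_to = "col", values_to = "r") |>
      dplyr::mutate(type = label)
  }
  d <- dplyr::bind_rows(to_long(object$pearson, "pairwise"),
                        to_long(object$partial, "partial"))
  d$row <- factor(d$row, levels = rownames(object$pearson))
  d$col <- factor(d$col, levels = rownames(object$pearson))
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~type) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Forest plot of a single-metabolite screening table
#'
#' @param screen Output of [single_lipid_screen()].
#' @return A ggplot object faceted by model family.
#' @export
plot_screen <- function(screen) {
  ggplot2::ggplot(screen,
                  ggplot2::aes(.data$hr, .data$metabolite,
                               colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "Hazard ratio per 1 SD (95% CI)", y = NULL,
                  colour = "FDR < 0.05") +
    ggplot2::theme_minimal()
}
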