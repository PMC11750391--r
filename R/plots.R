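#' Plot a biosynthesis pathway graph
#'
#' Layered left-to-right layout (Sugiyama), precursors boxed on the left,
#' edges labelled with the catalysing enzyme.
#'
#' @param object an `fa_pathway` from [build_pathway()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.fa_pathway <- function(object, ...) {
  lay <- igraph::layout_with_sugiyama(object$graph)$layout
  nodes <- object$nodes |>
    mutate(x = lay[, 2], y = lay[, 1])
  edges <- object$edges |>
    left_join(select(nodes, "id", x0 = "x", y0 = "y"),
              by = c(substrate = "id")) |>
    left_join(select(nodes, "id", x1 = "x", y1 = "y"),
              by = c(product = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey50") +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$shorthand,
                   fill = .data$class),
      size = 3) +
    ggplot2::scale_fill_brewer(palette = "Pastel1") +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "unsaturation")
}

#' Plot a DMOX spectrum or predicted fragment series
#'
#' Stick spectrum; for a predicted series the fragment carbon counts are
#' annotated and 12-a.m.u. gaps (double-bond evidence) are highlighted.
#'
#' @param object a `dmox_series` from [predict_dmox()], or a spectrum tibble
#'   with `mz` and `intensity`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.dmox_series <- function(object, ...) {
  d <- as_tibble(object)
  d$gap12 <- c(FALSE, diff(d$mz) == 12L)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mz)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, y = 0, yend = 1,
                                       colour = .data$gap12)) +
    ggplot2::geom_text(ggplot2::aes(y = 1.05, label = .data$n_carbons),
                       size = 2.5) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
      labels = c("+14 step", "+12 step (C=C)")) +
    ggplot2::labs(x = "m/z", y = NULL, colour = NULL,
                  title = attr(object, "fa")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @rdname autoplot.dmox_series
#' @param spectrum a tibble with columns `mz`, `intensity`.
#' @return a ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                         y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::labs(x = "m/z", y = "relative intensity") +
    ggplot2::theme_minimal()
}

#' Heatmap of enzyme conversion percentages
#'
#' Tile view of the activity panels: enzymes against substrate-to-product
#' reactions, filled by conversion percent; not-detected cells are blank and
#' qualitative cells are marked "q".
#'
#' @param panels an activity-panel tibble from [load_activity_panels()].
#' @return a ggplot object.
#' @export
plot_conversions <- function(panels = load_activity_panels()) {
  d <- panels |>
    mutate(reaction = paste(.data$substrate, "→", .data$product))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$enzyme, y = .data$reaction)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$conversion),
                       colour = "white") +
    ggplot2::geom_text(
      data = dplyr::filter(d, .data$status == "qualitative"),
      label = "q", size = 3) +
    ggplot2::scale_fill_viridis_c(na.value = "grey92") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$kind), scales = "free",
                        space = "free") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "conversion (%)")
}
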