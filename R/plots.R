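#' Bubble plot of the expression screen
#'
#' Regulation (log2 fold change) against significance (-log10 P) with the
#' bubble size showing heart specificity — nominated candidates sit top
#' left/right with large bubbles.
#'
#' @param candidates Output of [nominate_candidates()] (or
#'   `tidy(<cardio_screen>)`).
#' @param p_max Significance line drawn on the plot.
#' @return A ggplot object.
#' @export
plot_candidate_bubble <- function(candidates, p_max = 0.05) {
  d <- candidates[!is.na(candidates$p_value), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(
    x = log2_fold_change, y = -log10(p_value),
    size = hss, colour = verdict
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed") +
    ggplot2::scale_size_area(name = "HSS") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#D55E00", `FALSE` = "grey50"),
      name = "candidate"
    ) +
    ggplot2::labs(
      x = "log2 fold change (disease / control)",
      y = expression(-log[10] ~ italic(P))
    ) +
    ggplot2::theme_minimal()
}

#' Delta-PSI profile along a gene
#'
#' @param dpsi Output of [delta_psi_test()], typically filtered to one
#'   gene.
#' @param p_max Parts below this P value are highlighted.
#' @return A ggplot object.
#' @export
plot_delta_psi <- function(dpsi, p_max = 0.05) {
  d <- dpsi[!dpsi$skipped, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(
    x = part_index, y = delta_psi,
    fill = !is.na(p_value) & p_value < p_max
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(gene_id), scales = "free_x") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#D55E00", `FALSE` = "grey60"),
      name = paste0("P < ", p_max)
    ) +
    ggplot2::labs(x = "exonic part", y = expression(Delta * PSI)) +
    ggplot2::theme_minimal()
}

#' Along-gene correlation profiles of one or two factors
#'
#' @param ... One or more outputs of [exon_factor_correlation()]; names
#'   become the legend labels.
#' @return A ggplot object.
#' @export
plot_correlation_profile <- function(...) {
  profiles <- list(...)
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    names(profiles) <- paste0("factor_", seq_along(profiles))
  }
  d <- purrr::imap(profiles, function(p, nm) {
    dplyr::mutate(p, factor_label = nm)
  }) |> purrr::list_rbind()
  ggplot2::ggplot(
    d[!is.na(d$r), ],
    ggplot2::aes(x = part_index, y = r, colour = .data$factor_label)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_brewer(palette = "Dark2", name = NULL) +
    ggplot2::labs(x = "exonic part", y = "correlation coefficient") +
    ggplot2::theme_minimal()
}

#' @rdname plot_candidate_bubble
#' @param object A `cardio_screen` object.
#' @param ... Passed on.
#' @export
autoplot.cardio_screen <- function(object, ...) {
  plot_candidate_bubble(object$candidates, p_max = object$params$p_max)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
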