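# ggplot2 visualisations for the main result types.

#' @exportS3Method
autoplot.mutational_landscape <- function(object, ...) {
  tb <- tidy(object)
  wt <- tb[tb$mut_aa == tb$wt_aa, , drop = FALSE]
  ggplot2::ggplot(tb, ggplot2::aes(
    x = .data$position, y = .data$mut_aa, fill = .data$delta_e
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = wt, shape = 4, size = 2) +
    ggplot2::scale_fill_gradient2(
      low = "#b2182b", mid = "white", high = "#2166ac", midpoint = 0
    ) +
    ggplot2::scale_x_continuous(breaks = seq_len(max(tb$position))) +
    ggplot2::labs(
      x = "motif position", y = "substituted residue",
      fill = expression(Delta * E),
      title = sprintf("Mutational landscape of %s", object$wt)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.gene_embedding <- function(object, labels = NULL, t = "auto", ...) {
  coords <- project_2d(object, t = t)
  if (!is.null(labels)) {
    coords$label <- labels[coords$gene_id]
    p <- ggplot2::ggplot(coords, ggplot2::aes(
      .data$x, .data$y, colour = .data$label
    ))
  } else {
    p <- ggplot2::ggplot(coords, ggplot2::aes(.data$x, .data$y))
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "diffusion 1", y = "diffusion 2") +
    ggplot2::theme_minimal()
}

#' Bottom-right candidate plot of mutational indices
#'
#' WT-pool index against mutant-pool index; the shaded corner marks the
#' candidate region (`mi_mut >= tau_hi`, `mi_wt <= tau_lo`); off-targets are
#' drawn small.
#'
#' @param mis tibble from [mutational_index()].
#' @param tau_hi,tau_lo calling thresholds to display.
#' @return a ggplot.
#' @export
plot_mutational_index <- function(mis, tau_hi = 0.8, tau_lo = 0.2) {
  tb <- mis[!is.na(mis$mi_mut), , drop = FALSE]
  ggplot2::ggplot(tb, ggplot2::aes(
    x = .data$mi_mut, y = .data$mi_wt, size = !.data$is_offtarget
  )) +
    ggplot2::annotate("rect",
      xmin = tau_hi, xmax = 1, ymin = 0, ymax = tau_lo,
      alpha = 0.15, fill = "red"
    ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_manual(
      values = c(`TRUE` = 2.5, `FALSE` = 0.8), guide = "none"
    ) +
    ggplot2::labs(x = "MI (mutant-like pool)", y = "MI (WT-like pool)") +
    ggplot2::theme_minimal()
}

#' Heatmap of an APC-corrected coupling map
#'
#' @param cm matrix from [coupling_map()].
#' @return a ggplot.
#' @export
plot_coupling_map <- function(cm) {
  tb <- tibble(
    i = rep(seq_len(nrow(cm)), ncol(cm)),
    j = rep(seq_len(ncol(cm)), each = nrow(cm)),
    coupling = as.vector(cm)
  )
  ggplot2::ggplot(tb, ggplot2::aes(.data$i, .data$j, fill = .data$coupling)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "white", high = "#b2182b", midpoint = 0
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position", y = "position", fill = "APC score") +
    ggplot2::theme_minimal()
}
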