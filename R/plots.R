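# ggplot2 diagnostics.

#' SSF heatmap
#'
#' Unitig-by-library heatmap of strand state frequencies; matched-state
#' cells show near +/-1, unmatched-state cells near 0, so chromosomes
#' appear as shared column patterns.
#'
#' @param ssf tibble from [strand_state_frequency()].
#' @return a ggplot object.
#' @export
plot_ssf_heatmap <- function(ssf) {
  check_columns(ssf, c("unitig", "library", "ssf"), "ssf table")
  ggplot2::ggplot(ssf, ggplot2::aes(
    x = .data$library, y = .data$unitig, fill = .data$ssf
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#b2182b", mid = "grey95", high = "#2166ac", limits = c(-1, 1)
    ) +
    ggplot2::labs(x = "Strand-seq library", y = "Unitig", fill = "SSF") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}

#' Cluster size plot
#'
#' @param object a `strand_clusters` object.
#' @param ... unused.
#' @return a ggplot bar chart of cluster sizes.
#' @method autoplot strand_clusters
#' @export
autoplot.strand_clusters <- function(object, ...) {
  a <- object$assignment
  a$cluster <- dplyr::coalesce(a$cluster, "unclustered")
  ggplot2::ggplot(a, ggplot2::aes(x = .data$cluster)) +
    ggplot2::geom_bar(fill = "#2166ac") +
    ggplot2::labs(x = "Cluster", y = "Unitigs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)
    )
}

#' Chromosome-plane plot
#'
#' Unitig hap-informative SSF vectors of each cluster projected onto
#' the inferred chromosome plane. Diploid clusters show three directions
#' (the two haplotypes and, between them, homozygous unitigs); a merged
#' haploid cluster shows one direction per chromosome.
#'
#' @param object a `phase_fit` object.
#' @param ... unused.
#' @return a ggplot object, faceted by cluster.
#' @method autoplot phase_fit
#' @export
autoplot.phase_fit <- function(object, ...) {
  coords <- dplyr::bind_rows(lapply(object$models, function(m) {
    dplyr::mutate(m$coords, cluster = m$cluster)
  }))
  ggplot2::ggplot(coords, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(alpha = 0.7, colour = "#2166ac") +
    ggplot2::facet_wrap(~cluster, scales = "free") +
    ggplot2::labs(x = "Plane component 1", y = "Plane component 2") +
    ggplot2::theme_minimal()
}

#' Marker-count blob plot
#'
#' Haplotype-1 versus haplotype-2 marker counts per unitig.
#' Well-phased haplotype-specific unitigs hug the axes; homozygous
#' unitigs sit near the diagonal with large totals.
#'
#' @param markers tibble from [pool_markers()] (a `call` column from
#'   [call_haplotypes()] is used for colour when present).
#' @return a ggplot object.
#' @export
plot_marker_counts <- function(markers) {
  check_columns(markers, c("unitig", "hap1", "hap2"), "marker counts")
  p <- ggplot2::ggplot(markers, ggplot2::aes(
    x = .data$hap1, y = .data$hap2
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70")
  if ("call" %in% names(markers)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$call),
                                 alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7, colour = "#2166ac")
  }
  p +
    ggplot2::labs(x = "Haplotype 1 markers", y = "Haplotype 2 markers") +
    ggplot2::theme_minimal()
}
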