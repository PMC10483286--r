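# ggplot2 views of the comparison products. These draw the same aggregates
# the chart-data file serializes; the numbers always come from the tract
# table via genome_stats()/motif_matrix().

#' Plot motif-class counts per genome
#'
#' Stacked per-genome counts of mono- to hexanucleotide tracts, optionally
#' split into perfect and imperfect panels.
#'
#' @param stats Tibble of [genome_stats()] rows.
#' @param split Facet into perfect/imperfect panels.
#' @return A ggplot object.
#' @export
plot_class_distribution <- function(stats, split = FALSE) {
  cols <- if (split) {
    c(paste0("perfect_", CLASS_LABELS), paste0("imperfect_", CLASS_LABELS))
  } else {
    CLASS_LABELS
  }
  long <- stats %>%
    select("genome", all_of(cols)) %>%
    tidyr::pivot_longer(-"genome", names_to = "class", values_to = "count")
  if (split) {
    long <- long %>%
      tidyr::separate("class", into = c("fidelity", "class"), sep = "_")
  }
  long$class <- factor(long$class, levels = CLASS_LABELS)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$genome,
                                          y = .data$count,
                                          fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "SSR tracts", fill = "Motif class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
  if (split) p <- p + ggplot2::facet_wrap(~fidelity, ncol = 1)
  p
}

#' Plot coding vs non-coding proportions per genome
#'
#' @param stats Tibble of [genome_stats()] rows.
#' @return A ggplot object.
#' @export
plot_coding_split <- function(stats) {
  long <- stats %>%
    select("genome", "coding_total", "noncoding_total") %>%
    tidyr::pivot_longer(-"genome", names_to = "region",
                        values_to = "count") %>%
    mutate(region = ifelse(.data$region == "coding_total",
                           "coding", "non-coding"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genome, y = .data$count,
                                     fill = .data$region)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "Proportion of tracts", fill = "Region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Plot the top-ranked motifs as stacked per-genome bars
#'
#' Motifs are ranked by presence across genomes, then total frequency (the
#' ranking of [rank_top_motifs()]); bars stack the per-genome counts.
#'
#' @param matrix A [motif_matrix()] (or its `iterations = TRUE` variant).
#' @param k Number of motifs to show.
#' @return A ggplot object.
#' @export
plot_top_motifs <- function(matrix, k = 10) {
  top <- rank_top_motifs(matrix, k)
  gcols <- setdiff(names(top), c("motif", "total_genomes", "total_count"))
  long <- top %>%
    select("motif", all_of(gcols)) %>%
    tidyr::pivot_longer(-"motif", names_to = "genome", values_to = "count")
  long$motif <- factor(long$motif, levels = rev(top$motif))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$count, y = .data$motif,
                                     fill = .data$genome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Loci", y = NULL, fill = "Genome") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a mining project
#'
#' @param object An `ssr_project` from [run_ssr_project()].
#' @param ... Unused.
#' @return A ggplot object: per-genome motif-class distribution.
#' @export
autoplot.ssr_project <- function(object, ...) {
  plot_class_distribution(object$stats)
}
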