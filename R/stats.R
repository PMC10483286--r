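CLASS_LABELS <- c("mono", "di", "tri", "tetra", "penta", "hexa")

#' Per-genome aggregate statistics
#'
#' Summarises a genome's tracts into the row shape used by the comparison
#' statistics table: totals, motif-class counts, perfect/imperfect and
#' coding/non-coding splits, their cross-tabulation, and the SSR density
#' `total_ssr * 100 / genome_size` (a count-based percentage per base pair).
#' Compound repeats are never part of these statistics; pass the plain tract
#' table.
#'
#' @param tracts Tract tibble for one genome (may be empty).
#' @param genome The `genome_seq` the tracts came from, or a list with
#'   `name` and `total_length`.
#' @return A one-row tibble: `genome`, `genome_size`, `total_ssr`,
#'   `density_pct`, `perfect_total`, `imperfect_total`, `coding_total`,
#'   `noncoding_total`, the four perfect/imperfect x coding/non-coding
#'   subtotals, and per-class counts `mono`..`hexa`, `perfect_mono`..
#'   `perfect_hexa`, `imperfect_mono`..`imperfect_hexa`.
#' @export
genome_stats <- function(tracts, genome) {
  name <- genome$name
  size <- genome$total_length
  if (is.null(size) || size == 0) {
    stop("genome size must be positive", call. = FALSE)
  }
  if (nrow(tracts) > 0 && !all(tracts$genome %in% c(name, NA))) {
    stop("tracts belong to a different genome than '", name, "'",
         call. = FALSE)
  }
  cls <- as.integer(tracts$size)
  perfect <- tracts$perfect
  coding <- tracts$region == "coding"
  class_counts <- function(sel) {
    vapply(1:6, function(k) sum(cls[sel] == k), integer(1))
  }
  all_sel <- rep(TRUE, nrow(tracts))
  pc <- class_counts(all_sel)
  ppc <- class_counts(perfect)
  ipc <- class_counts(!perfect)
  row <- tibble(
    genome = name,
    genome_size = size,
    total_ssr = nrow(tracts),
    density_pct = nrow(tracts) * 100 / size,
    perfect_total = sum(perfect),
    imperfect_total = sum(!perfect),
    coding_total = sum(coding),
    noncoding_total = sum(!coding),
    perfect_coding = sum(perfect & coding),
    perfect_noncoding = sum(perfect & !coding),
    imperfect_coding = sum(!perfect & coding),
    imperfect_noncoding = sum(!perfect & !coding)
  )
  for (k in 1:6) row[[CLASS_LABELS[k]]] <- pc[k]
  for (k in 1:6) row[[paste0("perfect_", CLASS_LABELS[k])]] <- ppc[k]
  for (k in 1:6) row[[paste0("imperfect_", CLASS_LABELS[k])]] <- ipc[k]
  row
}

#' Motif-frequency matrix across genomes
#'
#' Counts how many loci carry each motif in each genome. Rows key on the
#' repeat unit *as found* in the sequence (standardized forms are available
#' per tract in the `canonical` column); with `iterations = TRUE` rows key on
#' the (unit, iteration) pair written `"(UNIT)n"`, the dataset behind the
#' motif-iteration ranking. Genome columns are ordered lexicographically so
#' the matrix never depends on input order.
#'
#' @param tracts Combined tract tibble (one or many genomes).
#' @param genomes Optional character vector of genome names to materialize as
#'   columns even when they carry no tracts.
#' @param iterations Key rows on (unit, iterations) instead of unit alone.
#' @return A tibble: `motif`, one count column per genome, `total_genomes`
#'   (number of genomes where the motif is present) and `total_count`.
#' @export
motif_matrix <- function(tracts, genomes = NULL, iterations = FALSE) {
  if (is.null(genomes)) genomes <- unique(tracts$genome)
  genomes <- sort(unique(as.character(genomes)), method = "radix")
  key <- if (iterations) {
    paste0("(", tracts$unit, ")", tracts$iterations)
  } else {
    tracts$unit
  }
  if (nrow(tracts) == 0 || length(genomes) == 0) {
    out <- tibble(motif = character(0))
    for (g in genomes) out[[g]] <- integer(0)
    out$total_genomes <- integer(0)
    out$total_count <- integer(0)
    return(out)
  }
  counts <- tibble(motif = key, genome = tracts$genome) %>%
    dplyr::count(.data$motif, .data$genome)
  wide <- tidyr::pivot_wider(counts, names_from = "genome",
                             values_from = "n", values_fill = 0L)
  for (g in setdiff(genomes, names(wide))) wide[[g]] <- 0L
  wide <- wide[, c("motif", genomes)]
  m <- as.matrix(wide[, genomes, drop = FALSE])
  wide$total_genomes <- as.integer(rowSums(m > 0))
  wide$total_count <- as.integer(rowSums(m))
  wide[order(wide$motif, method = "radix"), ]
}

#' Rank motifs by cross-genome presence and abundance
#'
#' Orders motif-frequency rows by the number of genomes in which the motif is
#' present (descending), then by absolute frequency across all genomes
#' (descending), then lexicographically by motif, and returns the first `k`.
#' Applied to a matrix built with `iterations = TRUE` it ranks
#' (motif, iteration) pairs instead.
#'
#' @param matrix A tibble from [motif_matrix()].
#' @param k Number of rows to keep (the charts use 10).
#' @return The top `k` rows of `matrix`, in rank order.
#' @export
rank_top_motifs <- function(matrix, k = 10) {
  stopifnot(k >= 1)
  ord <- order(-matrix$total_genomes, -matrix$total_count, matrix$motif,
               method = "radix")
  head(matrix[ord, ], k)
}
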