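#' Classify tracts into coding and non-coding regions
#'
#' A tract is coding when it overlaps at least one annotated gene interval by
#' one or more base pairs on its own record; otherwise it is non-coding.
#' Classification ignores strand. With an empty (or `NULL`) gene set every
#' tract is non-coding, the convention used when no annotation file
#' accompanies a genome.
#'
#' Gene intervals are matched to tracts by `record_id`. If the gene table has
#' no `record_id` column (or only missing values), the intervals are applied
#' to every record, which is the common single-record case.
#'
#' @param tracts A tract tibble from [mine_ssrs()].
#' @param genes A gene tibble with `start`, `end` (1-based inclusive) and
#'   optionally `record_id`, e.g. from [genbank_to_ptt()] or [read_ptt()].
#' @return `tracts` with its `region` column set to `"coding"`/`"noncoding"`.
#' @examples
#' tr <- find_perfect_tracts(strrep("ACG", 10),
#'                           ssr_params(min_repeats = rep(3, 6)))
#' classify_tracts(tr, tibble::tibble(start = 1, end = 100))$region
#' @export
classify_tracts <- function(tracts, genes) {
  if (nrow(tracts) == 0) return(tracts)
  if (is.null(genes) || nrow(genes) == 0) {
    tracts$region <- "noncoding"
    return(tracts)
  }
  stopifnot(all(genes$start >= 1), all(genes$start <= genes$end))
  by_record <- !is.null(genes[["record_id"]]) && !all(is.na(genes$record_id))
  region <- rep(NA_character_, nrow(tracts))
  for (rid in unique(tracts$record_id)) {
    sel <- tracts$record_id %in% rid
    g <- if (by_record) genes[genes$record_id %in% rid, ] else genes
    if (nrow(g) == 0) {
      region[sel] <- "noncoding"
      next
    }
    hits <- IRanges::overlapsAny(
      IRanges::IRanges(start = tracts$start[sel], end = tracts$end[sel]),
      IRanges::IRanges(start = g$start, end = g$end),
      minoverlap = 1L
    )
    region[sel] <- ifelse(hits, "coding", "noncoding")
  }
  tracts$region <- region
  tracts
}

# Rewrite GenBank record ids so they name FASTA records: matched ids are
# kept, unmatched GenBank records fall back to file order.
align_annotation <- function(genome, genes) {
  if (is.null(genes) || nrow(genes) == 0) return(genes)
  fasta_ids <- genome$records$record_id
  if (is.null(genes[["record_id"]])) return(genes)
  gb_ids <- unique(genes$record_id)
  if (all(gb_ids %in% fasta_ids)) return(genes)
  mapped <- fasta_ids[match(genes$record_id, gb_ids)]
  genes$record_id <- ifelse(genes$record_id %in% fasta_ids,
                            genes$record_id, mapped)
  genes
}
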