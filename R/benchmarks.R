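# Published validation protocols. The expected per-sequence totals shipped
# under inst/extdata/benchmarks/ are frozen from the published comparisons;
# the sequence data themselves are versioned NCBI accessions and must be
# downloaded by the user (they are too large to ship).

#' Published benchmark protocols
#'
#' `benchmark_expected()` returns the frozen expected counts for one of the
#' three published validation datasets; `benchmark_params()` returns the
#' mining parameters each protocol prescribes; `run_benchmark()` executes the
#' protocol on locally downloaded sequence files and compares observed totals
#' to the expected ones.
#'
#' Protocols: `"perfect_bac"` (10 barley BAC accessions, perfect-only search,
#' minimum 5 copies for every motif size, FASTA only); `"imperfect_mixed"`
#' (5 sequences from a human gene to whole prokaryote genomes, imperfect
#' search with per-size minima 5/3/2/2/2/2, 10% imperfection, mismatch limits
#' 1/1/1/2/2/3); `"cp_perfect"` (54 Corynebacterium pseudotuberculosis
#' genomes, perfect-only search at the default minima, with GenBank
#' annotation).
#'
#' @param which One of `"perfect_bac"`, `"imperfect_mixed"`, `"cp_perfect"`.
#' @return `benchmark_expected()`: a tibble of expected counts.
#' @export
benchmark_expected <- function(which = c("perfect_bac", "imperfect_mixed",
                                         "cp_perfect")) {
  which <- match.arg(which)
  f <- c(perfect_bac = "perfect_bac_totals.tsv",
         imperfect_mixed = "imperfect_mixed_totals.tsv",
         cp_perfect = "cp_perfect_table.tsv")[[which]]
  path <- system.file("extdata", "benchmarks", f, package = "ssrmine")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname benchmark_expected
#' @export
benchmark_params <- function(which = c("perfect_bac", "imperfect_mixed",
                                       "cp_perfect")) {
  which <- match.arg(which)
  switch(which,
    perfect_bac = misa_params(min_repeats = rep(5L, 6), dmax = 0L),
    imperfect_mixed = ssr_params(
      min_repeats = c(5L, 3L, 2L, 2L, 2L, 2L),
      imperfection_pct = rep(10, 6),
      mismatch_limit = c(1L, 1L, 1L, 2L, 2L, 3L),
      dmax = 0L, flank_len = 15L, std_level = 3
    ),
    cp_perfect = misa_params(dmax = 0L, flank_len = 15L, std_level = 3)
  )
}

#' @rdname benchmark_expected
#' @param data_dir Directory containing the downloaded inputs, one FASTA per
#'   accession named `<accession>.fasta` (plus `<accession>.gb` for the
#'   annotated protocol).
#' @return `run_benchmark()`: a tibble with one row per sequence
#'   (`accession`, `expected`, `observed`, `diff`).
#' @export
run_benchmark <- function(which = c("perfect_bac", "imperfect_mixed",
                                    "cp_perfect"), data_dir) {
  which <- match.arg(which)
  expected <- benchmark_expected(which)
  params <- benchmark_params(which)
  acc <- expected$accession
  fasta <- file.path(data_dir, paste0(acc, ".fasta"))
  missing <- fasta[!file.exists(fasta)]
  if (length(missing) > 0) {
    stop("Benchmark input files not found under '", data_dir, "': ",
         paste(basename(missing), collapse = ", "),
         "\nDownload the versioned accessions from NCBI first.",
         call. = FALSE)
  }
  observed <- vapply(fasta, function(f) {
    nrow(mine_ssrs(read_fasta(f), params))
  }, numeric(1))
  tibble(
    accession = acc,
    expected = expected[[if ("expected_total" %in% names(expected))
      "expected_total" else "total"]],
    observed = as.numeric(observed)
  ) %>%
    mutate(diff = .data$observed - .data$expected)
}
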