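# hand-built tract rows for statistics and reporting tests
fake_tract <- function(n, genome = "g", size = 3L, perfect = TRUE,
                       region = "noncoding", unit = "ACG",
                       iterations = 4L) {
  if (n == 0) {
    return(find_perfect_tracts("ACGT", ssr_params())[0, ])
  }
  tibble::tibble(
    genome = genome, record_id = "r", unit = unit,
    canonical = unit, size = size,
    start = seq_len(n) * 100L, end = seq_len(n) * 100L + size * iterations - 1L,
    tract_length = size * iterations, iterations = iterations,
    mismatches = ifelse(perfect, 0L, 1L),
    imperfection_obs = ifelse(perfect, 0, 100 / (size * iterations)),
    perfect = perfect, left_flank = "", right_flank = "", region = region
  )
}
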