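#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mining project into its per-tract table
#'
#' @param x An `ssr_project` from [run_ssr_project()].
#' @param ... Unused.
#' @return The combined tract tibble (one row per tract across all genomes).
#' @export
tidy.ssr_project <- function(x, ...) {
  x$tracts
}

#' One-row project summary
#'
#' @param x An `ssr_project` from [run_ssr_project()].
#' @param ... Unused.
#' @return A one-row tibble: genome count, totals, perfect/imperfect and
#'   coding/non-coding splits, distinct motif count and mean density.
#' @export
glance.ssr_project <- function(x, ...) {
  tibble(
    n_genomes = nrow(x$stats),
    total_ssr = sum(x$stats$total_ssr),
    perfect_total = sum(x$stats$perfect_total),
    imperfect_total = sum(x$stats$imperfect_total),
    coding_total = sum(x$stats$coding_total),
    noncoding_total = sum(x$stats$noncoding_total),
    n_compounds = nrow(x$compounds),
    n_motifs = nrow(x$matrix),
    mean_density_pct = mean(x$stats$density_pct)
  )
}
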