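# Output serialization. All files use 1-based inclusive coordinates; every
# number in the chart data is re-derivable from the tract table alone.

TRACT_COLUMNS <- c("Motif", "Canonical", "Iterations", "Genome", "Record",
                   "Left Flanking", "Right Flanking", "Start", "End",
                   "Mismatches", "Imperfection%", "Perfect", "Region")

#' Write the per-tract data table
#'
#' One row per tract with the columns `Motif, Canonical, Iterations, Genome,
#' Record, Left Flanking, Right Flanking, Start, End, Mismatches,
#' Imperfection%, Perfect, Region`, ordered by genome, record, start and
#' motif size. Coordinates are 1-based inclusive; imperfection is rounded to
#' two decimals.
#'
#' @param tracts Tract tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tract_table <- function(tracts, path) {
  ord <- tracts %>%
    arrange(.data$genome, .data$record_id, .data$start, .data$size)
  out <- tibble(
    Motif = ord$unit,
    Canonical = ord$canonical,
    Iterations = ord$iterations,
    Genome = ord$genome,
    Record = ord$record_id,
    `Left Flanking` = ord$left_flank,
    `Right Flanking` = ord$right_flank,
    Start = ord$start,
    End = ord$end,
    Mismatches = ord$mismatches,
    `Imperfection%` = round(ord$imperfection_obs, 2),
    Perfect = ord$perfect,
    Region = ord$region
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write the cross-genome statistics table
#'
#' One row per genome with every [genome_stats()] column, plus an appended
#' totals row (density recomputed over the summed genome sizes). Written as
#' CSV and, for spreadsheet import, as an identical tab-separated file.
#'
#' @param stats Tibble of [genome_stats()] rows.
#' @param path Output CSV path (a sibling `.tsv` is written alongside).
#' @return `path`, invisibly.
#' @export
write_statistics_table <- function(stats, path) {
  out <- bind_rows(stats, stats_totals_row(stats))
  readr::write_csv(out, path)
  readr::write_tsv(out, sub("\\.csv$", ".tsv", path))
  invisible(path)
}

stats_totals_row <- function(stats) {
  numcols <- names(stats)[vapply(stats, is.numeric, logical(1))]
  tot <- stats %>%
    summarise(across(all_of(numcols), sum))
  tot$genome <- "Total"
  tot$density_pct <- tot$total_ssr * 100 / tot$genome_size
  tot[, names(stats)]
}

#' Write chart-ready datasets
#'
#' Emits, as structured JSON, the seven donut datasets (perfect vs imperfect;
#' perfect per motif class; imperfect per motif class; perfect
#' coding/non-coding; imperfect coding/non-coding; overall coding/non-coding;
#' total per motif class) and the two top-10 stacked-bar datasets (per motif
#' and per motif-iteration, with per-genome counts), all aggregated over the
#' project.
#'
#' @param stats Tibble of [genome_stats()] rows.
#' @param matrix Motif-frequency matrix from [motif_matrix()].
#' @param matrix_iter Motif-iteration matrix
#'   (`motif_matrix(..., iterations = TRUE)`).
#' @param path Output JSON path.
#' @param top_k Number of motifs in the bar datasets.
#' @return `path`, invisibly.
#' @export
write_chart_data <- function(stats, matrix, matrix_iter, path, top_k = 10) {
  per_class <- function(prefix = "") {
    cols <- paste0(prefix, CLASS_LABELS)
    setNames(as.list(vapply(cols, function(cc) sum(stats[[cc]]),
                            numeric(1))), CLASS_LABELS)
  }
  donuts <- list(
    perfect_vs_imperfect = list(
      perfect = sum(stats$perfect_total),
      imperfect = sum(stats$imperfect_total)
    ),
    perfect_per_class = per_class("perfect_"),
    imperfect_per_class = per_class("imperfect_"),
    perfect_coding_noncoding = list(
      coding = sum(stats$perfect_coding),
      noncoding = sum(stats$perfect_noncoding)
    ),
    imperfect_coding_noncoding = list(
      coding = sum(stats$imperfect_coding),
      noncoding = sum(stats$imperfect_noncoding)
    ),
    coding_vs_noncoding = list(
      coding = sum(stats$coding_total),
      noncoding = sum(stats$noncoding_total)
    ),
    total_per_class = per_class("")
  )
  bars <- list(
    top_motifs = bar_dataset(matrix, top_k),
    top_motif_iterations = bar_dataset(matrix_iter, top_k)
  )
  jsonlite::write_json(
    list(coordinates = "1-based inclusive", donuts = donuts, bars = bars),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

bar_dataset <- function(matrix, top_k) {
  if (nrow(matrix) == 0) return(list())
  top <- rank_top_motifs(matrix, top_k)
  gcols <- setdiff(names(top), c("motif", "total_genomes", "total_count"))
  purrr::map(seq_len(nrow(top)), function(i) {
    list(
      motif = top$motif[i],
      genomes_present = top$total_genomes[i],
      total = top$total_count[i],
      per_genome = as.list(top[i, gcols])
    )
  })
}

#' Run a complete mining project
#'
#' The end-to-end batch pipeline: validates and pairs the inputs, converts
#' each GenBank annotation to a PTT table, mines every FASTA file as one
#' genome, classifies tracts into coding/non-coding regions, joins compound
#' repeats, and writes a report folder with one subfolder per genome (input
#' copies, generated PTT, tract and compound tables) plus the project-level
#' statistics table, motif-frequency matrices, chart data and a run manifest.
#' Rerunning with identical inputs and parameters reproduces every table
#' byte for byte (the manifest records wall-clock time and is exempt).
#'
#' @param fasta_paths One or more FASTA files (each one genome).
#' @param genbank_paths Optional GenBank files pairing with the FASTA inputs
#'   by filename stem.
#' @param params An [ssr_params()] object.
#' @param outdir Report folder to create.
#' @param project Project name recorded in the manifest.
#' @return An `ssr_project` object (list with `tracts`, `compounds`, `stats`,
#'   `matrix`, `matrix_iter`, `params`, `outdir`), invisibly usable with
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
run_ssr_project <- function(fasta_paths, genbank_paths = character(0),
                            params = ssr_params(), outdir,
                            project = "ssr-project") {
  t0 <- Sys.time()
  pairs <- pair_inputs(fasta_paths, genbank_paths)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  all_tracts <- list()
  all_compounds <- list()
  all_stats <- list()
  for (i in seq_len(nrow(pairs))) {
    genome <- read_fasta(pairs$fasta[i])
    sub <- file.path(outdir, genome$name)
    if (!dir.exists(sub)) dir.create(sub)
    file.copy(pairs$fasta[i], sub, overwrite = TRUE)

    genes <- NULL
    if (!is.na(pairs$genbank[i])) {
      file.copy(pairs$genbank[i], sub, overwrite = TRUE)
      genes <- genbank_to_ptt(pairs$genbank[i])
      genes <- align_annotation(genome, genes)
      write_ptt(genes,
                header = paste0(genome$name, " - ", genome$total_length,
                                " bp"),
                path = file.path(sub, paste0(genome$name, ".ptt")))
    }

    tracts <- mine_ssrs(genome, params)
    if (params$classify_coding && !is.null(genes)) {
      tracts <- classify_tracts(tracts, genes)
    }
    comp <- join_compound(tracts, params$dmax)
    write_tract_table(tracts, file.path(sub, paste0(genome$name,
                                                    "_tracts.csv")))
    readr::write_csv(comp$compounds,
                     file.path(sub, paste0(genome$name, "_compounds.csv")))
    all_tracts[[genome$name]] <- tracts
    all_compounds[[genome$name]] <- comp$compounds
    all_stats[[genome$name]] <- genome_stats(tracts, genome)
  }

  tracts <- bind_rows(all_tracts)
  compounds <- bind_rows(all_compounds)
  stats <- bind_rows(all_stats)
  genomes <- pairs$stem
  mat <- motif_matrix(tracts, genomes = genomes)
  mat_iter <- motif_matrix(tracts, genomes = genomes, iterations = TRUE)

  write_statistics_table(stats, file.path(outdir, "statistics.csv"))
  readr::write_csv(mat, file.path(outdir, "motif_frequency.csv"))
  readr::write_csv(mat_iter, file.path(outdir,
                                       "motif_iteration_frequency.csv"))
  write_chart_data(stats, mat, mat_iter,
                   file.path(outdir, "chart_data.json"))

  manifest <- list(
    project = project,
    tool = paste0("ssrmine ", as.character(packageVersion("ssrmine"))),
    r_version = as.character(getRversion()),
    coordinates = "1-based inclusive",
    inputs = list(fasta = basename(pairs$fasta),
                  genbank = ifelse(is.na(pairs$genbank), "",
                                   basename(pairs$genbank))),
    parameters = unclass(params),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(
    list(tracts = tracts, compounds = compounds, stats = stats,
         matrix = mat, matrix_iter = mat_iter, params = params,
         outdir = outdir),
    class = "ssr_project"
  )
}

#' @export
print.ssr_project <- function(x, ...) {
  cat("SSR mining project:", nrow(x$stats), "genome(s),",
      nrow(x$tracts), "tract(s),", nrow(x$compounds), "compound(s)\n")
  cat("Report folder:", x$outdir, "\n")
  invisible(x)
}
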