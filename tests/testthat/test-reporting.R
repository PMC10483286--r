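# End-to-end project runs on fixture genomes written to disk.

fixture_project <- function(dir, seed = 17) {
  g1 <- generate_genome(
    8000,
    plants = dplyr::bind_rows(
      plant_spec("A", 14),
      plant_spec("ATG", 8, mismatches = tibble::tibble(
        unit_index = 4L, offset = 3L, base = "A")),
      plant_spec("AG", 9)
    ),
    genes = tibble::tibble(start = c(500L, 4000L), end = c(2500L, 6000L),
                           strand = c("+", "-")),
    seed = seed, name = "fixA", dir = dir
  )
  g2 <- generate_genome(
    8000,
    plants = dplyr::bind_rows(
      plant_spec("ATG", 10),
      plant_spec("ACGT", 5)
    ),
    genes = tibble::tibble(start = 1000L, end = 3000L, strand = "+"),
    seed = seed + 1, name = "fixB", dir = dir
  )
  list(g1 = g1, g2 = g2)
}

test_that("a two-genome project writes the full report folder", {
  dir <- withr::local_tempdir()
  fx <- fixture_project(dir)
  out <- file.path(dir, "report")
  suppressWarnings(
    prj <- run_ssr_project(
      c(fx$g1$paths$fasta, fx$g2$paths$fasta),
      c(fx$g1$paths$genbank, fx$g2$paths$genbank),
      params = ssr_params(), outdir = out
    )
  )
  # per-genome subfolders with inputs, PTT, tract and compound tables
  for (g in c("fixA", "fixB")) {
    expect_true(dir.exists(file.path(out, g)))
    expect_true(file.exists(file.path(out, g, paste0(g, ".fasta"))))
    expect_true(file.exists(file.path(out, g, paste0(g, ".ptt"))))
    expect_true(file.exists(file.path(out, g, paste0(g, "_tracts.csv"))))
    expect_true(file.exists(file.path(out, g, paste0(g, "_compounds.csv"))))
  }
  # project-level files
  for (f in c("statistics.csv", "statistics.tsv", "motif_frequency.csv",
              "motif_iteration_frequency.csv", "chart_data.json",
              "manifest.json")) {
    expect_true(file.exists(file.path(out, f)))
  }
  # tracts recovered match the planted truth per genome
  expect_identical(sum(prj$tracts$genome == "fixA"), nrow(fx$g1$truth))
  expect_identical(sum(prj$tracts$genome == "fixB"), nrow(fx$g2$truth))
  # region classification agrees with the truth table
  trA <- prj$tracts[prj$tracts$genome == "fixA", ]
  expect_identical(trA$region, fx$g1$truth$region)
})

test_that("the tract table has the documented columns and round-trips", {
  dir <- withr::local_tempdir()
  tr <- find_imperfect_tracts(paste0(strrep("TGCC", 3), strrep("A", 14),
                                     strrep("GATC", 3)), ssr_params())
  tr$genome <- "g"
  tr$record_id <- "r"
  path <- file.path(dir, "tracts.csv")
  write_tract_table(tr, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(names(back),
                   c("Motif", "Canonical", "Iterations", "Genome", "Record",
                     "Left Flanking", "Right Flanking", "Start", "End",
                     "Mismatches", "Imperfection%", "Perfect", "Region"))
  expect_identical(nrow(back), nrow(tr))
  expect_identical(as.integer(back$Start), tr$start)
  expect_identical(as.integer(back$End), tr$end)
  expect_identical(back$Motif, tr$unit)
  expect_identical(dplyr::coalesce(back$`Left Flanking`, ""), tr$left_flank)
  # empty input -> header-only file
  write_tract_table(tr[0, ], path)
  expect_identical(nrow(readr::read_csv(path, show_col_types = FALSE)), 0L)
  expect_identical(readLines(path)[1],
                   paste0("Motif,Canonical,Iterations,Genome,Record,",
                          "Left Flanking,Right Flanking,Start,End,",
                          "Mismatches,Imperfection%,Perfect,Region"))
})

test_that("statistics table appends a conserving totals row", {
  dir <- withr::local_tempdir()
  st <- dplyr::bind_rows(
    genome_stats(fake_tract(5, genome = "a"),
                 list(name = "a", total_length = 10000L)),
    genome_stats(fake_tract(7, genome = "b"),
                 list(name = "b", total_length = 20000L))
  )
  path <- file.path(dir, "stats.csv")
  write_statistics_table(st, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(nrow(back), 3L)
  tot <- back[back$genome == "Total", ]
  expect_identical(tot$total_ssr, 12)
  expect_identical(tot$genome_size, 30000)
  expect_equal(tot$density_pct, 12 * 100 / 30000, tolerance = 1e-9)
  # written rows still conserve
  expect_identical(back$total_ssr, back$coding_total + back$noncoding_total)
  expect_identical(back$total_ssr,
                   back$perfect_total + back$imperfect_total)
  # spreadsheet-compatible sibling holds the same table
  tsv <- readr::read_tsv(file.path(dir, "stats.tsv"),
                         show_col_types = FALSE)
  expect_identical(tsv, back)
})

test_that("chart data re-derives from the tract table and matches rankings", {
  dir <- withr::local_tempdir()
  fx <- fixture_project(dir, seed = 23)
  out <- file.path(dir, "report")
  suppressWarnings(
    prj <- run_ssr_project(
      c(fx$g1$paths$fasta, fx$g2$paths$fasta),
      c(fx$g1$paths$genbank, fx$g2$paths$genbank),
      params = ssr_params(), outdir = out
    )
  )
  chart <- jsonlite::read_json(file.path(out, "chart_data.json"),
                               simplifyVector = TRUE)
  tracts <- prj$tracts
  expect_equal(chart$donuts$perfect_vs_imperfect$perfect,
               sum(tracts$perfect))
  expect_equal(chart$donuts$perfect_vs_imperfect$imperfect,
               sum(!tracts$perfect))
  expect_equal(chart$donuts$coding_vs_noncoding$coding,
               sum(tracts$region == "coding"))
  expect_equal(sum(unlist(chart$donuts$total_per_class)), nrow(tracts))
  expect_equal(chart$donuts$perfect_per_class$mono,
               sum(tracts$perfect & tracts$size == 1))
  # bar datasets follow rank_top_motifs order
  top <- rank_top_motifs(prj$matrix, 10)
  bars <- chart$bars$top_motifs # simplified to a data frame on read
  expect_identical(bars$motif, head(top$motif, nrow(bars)))
})

test_that("rerunning a project reproduces every table byte for byte", {
  dir <- withr::local_tempdir()
  fx <- fixture_project(dir, seed = 31)
  out1 <- file.path(dir, "r1")
  out2 <- file.path(dir, "r2")
  for (out in c(out1, out2)) {
    suppressWarnings(run_ssr_project(
      c(fx$g1$paths$fasta, fx$g2$paths$fasta),
      c(fx$g1$paths$genbank, fx$g2$paths$genbank),
      params = ssr_params(), outdir = out
    ))
  }
  files <- c("statistics.csv", "motif_frequency.csv",
             "motif_iteration_frequency.csv", "chart_data.json",
             "fixA/fixA_tracts.csv", "fixA/fixA_compounds.csv",
             "fixB/fixB_tracts.csv", "fixA/fixA.ptt")
  for (f in files) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("a project without annotation classifies everything non-coding", {
  dir <- withr::local_tempdir()
  fx <- generate_genome(6000, plants = plant_spec("ATG", 8), seed = 41,
                        name = "plaing", dir = dir)
  out <- file.path(dir, "report")
  prj <- run_ssr_project(fx$paths$fasta, character(0),
                         params = ssr_params(), outdir = out)
  expect_identical(unique(prj$tracts$region), "noncoding")
  st <- prj$stats
  expect_identical(st$coding_total, 0L)
  expect_identical(st$noncoding_total, st$total_ssr)
  expect_false(file.exists(file.path(out, "plaing", "plaing.ptt")))
})

test_that("tidy, glance and autoplot expose the project results", {
  dir <- withr::local_tempdir()
  fx <- generate_genome(
    6000,
    plants = dplyr::bind_rows(plant_spec("ATG", 8), plant_spec("A", 14)),
    seed = 43, name = "tg", dir = dir
  )
  prj <- run_ssr_project(fx$paths$fasta, outdir = file.path(dir, "rep"))
  td <- generics::tidy(prj)
  expect_identical(nrow(td), 2L)
  gl <- generics::glance(prj)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$total_ssr, 2L)
  expect_identical(gl$n_genomes, 1L)
  p <- ggplot2::autoplot(prj)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_coding_split(prj$stats), "ggplot")
  expect_s3_class(plot_top_motifs(prj$matrix), "ggplot")
})
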