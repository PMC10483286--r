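# Deterministic synthetic genomes with planted repeat truth sets. The
# background is rejection-sampled until it contains no tract passing the
# target thresholds outside the planted regions, so recovery tests have a
# clean false-positive surface. Substitution-type imperfections only, which
# is the mutation model the mining parameters expose.

#' Describe a repeat tract to plant in a synthetic genome
#'
#' @param unit Primitive repeat unit (1-6 bp, ACGT).
#' @param iterations Number of complete unit copies to plant.
#' @param at 1-based insertion position, or `NA` to place randomly.
#' @param mismatches Optional tibble with columns `unit_index` (2..iterations),
#'   `offset` (1..size) and `base`: substitutions applied to the perfect
#'   tract. Mismatches in the first unit or at the final base would shift the
#'   detected anchor and are rejected.
#' @param label Free-text label carried into the truth table.
#' @return A one-row tibble consumed by [generate_genome()].
#' @export
plant_spec <- function(unit, iterations, at = NA_integer_,
                       mismatches = NULL, label = unit) {
  stopifnot(nchar(unit) >= 1, nchar(unit) <= 6, !grepl("[^ACGT]", unit),
            iterations >= 1)
  if (!is_primitive(unit)) {
    stop("plant unit '", unit, "' is not primitive", call. = FALSE)
  }
  tibble(
    unit = unit,
    iterations = as.integer(iterations),
    at = as.integer(at),
    mismatches = list(mismatches %||% tibble(unit_index = integer(0),
                                             offset = integer(0),
                                             base = character(0))),
    label = label
  )
}

#' Generate a synthetic genome with planted repeats and annotation
#'
#' Builds a random background of the requested length and GC content, plants
#' the requested tracts at known coordinates, and resamples any background
#' stretch (never the plants) in which the mining engine finds an unplanted
#' tract, until the engine's output over the whole genome equals the planted
#' truth exactly. The same seed always yields byte-identical output.
#'
#' @param length Genome length in bp.
#' @param gc GC fraction of the background (0-1).
#' @param plants A tibble of [plant_spec()] rows (bind with
#'   `dplyr::bind_rows()`), or `NULL` for pure background.
#' @param genes Optional tibble of gene intervals (`start`, `end`, `strand`)
#'   used to write a minimal GenBank annotation and to set each plant's
#'   expected region.
#' @param seed Integer seed; all randomness derives from it.
#' @param params Target [ssr_params()]; the background is guaranteed free of
#'   tracts passing these thresholds.
#' @param name Genome name (FASTA stem and record id).
#' @param dir If non-`NULL`, write `<name>.fasta`, `<name>_truth.tsv` and
#'   (when `genes` is supplied) `<name>.gb` into this directory.
#' @param max_attempts Cap on background resampling rounds.
#' @return A list: `genome` (a `genome_seq`), `truth` (tibble: `label`,
#'   `unit`, `size`, `start`, `end`, `iterations`, `mismatches`, `region`),
#'   `genes`, and `paths` (when `dir` is given).
#' @export
generate_genome <- function(length, gc = 0.5, plants = NULL, genes = NULL,
                            seed = 1L, params = ssr_params(),
                            name = "synthetic", dir = NULL,
                            max_attempts = 1000L) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(names(probs), length, replace = TRUE, prob = probs)

  margin <- 25L
  placed <- tibble(label = character(0), unit = character(0),
                   size = integer(0), start = integer(0), end = integer(0),
                   iterations = integer(0), mismatches = integer(0))
  if (!is.null(plants) && nrow(plants) > 0) {
    seqs <- purrr::pmap(plants, build_plant)
    for (i in seq_along(seqs)) validate_plant(plants[i, ], seqs[[i]], params)
    occupied <- integer(0)
    starts <- integer(nrow(plants))
    ord <- order(is.na(plants$at)) # explicit positions first
    for (i in ord) {
      len <- length(seqs[[i]])
      at <- plants$at[i]
      if (is.na(at)) {
        lo <- margin + 1L
        hi <- length - len - margin + 1L
        if (hi < lo) stop("genome too short for plant ", i, call. = FALSE)
        ok <- FALSE
        for (try in seq_len(max_attempts)) {
          at <- sample(lo:hi, 1)
          span <- (at - margin):(at + len - 1L + margin)
          if (!any(span %in% occupied)) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place plant ", i, " without overlap",
                      call. = FALSE)
      } else {
        if (at < 1 || at + len - 1L > length) {
          stop("plant ", i, " does not fit at position ", at, call. = FALSE)
        }
        if (any(at:(at + len - 1L) %in% occupied)) {
          stop("plant ", i, " overlaps another plant", call. = FALSE)
        }
      }
      starts[i] <- at
      occupied <- c(occupied, (at - margin):(at + len - 1L + margin))
      chars[at:(at + len - 1L)] <- seqs[[i]]
    }
    placed <- tibble(
      label = plants$label,
      unit = plants$unit,
      size = nchar(plants$unit),
      start = starts,
      end = starts + vapply(seqs, length, integer(1)) - 1L,
      iterations = plants$iterations,
      mismatches = vapply(plants$mismatches, nrow, integer(1))
    )
  }

  truth <- placed %>% arrange(.data$start, .data$size)
  plant_pos <- unlist(purrr::map2(truth$start, truth$end, seq),
                      use.names = FALSE)

  clean <- FALSE
  for (attempt in seq_len(max_attempts)) {
    residues <- paste(chars, collapse = "")
    found <- find_imperfect_tracts(residues, params)
    extras <- dplyr::anti_join(
      found[, c("start", "end", "size", "mismatches")],
      truth[, c("start", "end", "size", "mismatches")],
      by = c("start", "end", "size", "mismatches")
    )
    if (nrow(extras) == 0) {
      missing <- dplyr::anti_join(
        truth[, c("start", "end", "size", "mismatches")],
        found[, c("start", "end", "size", "mismatches")],
        by = c("start", "end", "size", "mismatches")
      )
      if (nrow(missing) > 0) {
        stop("planted tract(s) not recovered by the engine; ",
             "check plant specs against the parameters", call. = FALSE)
      }
      clean <- TRUE
      break
    }
    resample <- unique(unlist(
      purrr::map2(pmax(1L, extras$start - 1L),
                  pmin(length, extras$end + 1L), seq),
      use.names = FALSE
    ))
    resample <- setdiff(resample, plant_pos)
    if (length(resample) == 0) {
      stop("an unplanted tract lies entirely inside planted regions; ",
           "the requested plants embed secondary repeats", call. = FALSE)
    }
    chars[resample] <- sample(names(probs), length(resample),
                              replace = TRUE, prob = probs)
  }
  if (!clean) {
    stop("failed to obtain a repeat-free background after ", max_attempts,
         " attempts", call. = FALSE)
  }

  truth$region <- if (!is.null(genes) && nrow(genes) > 0) {
    ifelse(
      IRanges::overlapsAny(
        IRanges::IRanges(truth$start, truth$end),
        IRanges::IRanges(genes$start, genes$end), minoverlap = 1L),
      "coding", "noncoding")
  } else {
    rep("noncoding", nrow(truth))
  }

  genome <- genome_seq(name, setNames(paste(chars, collapse = ""), name))
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fasta <- file.path(dir, paste0(name, ".fasta"))
    write_fasta(genome, fasta)
    truth_path <- file.path(dir, paste0(name, "_truth.tsv"))
    readr::write_tsv(truth, truth_path)
    gb <- NULL
    if (!is.null(genes) && nrow(genes) > 0) {
      gb <- file.path(dir, paste0(name, ".gb"))
      write_genbank_minimal(name, length, genes, gb)
    }
    paths <- list(fasta = fasta, truth = truth_path, genbank = gb)
  }
  list(genome = genome, truth = truth, genes = genes, paths = paths)
}

build_plant <- function(unit, iterations, at, mismatches, label) {
  k <- nchar(unit)
  chars <- rep(strsplit(unit, "")[[1]], iterations)
  if (nrow(mismatches) > 0) {
    pos <- (mismatches$unit_index - 1L) * k + mismatches$offset
    chars[pos] <- mismatches$base
  }
  chars
}

validate_plant <- function(spec, seq_chars, params) {
  k <- nchar(spec$unit)
  mm <- spec$mismatches[[1]]
  r <- params$min_repeats[k]
  m <- params$mismatch_limit[k]
  p <- params$imperfection_pct[k]
  len <- spec$iterations * k
  if (spec$iterations < r) {
    stop("plant '", spec$label, "': ", spec$iterations,
         " iterations is below the minimum of ", r, call. = FALSE)
  }
  if (nrow(mm) == 0) return(invisible(TRUE))
  unit_chars <- strsplit(spec$unit, "")[[1]]
  if (any(mm$unit_index <= 1L) || any(mm$unit_index > spec$iterations)) {
    stop("plant '", spec$label,
         "': mismatches must fall in units 2..iterations", call. = FALSE)
  }
  if (any(mm$offset < 1L | mm$offset > k)) {
    stop("plant '", spec$label, "': mismatch offset outside unit",
         call. = FALSE)
  }
  if (any(mm$unit_index == spec$iterations & mm$offset == k)) {
    stop("plant '", spec$label, "': mismatch at the final base would ",
         "truncate the detected tract", call. = FALSE)
  }
  if (any(mm$base == unit_chars[mm$offset])) {
    stop("plant '", spec$label, "': substitution equals the consensus base",
         call. = FALSE)
  }
  per_unit <- table(mm$unit_index)
  if (any(per_unit > m)) {
    stop("plant '", spec$label, "': more than ", m,
         " mismatches in one unit", call. = FALSE)
  }
  if (100 * nrow(mm) / len > p) {
    stop("plant '", spec$label, "': imperfection exceeds ", p, "%",
         call. = FALSE)
  }
  pos <- sort((mm$unit_index - 1L) * k + mm$offset)
  if (length(pos) > 1 && any(diff(pos) == 1L)) {
    runs <- rle(diff(pos) == 1L)
    if (any(runs$values & runs$lengths >= m * k)) {
      stop("plant '", spec$label, "': consecutive mismatch run exceeds ",
           m * k, " bases", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Minimal GenBank flat file carrying CDS features; enough for genbank_to_ptt.
write_genbank_minimal <- function(name, length, genes, path) {
  loc <- ifelse(genes$strand == "-",
                paste0("complement(", genes$start, "..", genes$end, ")"),
                paste0(genes$start, "..", genes$end))
  feat <- unlist(purrr::map(seq_len(nrow(genes)), function(i) {
    c(sprintf("     %-16s%s", "CDS", loc[i]),
      sprintf("                     /locus_tag=\"%s_%04d\"", name, i),
      sprintf("                     /product=\"synthetic protein %d\"", i))
  }))
  writeLines(c(
    sprintf("LOCUS       %s %d bp    DNA     linear   SYN", name, length),
    "DEFINITION  synthetic genome with planted repeat tracts.",
    sprintf("ACCESSION   %s", name),
    sprintf("VERSION     %s", name),
    "FEATURES             Location/Qualifiers",
    sprintf("     %-16s%s", "source", paste0("1..", length)),
    feat,
    "ORIGIN",
    "//"
  ), path)
  invisible(path)
}
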