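# Core detection layer: thin R wrappers over the compiled scanners plus
# tract assembly (units, canonical motifs, flanks, iteration counts).

DNA_CODE <- local({
  m <- rep(-1L, 128)
  m[utf8ToInt("A")] <- 0L
  m[utf8ToInt("C")] <- 1L
  m[utf8ToInt("G")] <- 2L
  m[utf8ToInt("T")] <- 3L
  m
})

encode_dna <- function(residues) {
  idx <- utf8ToInt(residues)
  out <- rep(-1L, length(idx))
  ok <- idx <= 128L
  out[ok] <- DNA_CODE[idx[ok]]
  out
}

#' Find microsatellite tracts in a nucleotide sequence
#'
#' `find_perfect_tracts()` reports every maximal run of a primitive 1-6 bp
#' unit whose complete copy number reaches `min_repeats` for its size; runs
#' include any trailing partial unit. `find_imperfect_tracts()` runs the
#' general search that also admits substitutions, bounded per repeat unit by
#' `mismatch_limit` and over the whole tract by `imperfection_pct`; with all
#' budgets at zero (Misa mode) its output is identical to the perfect search.
#' Tracts with zero mismatches are flagged perfect.
#'
#' Coordinates are 1-based inclusive and relative to the scanned sequence.
#' Ambiguity codes (N, R, ...) never occur inside a perfect tract and never
#' form part of a consensus unit; in imperfect tracts they count as
#' mismatches.
#'
#' @param x A nucleotide string, or a `genome_seq` object (each record is
#'   scanned independently).
#' @param params An [ssr_params()] object.
#' @return A tibble with one row per tract: `genome`, `record_id`, `unit` (as
#'   found), `canonical`, `size`, `start`, `end`, `tract_length`,
#'   `iterations`, `mismatches`, `imperfection_obs`, `perfect`, `left_flank`,
#'   `right_flank`, `region` (initialized to "noncoding"; see
#'   [classify_tracts()]). Sorted by record, start, then size.
#' @examples
#' find_perfect_tracts("GACACACAT", ssr_params(min_repeats = c(12, 3, 4, 3, 3, 3)))
#' @export
find_perfect_tracts <- function(x, params = ssr_params()) {
  mine_ssrs(x, params, search = "perfect")
}

#' @rdname find_perfect_tracts
#' @export
find_imperfect_tracts <- function(x, params = ssr_params()) {
  mine_ssrs(x, params, search = "imperfect")
}

#' @rdname find_perfect_tracts
#' @param search `"imperfect"` (the general search; the default) or
#'   `"perfect"` (maximal exact runs only).
#' @export
mine_ssrs <- function(x, params = ssr_params(), search = c("imperfect", "perfect")) {
  search <- match.arg(search)
  if (inherits(x, "genome_seq")) {
    recs <- x$records
    out <- purrr::pmap(
      list(recs$record_id, recs$residues),
      function(id, res) scan_record(res, params, search, x$name, id)
    )
    return(bind_rows(out))
  }
  stopifnot(is.character(x), length(x) == 1)
  scan_record(toupper(x), params, search,
              genome = NA_character_, record_id = NA_character_)
}

scan_record <- function(residues, params, search, genome, record_id) {
  code <- encode_dna(residues)
  sizes <- sizes_for(params)
  scan <- if (search == "perfect") {
    .scan_perfect_cpp(code, sizes, params$min_repeats)
  } else {
    .scan_imperfect_cpp(code, sizes, params$min_repeats,
                        params$mismatch_limit, params$imperfection_pct)
  }
  tracts_from_scan(as_tibble(scan), residues, params, genome, record_id)
}

tracts_from_scan <- function(scan, residues, params, genome, record_id) {
  n <- nchar(residues)
  if (nrow(scan) == 0) {
    return(tibble(
      genome = character(0), record_id = character(0), unit = character(0),
      canonical = character(0), size = integer(0), start = integer(0),
      end = integer(0), tract_length = integer(0), iterations = integer(0),
      mismatches = integer(0), imperfection_obs = numeric(0),
      perfect = logical(0), left_flank = character(0),
      right_flank = character(0), region = character(0)
    ))
  }
  scan <- scan %>% arrange(.data$start, .data$size)
  unit <- substring(residues, scan$start, scan$start + scan$size - 1)
  canon <- canonical_map(unit, params$std_level)
  len <- scan$end - scan$start + 1L
  tibble(
    genome = genome,
    record_id = record_id,
    unit = unit,
    canonical = canon,
    size = scan$size,
    start = scan$start,
    end = scan$end,
    tract_length = len,
    iterations = len %/% scan$size,
    mismatches = scan$mismatches,
    imperfection_obs = 100 * scan$mismatches / len,
    perfect = scan$mismatches == 0L,
    left_flank = substring(residues, pmax(1L, scan$start - params$flank_len),
                           scan$start - 1L),
    right_flank = substring(residues, scan$end + 1L,
                            pmin(n, scan$end + params$flank_len)),
    region = rep("noncoding", nrow(scan))
  )
}

canonical_map <- function(units, level) {
  if (length(units) == 0) return(character(0))
  uu <- unique(units)
  canon <- vapply(uu, canonical_motif, character(1), level = level)
  unname(canon[match(units, uu)])
}

#' Extract flanking sequences around a tract
#'
#' Returns the up- and downstream bases adjacent to `[start, end]`, truncated
#' at the sequence boundaries.
#'
#' @param residues Nucleotide string.
#' @param start,end Tract coordinates, 1-based inclusive.
#' @param flank_len Maximum flank length (bp).
#' @return A tibble with columns `left_flank` and `right_flank`.
#' @export
extract_flanks <- function(residues, start, end, flank_len = 15L) {
  n <- nchar(residues)
  tibble(
    left_flank = substring(residues, pmax(1L, start - flank_len), start - 1L),
    right_flank = substring(residues, end + 1L, pmin(n, end + flank_len))
  )
}

#' Join nearby tracts into compound repeats
#'
#' Consecutive tracts (sorted by start within a record) whose gaps are each
#' between 0 and `dmax` bases are chained into one compound repeat.
#' Overlapping tracts are never chained. Compounds are reported separately
#' and their member tracts stay in all summary statistics; `dmax = -1`
#' disables joining entirely.
#'
#' @param tracts A tract tibble from [mine_ssrs()].
#' @param dmax Maximum gap in bp (-1..100).
#' @return A list with `compounds` (one row per compound: span, member count,
#'   member units, gaps) and `standalone` (tracts in no compound).
#' @export
join_compound <- function(tracts, dmax) {
  stopifnot(dmax >= -1, dmax <= 100)
  empty <- tibble(
    genome = character(0), record_id = character(0),
    compound_id = integer(0), n_members = integer(0),
    span_start = integer(0), span_end = integer(0),
    members = character(0), gaps = character(0)
  )
  if (dmax < 0 || nrow(tracts) == 0) {
    return(list(compounds = empty, standalone = tracts))
  }
  chained <- tracts %>%
    group_by(.data$genome, .data$record_id) %>%
    arrange(.data$start, .data$size, .by_group = TRUE) %>%
    mutate(
      gap_prev = .data$start - dplyr::lag(.data$end) - 1L,
      new_chain = is.na(.data$gap_prev) | .data$gap_prev < 0L |
        .data$gap_prev > dmax,
      chain = cumsum(.data$new_chain)
    ) %>%
    group_by(.data$chain, .add = TRUE) %>%
    mutate(chain_size = n()) %>%
    ungroup()

  members <- chained %>% filter(.data$chain_size >= 2)
  compounds <- if (nrow(members) == 0) empty else {
    members %>%
      group_by(.data$genome, .data$record_id, .data$chain) %>%
      summarise(
        n_members = n(),
        span_start = min(.data$start),
        span_end = max(.data$end),
        members = paste0("(", .data$unit, ")", .data$iterations,
                         collapse = "+"),
        gaps = paste(.data$gap_prev[-1], collapse = ","),
        .groups = "drop"
      ) %>%
      arrange(.data$genome, .data$record_id, .data$span_start) %>%
      mutate(compound_id = row_number()) %>%
      select("genome", "record_id", "compound_id", "n_members",
             "span_start", "span_end", "members", "gaps")
  }
  standalone <- chained %>%
    filter(.data$chain_size == 1) %>%
    select(-"gap_prev", -"new_chain", -"chain", -"chain_size")
  list(compounds = compounds, standalone = standalone)
}
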