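# GenBank feature-table parsing, NCBI PTT emission, and FASTA/GenBank
# pairing. Only CDS features define "coding": the PTT is a protein table,
# so tRNA/rRNA/misc features are never emitted. Pseudo-genes (CDS with
# /pseudo) are kept -- coordinate overlap, not translatability, drives
# region classification.

#' Pair FASTA inputs with optional GenBank annotation files
#'
#' Files are paired on identical filename stems (case-sensitive). When no
#' GenBank files are supplied at all, every FASTA is paired with an absent
#' annotation and all regions later classify as non-coding. When any GenBank
#' file is supplied, every FASTA must have a partner and no GenBank file may
#' be orphaned.
#'
#' @param fasta_paths Character vector of FASTA paths.
#' @param genbank_paths Character vector of GenBank paths (may be empty).
#' @return A tibble with columns `stem`, `fasta`, `genbank` (`NA` when
#'   absent), in the order of `fasta_paths`.
#' @examples
#' pair_inputs(c("a.fasta", "b.fasta"), character(0))
#' @export
pair_inputs <- function(fasta_paths, genbank_paths = character(0)) {
  stopifnot(length(fasta_paths) >= 1)
  fstem <- vapply(fasta_paths, fasta_stem, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(fstem)) {
    stop("Duplicate FASTA filename stems: ",
         paste(unique(fstem[duplicated(fstem)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(genbank_paths) == 0) {
    return(tibble(stem = fstem, fasta = fasta_paths,
                  genbank = NA_character_))
  }
  gstem <- vapply(genbank_paths, fasta_stem, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(gstem)) {
    stop("Duplicate GenBank filename stems: ",
         paste(unique(gstem[duplicated(gstem)]), collapse = ", "),
         call. = FALSE)
  }
  unmatched_fasta <- setdiff(fstem, gstem)
  if (length(unmatched_fasta) > 0) {
    stop("GenBank files were supplied but these FASTA inputs have no ",
         "annotation partner: ", paste(unmatched_fasta, collapse = ", "),
         call. = FALSE)
  }
  orphans <- setdiff(gstem, fstem)
  if (length(orphans) > 0) {
    stop("GenBank files without a matching FASTA input: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  tibble(stem = fstem, fasta = fasta_paths,
         genbank = genbank_paths[match(fstem, gstem)])
}

#' Extract CDS gene intervals from a GenBank flat file
#'
#' Parses the feature table of a GenBank flat file and returns one row per
#' CDS feature, the material of an NCBI PTT protein table. Compound
#' (`join`/`complement`) locations are resolved to their outer `min..max`
#' span; the strand is `-` when the location is complemented. The amino-acid
#' length is `floor(span/3) - 1` (the span minus the stop codon, in codons).
#' Missing qualifiers are emitted as `"-"`.
#'
#' @param path Path to a GenBank flat file (one or more records).
#' @return A tibble sorted by record then start with columns `record_id`,
#'   `start`, `end`, `strand`, `length_aa`, `pid`, `gene`, `synonym`, `code`,
#'   `cog`, `product`. Zero rows (with a warning) when the file has no CDS
#'   features: the genome is then treated as entirely non-coding.
#' @export
genbank_to_ptt <- function(path) {
  if (!file.exists(path)) {
    stop("GenBank file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^LOCUS", lines))) {
    stop("'", basename(path), "' does not look like a GenBank flat file ",
         "(no LOCUS line)", call. = FALSE)
  }
  rec_starts <- grep("^LOCUS", lines)
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  out <- purrr::map2(rec_starts, rec_ends, function(s, e) {
    parse_genbank_record(lines[s:e])
  })
  genes <- bind_rows(out)
  if (nrow(genes) == 0) {
    warning("No CDS features in '", basename(path),
            "'; the genome will be treated as entirely non-coding",
            call. = FALSE)
  }
  genes
}

parse_genbank_record <- function(lines) {
  empty <- tibble(
    record_id = character(0), start = integer(0), end = integer(0),
    strand = character(0), length_aa = integer(0), pid = character(0),
    gene = character(0), synonym = character(0), code = character(0),
    cog = character(0), product = character(0)
  )
  ver <- grep("^VERSION", lines, value = TRUE)
  acc <- grep("^ACCESSION", lines, value = TRUE)
  record_id <- if (length(ver) > 0) {
    strsplit(trimws(sub("^VERSION", "", ver[1])), "\\s+")[[1]][1]
  } else if (length(acc) > 0) {
    strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
  } else {
    strsplit(trimws(sub("^LOCUS", "", lines[1])), "\\s+")[[1]][1]
  }
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0) return(empty)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- fend[fend > fstart[1]]
  fend <- if (length(fend) > 0) fend[1] - 1L else length(lines)
  feat <- lines[(fstart[1] + 1L):fend]
  if (length(feat) == 0) return(empty)

  # feature starts carry a key in columns 6-20
  is_start <- grepl("^ {5}\\S", feat)
  idx <- which(is_start)
  if (length(idx) == 0) return(empty)
  rows <- purrr::map(seq_along(idx), function(i) {
    block <- feat[idx[i]:(if (i < length(idx)) idx[i + 1] - 1L else length(feat))]
    key <- sub("^\\s*(\\S+).*$", "\\1", block[1])
    if (key != "CDS") return(NULL)
    parse_cds_block(block, record_id)
  })
  genes <- bind_rows(purrr::compact(rows))
  if (nrow(genes) == 0) return(empty)
  genes %>% arrange(.data$start, .data$end)
}

parse_cds_block <- function(block, record_id) {
  # location may continue over lines until the first qualifier
  qual_at <- grep("^\\s{10,}/", block)
  loc_end <- if (length(qual_at) > 0) qual_at[1] - 1L else length(block)
  loc <- paste(gsub("\\s+", "", c(
    sub("^\\s*\\S+\\s*", "", block[1]),
    if (loc_end >= 2) block[2:loc_end] else character(0)
  )), collapse = "")
  pos <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (length(pos) == 0) return(NULL)
  start <- min(pos)
  end <- max(pos)
  strand <- if (grepl("complement", loc, fixed = TRUE)) "-" else "+"

  quals <- parse_qualifiers(block[seq_along(block) >= loc_end + 1L])
  pid <- quals[["protein_id"]] %||% "-"
  gis <- quals_all(block, "db_xref")
  gi <- grep("^GI:", gis, value = TRUE)
  if (length(gi) > 0) pid <- sub("^GI:", "", gi[1])
  tibble(
    record_id = record_id,
    start = start,
    end = end,
    strand = strand,
    length_aa = (end - start + 1L) %/% 3L - 1L,
    pid = pid,
    gene = quals[["gene"]] %||% "-",
    synonym = quals[["locus_tag"]] %||% "-",
    code = "-",
    cog = "-",
    product = quals[["product"]] %||% "-"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

parse_qualifiers <- function(lines) {
  if (length(lines) == 0) return(list())
  txt <- trimws(lines)
  starts <- grepl("^/", txt)
  if (!any(starts)) return(list())
  grp <- cumsum(starts)
  keep <- grp >= 1
  pieces <- split(txt[keep], grp[keep])
  out <- list()
  for (p in pieces) {
    joined <- paste(p, collapse = " ")
    m <- regmatches(joined, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", joined))[[1]]
    if (length(m) == 0) next
    key <- m[2]
    val <- if (is.na(m[4]) || m[4] == "") "true" else gsub("^\"|\"$", "", m[4])
    if (is.null(out[[key]])) out[[key]] <- val
  }
  out
}

quals_all <- function(block, key) {
  txt <- trimws(block)
  hits <- grep(paste0("^/", key, "="), txt, value = TRUE)
  gsub("^\"|\"$", "", sub(paste0("^/", key, "="), "", hits))
}

#' Write and read NCBI PTT protein tables
#'
#' `write_ptt()` emits the NCBI PTT dialect: a description line, a
#' `"<N> proteins"` line, the nine tab-separated column headers
#' (`Location Strand Length PID Gene Synonym Code COG Product`, with Location
#' as `start..end`), then one row per gene. `read_ptt()` parses the same
#' dialect back; `read_ptt(write_ptt(x))` is the identity on every field.
#'
#' @param genes A gene tibble as returned by [genbank_to_ptt()] (the
#'   `record_id` column is optional and not serialized).
#' @param header Description placed on the first line.
#' @param path Output (or input) file path.
#' @return `write_ptt()` returns `path` invisibly; `read_ptt()` returns a
#'   gene tibble.
#' @export
write_ptt <- function(genes, header, path) {
  body <- if (nrow(genes) == 0) character(0) else {
    paste(paste0(genes$start, "..", genes$end), genes$strand,
          genes$length_aa, genes$pid, genes$gene, genes$synonym,
          genes$code, genes$cog, genes$product, sep = "\t")
  }
  writeLines(c(
    header,
    paste0(nrow(genes), " proteins"),
    paste("Location", "Strand", "Length", "PID", "Gene", "Synonym",
          "Code", "COG", "Product", sep = "\t"),
    body
  ), path)
  invisible(path)
}

#' @rdname write_ptt
#' @export
read_ptt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) {
    stop("'", basename(path), "' is not a PTT file (fewer than 3 lines)",
         call. = FALSE)
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(tibble(
      start = integer(0), end = integer(0), strand = character(0),
      length_aa = integer(0), pid = character(0), gene = character(0),
      synonym = character(0), code = character(0), cog = character(0),
      product = character(0)
    ))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  loc <- vapply(parts, `[`, character(1), 1)
  se <- strsplit(loc, "..", fixed = TRUE)
  tibble(
    start = as.integer(vapply(se, `[`, character(1), 1)),
    end = as.integer(vapply(se, `[`, character(1), 2)),
    strand = vapply(parts, `[`, character(1), 2),
    length_aa = as.integer(vapply(parts, `[`, character(1), 3)),
    pid = vapply(parts, `[`, character(1), 4),
    gene = vapply(parts, `[`, character(1), 5),
    synonym = vapply(parts, `[`, character(1), 6),
    code = vapply(parts, `[`, character(1), 7),
    cog = vapply(parts, `[`, character(1), 8),
    product = vapply(parts, `[`, character(1), 9)
  )
}
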