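#' Read a FASTA file as a single genome
#'
#' Each FASTA file is treated as one genome: a multi-record file is analyzed
#' as a single draft genome whose records are scanned independently (tracts
#' never span record boundaries) but aggregated together. The genome label is
#' the filename stem, never a record header, and must be shorter than 35
#' characters.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @return A `genome_seq` object: a list with `name` (filename stem), a
#'   `records` tibble (`record_id`, `residues`, `length`) in file order, and
#'   `total_length`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "acgtACGT"), fa)
#' g <- read_fasta(fa)
#' g$total_length
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  stem <- fasta_stem(path)
  if (nchar(stem) >= 35) {
    stop("Filename stem of '", basename(path),
         "' has ", nchar(stem), " characters; it must have fewer than 35",
         call. = FALSE)
  }
  set <- tryCatch(
    withCallingHandlers(
      Biostrings::readDNAStringSet(path),
      warning = function(w) {
        # the reader silently drops letters outside the IUPAC DNA alphabet
        if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
          stop("non-nucleotide characters present", call. = FALSE)
        }
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) {
      stop("'", basename(path), "' is not a valid nucleotide FASTA file: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (length(set) == 0) {
    stop("FASTA file '", basename(path), "' contains no records",
         call. = FALSE)
  }
  if (any(Biostrings::width(set) == 0)) {
    stop("FASTA file '", basename(path), "' contains empty records",
         call. = FALSE)
  }
  bad <- Biostrings::alphabetFrequency(set)[, c("-", "+", "."), drop = FALSE]
  if (any(bad > 0)) {
    stop("FASTA file '", basename(path),
         "' contains gap or non-nucleotide characters", call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  residues <- toupper(as.character(set))
  genome_seq(stem, setNames(residues, ids))
}

#' Construct a genome object from named residue strings
#'
#' @param name Genome label (< 35 characters).
#' @param records Named character vector of uppercase nucleotide sequences,
#'   in order; names are record ids.
#' @return A `genome_seq` object.
#' @export
genome_seq <- function(name, records) {
  stopifnot(is.character(records), length(records) >= 1,
            all(nchar(records) > 0), nchar(name) < 35)
  ids <- names(records)
  if (is.null(ids)) ids <- paste0("record", seq_along(records))
  recs <- tibble(
    record_id = ids,
    residues = toupper(unname(records)),
    length = nchar(unname(records))
  )
  structure(
    list(name = name, records = recs, total_length = sum(recs$length)),
    class = "genome_seq"
  )
}

#' Write a genome back to FASTA
#'
#' @param genome A `genome_seq` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(setNames(genome$records$residues,
                                           genome$records$record_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("Genome '", x$name, "': ", nrow(x$records), " record(s), ",
      format(x$total_length, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

# stem of a (possibly gzipped) sequence file name
fasta_stem <- function(path) {
  b <- basename(path)
  b <- sub("\\.gz$", "", b)
  tools::file_path_sans_ext(b)
}
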