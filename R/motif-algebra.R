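#' Motif-level computations
#'
#' A repeat unit is *primitive* when it is not a whole-number power of a
#' shorter unit ("ATAT" is 2 x "AT" and therefore not primitive). Only
#' primitive units anchor tracts, so one physical repeat is never reported
#' under two motif sizes.
#'
#' @param unit A nucleotide string of length 1-6.
#' @return `is_primitive()`: a logical flag.
#' @examples
#' is_primitive("AT")
#' is_primitive("ATAT")
#' canonical_motif("GCT", 3)
#' @export
is_primitive <- function(unit) {
  k <- nchar(unit)
  stopifnot(k >= 1, k <= 6)
  chars <- strsplit(unit, "")[[1]]
  for (d in seq_len(k - 1)) {
    if (k %% d != 0) next
    if (all(chars == rep_len(chars[1:d], k))) return(FALSE)
  }
  TRUE
}

#' @rdname is_primitive
#' @param level Standardization level: `0` leaves the unit as found; `1` takes
#'   the lexicographically smallest cyclic rotation; `2` minimizes over
#'   rotations of the unit and of its complement; `3` (and its alias `"F"`)
#'   minimizes over rotations of the unit and of its reverse complement, so
#'   that repeats equivalent up to phase and strand share one representative.
#' @return `canonical_motif()`: the standardized unit (same length as `unit`).
#' @export
canonical_motif <- function(unit, level = 3) {
  level <- as.character(level)
  if (!level %in% c("0", "1", "2", "3", "F")) {
    stop("`level` must be one of 0, 1, 2, 3 or \"F\"", call. = FALSE)
  }
  if (grepl("[^ACGT]", unit)) {
    stop("Motif units must contain only A, C, G, T; got '", unit, "'",
         call. = FALSE)
  }
  if (!is_primitive(unit)) {
    stop("Motif unit '", unit, "' is not primitive", call. = FALSE)
  }
  if (level == "0") return(unit)
  orbit <- motif_rotations(unit)
  if (level == "2") {
    orbit <- c(orbit, motif_rotations(complement_dna(unit)))
  } else if (level %in% c("3", "F")) {
    orbit <- c(orbit, motif_rotations(revcomp_dna(unit)))
  }
  sort(orbit, method = "radix")[1]
}

#' @rdname is_primitive
#' @export
motif_rotations <- function(unit) {
  k <- nchar(unit)
  doubled <- paste0(unit, unit)
  vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1), character(1))
}

#' @rdname is_primitive
#' @export
revcomp_dna <- function(unit) {
  chartr("ACGT", "TGCA",
         vapply(unit, function(u) {
           paste(rev(strsplit(u, "")[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

#' @rdname is_primitive
#' @export
complement_dna <- function(unit) {
  chartr("ACGT", "TGCA", unit)
}

#' Motif size class labels (mono..hexa)
#' @param size Integer vector of unit lengths (1-6).
#' @return A factor with levels mono, di, tri, tetra, penta, hexa.
#' @export
motif_class <- function(size) {
  factor(c("mono", "di", "tri", "tetra", "penta", "hexa")[size],
         levels = c("mono", "di", "tri", "tetra", "penta", "hexa"))
}
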