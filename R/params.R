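#' Mining parameter set
#'
#' Builds the full parameter model controlling the repeat search. Defaults are
#' tuned for bacterial whole-genome comparisons: a tract must contain at least
#' 12/6/4/3/3/3 copies of a mono- to hexanucleotide unit, may carry at most
#' 1/1/1/2/2/2 mismatches per repeat unit, and its overall imperfection may
#' not exceed 10% of the tract length.
#'
#' Setting every `mismatch_limit` and `imperfection_pct` entry to 0 restricts
#' the search to perfect repeats ("Misa mode"); [misa_params()] is a shortcut.
#'
#' @param min_repeats Integer vector of length 6: minimum number of complete
#'   unit copies per motif size 1..6.
#' @param mismatch_limit Integer vector of length 6: maximum mismatches allowed
#'   within any single aligned repeat unit, per motif size.
#' @param imperfection_pct Numeric vector of length 6: maximum percentage of
#'   mismatched bases over the whole tract (0-100), per motif size.
#' @param dmax Maximum gap (bp) between consecutive tracts joined into a
#'   compound repeat; -1 disables compound joining; range -1..100.
#' @param flank_len Length (bp) of flanking sequence extracted on each side.
#' @param std_level Motif standardization level: `0` (as found), `1` (smallest
#'   cyclic rotation), `2` (rotations of unit and complement), `3` or `"F"`
#'   (rotations of unit and reverse complement).
#' @param ssr_type `0` to search all motif sizes, or a single size 1..6.
#' @param classify_coding Classify tracts into coding/non-coding regions when
#'   annotation is available.
#'
#' @return An object of class `ssr_params` (a named list).
#' @examples
#' ssr_params()
#' misa_params(min_repeats = rep(5L, 6))
#' @export
ssr_params <- function(min_repeats = c(12L, 6L, 4L, 3L, 3L, 3L),
                       mismatch_limit = c(1L, 1L, 1L, 2L, 2L, 2L),
                       imperfection_pct = rep(10, 6),
                       dmax = 0L,
                       flank_len = 15L,
                       std_level = 3,
                       ssr_type = 0L,
                       classify_coding = TRUE) {
  min_repeats <- as.integer(min_repeats)
  mismatch_limit <- as.integer(mismatch_limit)
  imperfection_pct <- as.numeric(imperfection_pct)
  stopifnot(
    length(min_repeats) == 6, all(min_repeats >= 1L),
    length(mismatch_limit) == 6, all(mismatch_limit >= 0L),
    length(imperfection_pct) == 6,
    all(imperfection_pct >= 0), all(imperfection_pct <= 100),
    length(dmax) == 1, dmax >= -1, dmax <= 100,
    length(flank_len) == 1, flank_len >= 0,
    length(ssr_type) == 1, ssr_type %in% 0:6,
    is.logical(classify_coding), length(classify_coding) == 1
  )
  std_level <- as.character(std_level)
  if (!std_level %in% c("0", "1", "2", "3", "F")) {
    stop("`std_level` must be one of 0, 1, 2, 3 or \"F\"", call. = FALSE)
  }
  structure(
    list(
      min_repeats = min_repeats,
      mismatch_limit = mismatch_limit,
      imperfection_pct = imperfection_pct,
      dmax = as.integer(dmax),
      flank_len = as.integer(flank_len),
      std_level = std_level,
      ssr_type = as.integer(ssr_type),
      classify_coding = classify_coding
    ),
    class = "ssr_params"
  )
}

#' @rdname ssr_params
#' @param ... Passed on to [ssr_params()].
#' @export
misa_params <- function(min_repeats = c(12L, 6L, 4L, 3L, 3L, 3L), ...) {
  ssr_params(min_repeats = min_repeats,
             mismatch_limit = rep(0L, 6),
             imperfection_pct = rep(0, 6), ...)
}

#' @rdname ssr_params
#' @param params An `ssr_params` object.
#' @export
is_misa_mode <- function(params) {
  all(params$imperfection_pct == 0) && all(params$mismatch_limit == 0)
}

#' @export
print.ssr_params <- function(x, ...) {
  cls <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  cat("SSR mining parameters",
      if (is_misa_mode(x)) "(Misa mode: perfect repeats only)", "\n")
  cat("  min repeats     :", paste(cls, x$min_repeats, sep = "=",
                                   collapse = " "), "\n")
  cat("  mismatch limit  :", paste(cls, x$mismatch_limit, sep = "=",
                                   collapse = " "), "\n")
  cat("  imperfection %  :", paste(cls, x$imperfection_pct, sep = "=",
                                   collapse = " "), "\n")
  cat("  dmax:", x$dmax, " flank:", x$flank_len,
      " std level:", x$std_level, " ssr type:", x$ssr_type,
      " classify coding:", x$classify_coding, "\n")
  invisible(x)
}

sizes_for <- function(params) {
  if (params$ssr_type == 0L) 1:6 else params$ssr_type
}
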