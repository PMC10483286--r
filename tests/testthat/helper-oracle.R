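# Independent brute-force oracle for the tract search. It evaluates every
# (start, end) candidate of every motif size by direct vector comparison
# against the anchored consensus, applies the declared constraints, and
# resolves same-size candidates by longest-then-leftmost with containment
# pruning. It shares no code with the compiled scanners.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# primitive iff all cyclic rotations are distinct
oracle_primitive <- function(unit_chars) {
  k <- length(unit_chars)
  rots <- vapply(seq_len(k), function(i) {
    paste(unit_chars[((seq_len(k) + i - 2) %% k) + 1], collapse = "")
  }, character(1))
  length(unique(rots)) == k
}

oracle_candidates <- function(chars, k, r, m, p) {
  n <- length(chars)
  acgt <- chars %in% c("A", "C", "G", "T")
  out <- list()
  if (n < r * k) return(data.frame(start = integer(0), end = integer(0),
                                   mismatches = integer(0)))
  for (a in seq_len(n - k + 1)) {
    unit <- chars[a:(a + k - 1)]
    if (!all(acgt[a:(a + k - 1)])) next
    if (!oracle_primitive(unit)) next
    idx <- a:n
    cons <- rep_len(unit, length(idx))
    mm <- as.integer(chars[idx] != cons | !acgt[idx])
    len <- seq_along(idx)
    cum <- cumsum(mm)
    cum0 <- c(0L, cum)
    # mismatches inside the aligned window each position belongs to
    win_mm <- cum - cum0[((len - 1) %/% k) * k + 1]
    cut1 <- which(win_mm > m)[1]
    last_match <- cummax(ifelse(mm == 0L, len, 0L))
    run <- len - last_match # length of the mismatch run ending here
    cut2 <- which(run > m * k)[1]
    cutoff <- min(cut1, cut2, length(idx) + 1L, na.rm = TRUE)
    valid <- mm == 0L & len >= r * k & 100 * cum <= p * len & len < cutoff
    js <- which(valid)
    if (length(js) > 0) {
      out[[length(out) + 1]] <- data.frame(start = a, end = a + js - 1L,
                                           mismatches = cum[js])
    }
  }
  if (length(out) == 0) return(data.frame(start = integer(0),
                                          end = integer(0),
                                          mismatches = integer(0)))
  do.call(rbind, out)
}

oracle_select <- function(cands) {
  if (nrow(cands) == 0) return(cands)
  len <- cands$end - cands$start + 1L
  cands <- cands[order(-len, cands$start), , drop = FALSE]
  keep <- logical(nrow(cands))
  sel_start <- integer(0)
  sel_end <- integer(0)
  for (i in seq_len(nrow(cands))) {
    contained <- any(sel_start <= cands$start[i] & sel_end >= cands$end[i])
    if (!contained) {
      keep[i] <- TRUE
      sel_start <- c(sel_start, cands$start[i])
      sel_end <- c(sel_end, cands$end[i])
    }
  }
  cands[keep, , drop = FALSE]
}

# full oracle: perfect search is the zero-budget special case
oracle_tracts <- function(residues, params, perfect = FALSE) {
  chars <- strsplit(residues, "")[[1]]
  sizes <- if (params$ssr_type == 0) 1:6 else params$ssr_type
  out <- list()
  for (k in sizes) {
    m <- if (perfect) 0L else params$mismatch_limit[k]
    p <- if (perfect) 0 else params$imperfection_pct[k]
    sel <- oracle_select(
      oracle_candidates(chars, k, params$min_repeats[k], m, p)
    )
    if (nrow(sel) > 0) {
      sel$size <- k
      out[[length(out) + 1]] <- sel
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0), size = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$size), c("start", "end", "size", "mismatches")]
}

# comparable key sets for set-equality between engine and oracle output
tract_key <- function(df) {
  sort(paste(df$start, df$end, df$size, df$mismatches, sep = ":"))
}
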