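p_di3 <- ssr_params(min_repeats = c(12L, 3L, 4L, 3L, 3L, 3L))

test_that("perfect search reports maximal runs with trailing partial units", {
  tr <- find_perfect_tracts(strrep("A", 12), ssr_params())
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$start, 1L)
  expect_identical(tr$end, 12L)
  expect_identical(tr$iterations, 12L)
  expect_identical(tr$size, 1L)

  tr2 <- find_perfect_tracts("ACACACAC", p_di3)
  expect_identical(c(tr2$start, tr2$end, tr2$iterations), c(1L, 8L, 4L))
  expect_identical(tr2$unit, "AC")

  # maximal run with leading offset and trailing partial unit
  tr3 <- find_perfect_tracts("GACACACAT", p_di3)
  expect_identical(c(tr3$start, tr3$end, tr3$tract_length, tr3$iterations),
                   c(2L, 8L, 7L, 3L))
})

test_that("non-primitive units are never reported at their composite size", {
  tr <- find_perfect_tracts("ATATATAT",
                            ssr_params(min_repeats = c(12L, 3L, 4L, 2L, 3L, 3L)))
  expect_identical(tr$size, 2L) # reported as (AT)4 only, never (ATAT)2
  expect_identical(tr$unit, "AT")
})

test_that("imperfect search honors mismatch budgets and anchors on a perfect unit", {
  tr <- find_imperfect_tracts("ATGATGATTATG", ssr_params())
  expect_identical(nrow(tr), 1L)
  expect_identical(c(tr$start, tr$end, tr$mismatches), c(1L, 12L, 1L))
  expect_identical(tr$unit, "ATG")
  expect_equal(tr$imperfection_obs, 100 / 12, tolerance = 1e-12)
  expect_false(tr$perfect)

  mono10 <- ssr_params(min_repeats = c(10L, 6L, 4L, 3L, 3L, 3L))
  tr2 <- find_imperfect_tracts("AAAAACAAAAA", mono10)
  expect_identical(c(tr2$start, tr2$end, tr2$mismatches), c(1L, 11L, 1L))
  expect_equal(tr2$imperfection_obs, 100 / 11, tolerance = 1e-12)
})

test_that("an accepted imperfect tract supersedes its contained perfect runs", {
  mono10 <- ssr_params(min_repeats = c(10L, 6L, 4L, 3L, 3L, 3L))
  s <- paste0(strrep("A", 10), "C", strrep("A", 10))
  tr <- find_imperfect_tracts(s, mono10)
  expect_identical(nrow(tr), 1L)
  expect_identical(c(tr$start, tr$end), c(1L, 21L))
  # the same sequence in perfect mode yields the two interrupted runs
  trp <- find_perfect_tracts(s, mono10)
  expect_identical(trp$start, c(1L, 12L))
  expect_identical(trp$end, c(10L, 21L))
})

test_that("ambiguity codes never seed a tract and count as mismatches", {
  mono10 <- ssr_params(min_repeats = c(10L, 6L, 4L, 3L, 3L, 3L))
  tr <- find_imperfect_tracts(paste0(strrep("A", 5), "N", strrep("A", 6)),
                              mono10)
  expect_identical(c(tr$start, tr$end, tr$mismatches), c(1L, 12L, 1L))
  # perfect tracts never contain an ambiguity code
  trp <- find_perfect_tracts(paste0(strrep("A", 12), "N", strrep("A", 12)),
                             ssr_params())
  expect_identical(trp$start, c(1L, 14L))
})

test_that("Misa-mode zero budgets reproduce the perfect search exactly", {
  set.seed(101)
  p <- misa_params(min_repeats = c(8L, 4L, 3L, 3L, 3L, 3L))
  for (i in 1:100) {
    s <- rand_dna(150)
    expect_identical(find_imperfect_tracts(s, p), find_perfect_tracts(s, p))
  }
})

test_that("no reported perfect tract is extendable in either direction", {
  set.seed(202)
  p <- ssr_params(min_repeats = c(6L, 3L, 2L, 2L, 2L, 2L))
  for (i in 1:25) {
    s <- rand_dna(300)
    chars <- strsplit(s, "")[[1]]
    tr <- find_perfect_tracts(s, p)
    for (j in seq_len(nrow(tr))) {
      a <- tr$start[j]; b <- tr$end[j]; k <- tr$size[j]
      if (a > 1) expect_false(chars[a - 1] == chars[a - 1 + k])
      if (b < nchar(s)) expect_false(chars[b + 1] == chars[b + 1 - k])
    }
  }
})

test_that("perfect mining is strand-symmetric at standardization level 3", {
  set.seed(303)
  p <- ssr_params(min_repeats = c(6L, 3L, 2L, 2L, 2L, 2L))
  for (i in 1:25) {
    s <- rand_dna(400)
    n <- nchar(s)
    fwd <- find_perfect_tracts(s, p)
    rev <- find_perfect_tracts(revcomp_dna(s), p)
    expect_identical(table(fwd$size), table(rev$size))
    expect_identical(sort(fwd$canonical), sort(rev$canonical))
    # coordinates mirror: start' = n - end + 1
    expect_identical(sort(n - fwd$end + 1L), sort(rev$start))
    expect_identical(sort(n - fwd$start + 1L), sort(rev$end))
  }
})

test_that("thresholds act monotonically on the reported tracts", {
  set.seed(404)
  for (i in 1:15) {
    s <- rand_dna(400)
    base <- ssr_params(min_repeats = c(8L, 4L, 3L, 2L, 2L, 2L))
    tr_base <- find_imperfect_tracts(s, base)
    # raising a minimum copy number never increases that size's tract count
    stricter <- ssr_params(min_repeats = c(9L, 5L, 4L, 3L, 3L, 3L))
    tr_strict <- find_imperfect_tracts(s, stricter)
    for (k in 1:6) {
      expect_lte(sum(tr_strict$size == k), sum(tr_base$size == k))
    }
    # widening mismatch budgets only merges or extends: every tract found
    # under the tight budgets lies inside a same-size tract of the wide run
    looser <- ssr_params(min_repeats = c(8L, 4L, 3L, 2L, 2L, 2L),
                         mismatch_limit = c(1L, 2L, 2L, 3L, 3L, 3L),
                         imperfection_pct = rep(20, 6))
    tr_loose <- find_imperfect_tracts(s, looser)
    for (j in seq_len(nrow(tr_base))) {
      covered <- any(tr_loose$size == tr_base$size[j] &
                       tr_loose$start <= tr_base$start[j] &
                       tr_loose$end >= tr_base$end[j])
      expect_true(covered)
    }
  }
})

test_that("ssr_type restricts the search to one motif size", {
  s <- paste0(strrep("A", 12), "GTC", strrep("AC", 8))
  all_sizes <- find_perfect_tracts(s, ssr_params())
  expect_setequal(all_sizes$size, c(1L, 2L))
  only_di <- find_perfect_tracts(s, ssr_params(ssr_type = 2L))
  expect_identical(unique(only_di$size), 2L)
})

make_tracts <- function(starts, ends, units = "AC") {
  tibble::tibble(
    genome = "g", record_id = "r",
    unit = units, size = nchar(units),
    start = as.integer(starts), end = as.integer(ends),
    iterations = (end - start + 1L) %/% size
  )
}

test_that("compound joining chains tracts by gap distance", {
  res <- join_compound(make_tracts(c(1, 11), c(10, 20)), dmax = 0)
  expect_identical(nrow(res$compounds), 1L)
  expect_identical(res$compounds$gaps, "0")
  expect_identical(c(res$compounds$span_start, res$compounds$span_end),
                   c(1L, 20L))
  expect_identical(nrow(res$standalone), 0L)

  res2 <- join_compound(make_tracts(c(1, 16), c(10, 25)), dmax = 0)
  expect_identical(nrow(res2$compounds), 0L)
  expect_identical(nrow(res2$standalone), 2L)

  res3 <- join_compound(make_tracts(c(1, 12, 22), c(10, 20, 30)), dmax = 1)
  expect_identical(res3$compounds$n_members, 3L)
  expect_identical(res3$compounds$gaps, "1,1")

  # dmax -1 disables compounding; overlapping tracts never chain
  expect_identical(nrow(join_compound(make_tracts(c(1, 11), c(10, 20)),
                                      dmax = -1)$compounds), 0L)
  expect_identical(nrow(join_compound(make_tracts(c(1, 8), c(10, 20)),
                                      dmax = 5)$compounds), 0L)
})

test_that("flanks are verbatim substrings truncated at record boundaries", {
  s <- paste(rep(c("A", "C", "G", "T"), 15), collapse = "")
  f <- extract_flanks(s, 16, 30, 15)
  expect_identical(f$left_flank, substr(s, 1, 15))
  expect_identical(f$right_flank, substr(s, 31, 45))
  expect_identical(extract_flanks(s, 1, 10, 15)$left_flank, "")
  expect_identical(nchar(extract_flanks(s, 40, 55, 15)$right_flank), 5L)
})

test_that("multi-record genomes are scanned per record", {
  g <- genome_seq("two", c(r1 = paste0("TGC", strrep("A", 12), "GTC"),
                           r2 = strrep("AG", 10)))
  tr <- mine_ssrs(g, ssr_params())
  expect_identical(tr$record_id, c("r1", "r2"))
  expect_identical(tr$start, c(4L, 1L))
  expect_identical(tr$genome, c("two", "two"))
  # flanks never cross record boundaries
  expect_identical(tr$left_flank[2], "")
})
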