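---
title: "Mining perfect and imperfect microsatellites across genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining perfect and imperfect microsatellites across genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmine)
library(dplyr)
```

## The problem

Microsatellites (SSRs) are tandem repetitions of a 1–6 bp motif. Comparing
their content across many genomes requires three ingredients that are
usually scattered over separate tools: a repeat search that handles both
perfect and imperfect (substitution-carrying) tracts, a mapping of each
tract onto gene annotation to split coding from non-coding repeats, and
cross-genome aggregation into comparable tables. `ssrmine` implements the
three as one pipeline: each FASTA file is one genome (multi-FASTA files are
treated as a single draft genome whose records are scanned independently),
an optional GenBank file per genome supplies gene intervals via an NCBI PTT
protein table, and the batch is summarized into statistics, motif-frequency
and ranking products.

## Detection model

All coordinates are 1-based inclusive and per record; tracts and flanks
never span record boundaries (concatenating records would invent junction
repeats). Input residues are uppercased before scanning, so soft-masked
FASTA gives identical results.

**Perfect tracts.** For each motif size $k$, every maximal run in which each
base equals the base $k$ positions earlier is a candidate; the run's unit is
its first $k$ bases. A run is reported when the unit is primitive (not a
whole-number power of a shorter unit — `ATAT` is reported as `(AT)`, never
as a size-4 unit) and the number of complete copies
$\lfloor \mathrm{length}/k \rfloor$ reaches the per-size minimum
`min_repeats[k]`. Trailing partial units are part of the span; `iterations`
always counts complete copies. Maximality holds in both directions: no
reported tract can be extended by one base and stay a pure repeat.

**Imperfect tracts.** The general search admits substitutions. The paper
trail of most published mining tools leaves the extension semantics
unspecified, so this package fixes them explicitly (they are the package's
own, documented semantics, validated in tests against an exhaustive
candidate oracle):

* the consensus unit is anchored at the tract start: $u = s[a..a+k-1]$, so
  the first unit is exact and the reported `unit` column is the repeat as
  found in the sequence;
* every aligned complete unit, and the trailing partial unit, carries at
  most `mismatch_limit[k]` mismatches relative to the consensus;
* a run of consecutive mismatched bases never exceeds
  `mismatch_limit[k] * k` bases — an interruption longer than one unit's
  whole budget ends the tract rather than hiding inside it. This keeps the
  per-unit budget meaningful for mononucleotides (where a "unit" is a single
  base) and guarantees the scan terminates at the first unsalvageable
  breakpoint;
* the first and last base of the tract match the consensus (a tract never
  starts or ends on a mismatch — otherwise any tract could be padded with
  noise);
* the tract-level imperfection, $100 M / \mathrm{length}$, is at most
  `imperfection_pct[k]`;
* complete copies number at least `min_repeats[k]`.

Ambiguity codes (N, R, Y, ...) are accepted at parse time, never occur
inside a perfect tract, never form part of a consensus unit, and count as
mismatches inside imperfect tracts.

**Candidate resolution.** All valid candidates of one size compete:
longest first, ties to the leftmost start, and a candidate is discarded only
when its span is *contained* in an already accepted same-size tract.
Containment (rather than any-overlap) pruning is deliberate: maximal perfect
runs of the same size can legitimately overlap by up to $k-1$ bases when
they are phase-shifted (in `ACACGCGC`, `(AC)` and `(CG)` runs share one
base), and the zero-budget search must reproduce the perfect search exactly.
Under containment pruning that equivalence is provable: with zero budgets
the valid candidates are precisely the subspans of maximal runs, the runs
themselves are selected, and every subspan is contained and discarded. A
consequence of the same rule is that an accepted imperfect tract supersedes
the perfect fragments it contains — mirroring the observation that allowing
mismatches extends tracts previously broken by an interruption and thereby
*lowers* the perfect count. For the same reason "more mismatch budget"
does not monotonically increase the tract count (two runs can merge into
one); what does hold, and is property-tested, is that every tract found
under tighter budgets lies inside a same-size tract found under wider
budgets, and that raising `min_repeats[k]` never increases the size-$k$
count.

**Compound SSRs.** After the per-size searches, consecutive tracts (sorted
by start within a record, any motif size) whose gaps are each between 0 and
`dmax` bases chain into compound repeats. `dmax = -1` disables joining;
overlapping tracts are never chained (a gap is a non-negative number of
intervening bases). Compounds are reported in their own table and their
members stay in all summary statistics — the statistics describe tracts, not
compounds.

## Parameters

| parameter | unit | default | role |
|---|---|---|---|
| `min_repeats` | copies, per size 1..6 | 12, 6, 4, 3, 3, 3 | minimum complete unit copies |
| `mismatch_limit` | mismatches per unit | 1, 1, 1, 2, 2, 2 | per-unit substitution budget |
| `imperfection_pct` | % of tract length | 10 for all sizes | tract-level mismatch cap |
| `dmax` | bp, −1..100 | 0 | compound joining distance |
| `flank_len` | bp | 15 | flanking sequence length |
| `std_level` | 0/1/2/3/F | 3 | motif standardization orbit |
| `ssr_type` | 0..6 | 0 | 0 = all sizes, k = only size k |
| `classify_coding` | flag | TRUE | coding/non-coding classification |

The defaults target bacterial whole-genome comparisons (long mononucleotide
minima suppress sequencing-noise homopolymers; 10% imperfection with 1–2
mismatches per unit matches common practice for imperfect SSR scans).
Setting every mismatch and imperfection entry to 0 — `misa_params()` — is
the conventional "perfect repeats only" configuration.

**Standardization levels.** Level 0 leaves units as found; level 1 maps a
unit to its lexicographically smallest cyclic rotation; level 2 minimizes
over rotations of the unit and of its complement; level 3 (alias `F`)
minimizes over rotations of the unit and of its reverse complement, so
repeats equivalent up to phase and strand share one representative
(`GCT`, `TGC` and `GCA` all standardize to `AGC`). These orbit definitions
are this package's fixed semantics; published tools do not document theirs,
so bit-level agreement with any particular tool is not claimed. Frequency
and report tables key on the *as-found* unit — distinct rotational forms are
biologically distinguishable loci and are counted separately — with the
canonical form carried as an extra column.

## Region classification

A tract is coding when it overlaps at least one annotated CDS interval by
one or more base pairs on its own record, irrespective of strand; the
outputs are strictly binary, so boundary-straddling tracts count as coding.
Only CDS features define coding sequence (a PTT is a protein table;
tRNA/rRNA/misc features are ignored), pseudo-genes are kept (coordinate
overlap, not translatability, is what matters here), and compound
`join(...)` locations use their outer span, matching PTT's single Location
column. With no annotation — the GenBank file is optional — every tract is
non-coding by convention. Amino-acid length in the PTT is
$\lfloor \mathrm{span}/3 \rfloor - 1$ (codons minus the stop). Multi-record
GenBank files map features to their own record, matched to FASTA records by
identical id with a fallback to file order.

## Statistics and rankings

`genome_stats()` reports, per genome: total tract count, the count-based
density `total_ssr * 100 / genome_size` (a literal reading of the printed
formula — a count percentage per base pair, not base-pair coverage),
per-class counts (mono..hexa), perfect/imperfect and coding/non-coding
splits and their cross-tabulation. The conservation identities (every split
sums to the total) are property-tested on every fixture run.
`motif_matrix()` counts loci per as-found unit per genome (optionally per
(unit, iteration) pair) with genome columns ordered lexicographically so
results never depend on input order; `rank_top_motifs()` orders rows by
presence across genomes, then total frequency, then unit (the lexicographic
tie-break is this package's choice — the first two keys are the standard
ones). Chart datasets (seven donuts, two top-10 stacked bars) are
re-derivable from the tract table alone.

## The synthetic-data generator

`generate_genome()` emulates the features the pipeline's correctness
depends on: an i.i.d. background of controlled GC content, planted perfect
and imperfect tracts of every motif class with exact known coordinates and
mismatch placement, and gene intervals for the coding/non-coding split. The
background is rejection-sampled — any stretch where the engine finds an
unplanted tract is resampled (never the plants), capped at a configurable
number of rounds — so recovery tests have a guaranteed clean false-positive
surface. Mismatch placement is validated against the target parameters
(never in the first unit or at the final base, per-unit and tract-level
budgets respected) so every plant is detectable by construction, and
imperfections are substitutions only, which is the mutation model the
mining parameters expose. The same seed yields byte-identical FASTA, truth
table and annotation.

What the generator does **not** emulate: real base composition structure
(codon bias, GC skew, repeat families), indels, sequencing errors, or the
correlated repeat landscapes of real genomes. Passing the planted-recovery
tests therefore demonstrates coordinate-exact detection under the declared
semantics, not field accuracy on any particular organism; the published
per-accession totals (see `run_benchmark()`) are the external yardstick for
that, and require downloading the versioned NCBI accessions.

## Numerical and engineering choices

* The scanners are compiled (Rcpp). For each size the imperfect scan
  enumerates, from every anchor, all valid end positions; the per-unit and
  interruption limits make the expected extension length a small constant on
  random or genomic sequence, so whole-genome scans are effectively linear
  (an annotated 5 Mb genome mines in about a second on one core). Extremely
  low-complexity inputs (e.g. megabase-scale pure `ACAC...`) degrade toward
  quadratic candidate enumeration for the mononucleotide scan; such inputs
  are outside the intended use.
* Selection is deterministic everywhere: candidate sort is (length desc,
  start asc), ranking tie-breaks are lexicographic in the C locale, and the
  engine is seed-free. Reruns reproduce every table byte for byte.
* Degenerate inputs: empty FASTA records, gap characters, protein
  sequences, and stems of 35+ characters are rejected at parse time with
  the file named; a GenBank file without CDS features yields an empty gene
  table plus a warning and an all-non-coding genome; an empty tract set
  produces zero-filled statistics and header-only tables.
* `min_repeats[k] = 1` would make every position a "tract" in the imperfect
  search while the perfect scanner reports only actual repetitions; minima
  of at least 2 are the meaningful range.
* Tests size the property checks to run on one core in well under five
  minutes: the exhaustive-oracle comparison uses 100 random sequences of
  100–500 bp under two parameter sets, Misa-mode equivalence uses 1,000
  random 200 bp sequences, orbit invariants cover all primitive 1–6-mers,
  and the scale checks use one annotated 5 Mb fixture plus a 54-genome
  batch of 12 kb fixtures.

## Known limitations

* Substitution-only imperfection model; indel-containing tracts are split
  or truncated rather than aligned through.
* Agreement with any published tool's binary output is validated only
  through the frozen per-accession totals; extension tie-breaking inside
  other tools is undocumented, and residual disagreement would localize to
  the documented choices above (partial-unit counting, containment pruning,
  interruption cap).
* The density statistic is count-based by design; a coverage-based density
  (repeat bp per genome bp) is a different quantity.
* PTT output keeps one table per genome file; per-record tables would be a
  trivial extension but are not what the downstream products consume.
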