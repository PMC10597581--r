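---
title: "Authenticating and placing ancient mitogenomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating and placing ancient mitogenomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomito)
```

## The problem

DNA recovered from mummified and century-old museum specimens is fragmented
(tens of bp), chemically damaged, present in minute amounts, and at constant
risk of contamination by modern DNA or by other specimens handled in the
same collection. The mitochondrial genome (~16.6 kb, circular, maternally
inherited, high copy number) is the marker of choice for such material:
deep geographic structure in many taxa lets a single authentic mitogenome
place a specimen into a geographic clade.

`paleomito` implements the complete desk-scale analysis chain for this
setting:

1. **Quality trimming** of single-end short reads (Trimmomatic-style
   LEADING / TRAILING / SLIDINGWINDOW / MINLEN / AVGQUAL semantics).
2. **Mapping** to small circular references with a seeded, ungapped
   aligner; mapping is repeated independently against several candidate
   reference mitogenomes and the best-supported reference is selected.
3. **Duplicate removal** keyed on mapping coordinates.
4. **Damage profiling**: terminal misincorporation frequencies (the
   post-mortem deamination signature: C→T at 5' ends, G→A at 3' ends),
   plus insertion/deletion tracks.
5. **Consensus calling** with minimum-depth masking and breadth-of-coverage
   QC.
6. **Clade diagnostics**: discovery of clade-diagnostic alignment columns,
   per-site read agreement (median / IQR) as a contamination check, and
   vote-based clade assignment.
7. **Haplotype networks**: haplotype collapsing, minimum spanning networks,
   and a median-joining algorithm for finer geographic resolution.

A synthetic ancient-read generator with complete ground truth drives all of
this at desk scale, so every stage is testable without touching archival
sequencing data.

## The synthetic world

The generator states a world; tests measure the pipeline against it.

**Clade panel.** One random root genome; each clade receives a fixed number
of *planted* substitutions at clade-unique positions (shared by all its
samples); each sample additionally receives private substitutions at a
small per-site rate, never at planted positions. Planted sites are exactly
the inter-clade fixed differences when the private rate is zero, which
gives the round-trip acceptance test its exact expectation. No indels are
simulated, so panel columns coincide with reference coordinates and the
panel is trivially aligned.

**Reads.** Fragment starts are uniform on the circle (fragments may span
the origin; a wrap flag is recorded), strands uniform, lengths log-normal
moment-matched to a mean of 60 bp and SD of 15 bp and truncated to
[30, 150] bp by rejection. The source study reports no fragment-length
distribution for its mummified specimen; the log-normal is a conventional
stand-in for degraded-DNA length distributions, not an inference about any
specimen.

**Damage.** C→T at 5' offset $i$ with probability $d_5 \lambda^i$ and
G→A at 3' offset $i$ with probability $d_3 \lambda^i$. Real damage curves
are empirical; the geometric form is the simplest monotone model matching
their shape, and its parameters ($d_5 = 0.033$, $d_3 = 0.016$ by default,
matching the terminal frequencies reported for a mummified specimen;
$\lambda = 0.5$) are recovered by the profiler within binomial error in the
acceptance suite. Damage is applied before sequencing error (uniform,
$10^{-3}$ per base by default).

**Qualities** are two-level: `qual_high` (37) everywhere, `qual_low` for
damaged or erroneous bases. `qual_low` defaults to 25 — *above* the
end-trimming thresholds (Phred 20) — because a sequencer reads a
deaminated base confidently: if damaged termini were assigned
trimmable qualities, quality trimming would silently erase the very
signature used for authentication, which does not happen with real data.

**Duplicates** are exact copies of an already-emitted read (new id, shared
duplicate-group id), emitted with probability `dup_rate` per read.
**Contamination** pools endogenous and contaminant reads with a binomial
contaminant share.

What the generator deliberately does **not** emulate: indel damage,
paired-end structure, capture-enrichment bias, GC bias, position-dependent
sequencing error, NUMT-like nuclear background. A green test therefore
establishes correctness of the pipeline's logic under the stated model,
not robustness to every artefact of real museum data.

## Numerical and algorithmic choices

**Trimming step order.** The emulated command string lists
`MINLEN:30 SLIDINGWINDOW:4:20 LEADING:20 TRAILING:20 AVGQUAL:30`, and the
tool it names executes steps in command order — so MINLEN runs *first*,
which is unusual. The default here follows that printed order; the order
is configurable. One consequence, verified in the tests: with MINLEN
first, trimming is not idempotent (window truncation can leave a kept
read shorter than 30 bp, which a second pass would discard). Under the
conventional order (SLIDINGWINDOW, LEADING, TRAILING, MINLEN, AVGQUAL)
trimming is exactly idempotent, and the test suite asserts both facts.
Window means use exact arithmetic on integer Phred scores with no
rounding before comparison; only complete windows are scanned, and reads
shorter than the window pass through the window step untouched.

**Mapper.** Exact k-mer seeds (k = 13, non-overlapping plus a 3'-anchored
seed) on both strands; candidate placements are evaluated by ungapped
mismatch counting against the reference linearised with a circular pad, so
origin-spanning placements are plain substring comparisons. A placement is
rejected above a 10% mismatch fraction. There is no MAPQ model; the proxy
for a MAPQ ≥ 30 filter is to retain only `unique_best` placements (best
score at least `min_score_gap` above any alternative) — the same intent,
stringency against nuclear mitochondrial insertions (NUMTs). Gapped
alignments enter the pipeline only via SAM import; the pileup and damage
modules handle M/I/D CIGARs throughout.

**Best reference.** The source study maps "independently to each" candidate
mitogenome and keeps "the best mapping results" without defining *best*.
Here best = greatest number of retained (unique-best, mismatch-filtered)
reads, ties broken by smaller summed edit distance, then lexicographically
by reference id with an explicit tie flag. Reference order never affects
the winner.

**Duplicates.** Key = (reference, start, end, strand); the representative
is the read with the highest summed base quality (ties: smallest read id).
Duplication level = 1 − retained/input.

**Damage profile.** Frequencies are conditional on the source base: the
denominator of C→T at offset $i$ counts reads whose *reference* base at
read-offset $i$ is C. Reverse-strand alignments are complemented and
flipped into read orientation first, so both strands contribute to the
same 5' C→T / 3' G→A signature. (The alternative — frequencies over all
read positions — is not what damage-profiling tools report; percentages in
the emulated study are consistent with conditional rates.) Indel
frequencies use reads covering the offset as denominator and are non-zero
only for imported gapped alignments.

**Consensus.** Plain majority per position; depth below 2 or a tied
majority gives `N`. The study's consensus caller weights by "effective
base depth"; with two-level qualities, quality weighting and plain
majority are near-equivalent, and the exact weighting scheme is not
specified — the approximation is documented rather than guessed at. Ties
produce `N`, not IUPAC codes, because downstream diagnostic logic treats
`N` as missing. Retention requires ≥ 80% of positions at 3× depth.

**Diagnostic sites.** An inter-clade fixed site is a column where every
clade is monomorphic (ignoring `N`/`-`; an all-missing clade contributes
no constraint) and at least two clades differ. Columns with more than 10%
missing characters are excluded — the emulated study is silent on missing
data at diagnostic columns, so this threshold mirrors its 10% sequence
level filter. Query-divergent sites (fixed in a focal clade, different and
determined in the query) anchor agreement on the *query's* base: high
agreement certifies the query's private variant as authentic, low
agreement flags contamination or error. For the 125-site-style analysis
the anchor is the focal clade's base. Both conventions are available; the
per-site base tallies are exported either way.

**Agreement statistics.** Per-site agreement = reads carrying the anchor
base / reads covering the site; the summary is the median and IQR
(Q3 − Q1, linear interpolation, i.e. `quantile(type = 7)`) over covered
sites, with zero-coverage sites excluded and counted. The median is over
*sites*, not reads, matching per-site barplot-style reporting.

**Assignment.** One vote per usable diagnostic site for every clade whose
base equals the query base; strict majority wins; ties fall back to the
smallest p-distance (pairwise deletion) to the clade consensus. This is a
transparent stand-in for tree placement, which is out of scope.

**Median-joining networks.** Haplotypes are collapsed after *network-wide*
masking of any column containing `N` or `-` (complete deletion): pairwise
deletion can violate the triangle inequality, which median-joining
assumes. The minimum spanning network is the union of all minimum
spanning trees, built tier by tier (every edge of the current weight that
joins components distinct at the tier start). Median joining iterates:
build the MSN over the current node set, form the coordinate-wise
strict-majority median of every mutually linked triple, add new vectors,
repeat; a column with three distinct bases contributes no median from that
triple. Finally, inferred vectors not on any shortest path between
observed haplotypes, or with degree < 3, are pruned. `epsilon` (default
0) widens the feasible-link set as in the usual formulation. The exact
internals of the popular desktop implementation are unpublished; these
rules are explicit substitutes, validated against exhaustive
spanning-tree enumeration and hand-computed Steiner cases.

## Reproducibility

Every stochastic component takes an explicit integer seed; a pipeline
run fans one global seed out to per-stage seeds by a stable keyed
derivation, so identical configurations produce byte-identical reports
and output files (verified in the tests). The pipeline report carries a
hash of its configuration.

## Limitations

- The mapper is ungapped by design; real indel-bearing reads must be
  aligned elsewhere and imported as SAM.
- Agreement-based contamination assessment needs diagnostic sites between
  the plausible contaminant and the endogenous clade; contamination from
  the *same* clade is invisible to it (as it is to the emulated analysis).
- The consensus caller does not model heteroplasmy or quality-weighted
  depth.
- Damage profiling reports frequencies; it deliberately implements no
  likelihood-based authenticity test.
- At panel scale the diagnostics are exact; the pipeline is desk-scale by
  intent and has not been profiled against full-size sequencing runs.
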