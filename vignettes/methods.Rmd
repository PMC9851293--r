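---
title: "Detecting fusion circular RNAs and linear fusion transcripts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fusion circular RNAs and linear fusion transcripts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A balanced chromosomal translocation produces two derivative chromosomes.
From a gene pair (gene5, gene3) the *direct* derivative expresses a chimeric
transcript joining gene5 exons 1..p to gene3 exons q..n, and the
*reciprocal* derivative (when expressed) joins gene3 exons 1..s to gene5
exons r..m. Besides the linear chimeric mRNAs, the derivative loci can
produce *fusion circular RNAs* (f-circRNAs): backsplicing on a chimeric
transcript joins a downstream splice donor back to an upstream splice
acceptor, yielding a circle whose backsplice junction joins exons of the two
partner genes. Reads spanning either chimeric junction fail linear alignment
to the reference genome; this package detects and classifies them starting
from that linearly unmapped read set.

`fcircdetect` implements the full workflow: chimeric reference
construction, split-read alignment, junction classification,
quantification/reporting, plus a synthetic read simulator and a
benchmarking harness that scores the detector against ground truth.

## Chimeric reference construction

For each translocation gene pair, every transcript-collapsed exon of the 5'
partner is concatenated with every exon of the 3' partner (the *direct*
gene order), and the gene order is also inverted (*reciprocal*): `2 * m * n`
references in total, each annotated with its internal junction offset.
Exon models are the interval union over all annotated transcripts of a
gene, numbered 1..m in transcription order; coordinates are 0-based
half-open internally, converted from the 1-based GTF on input.

The key structural observation is that **backsplice reads never need a
special alignment mode**: a read spanning the backsplice of, say, the
reciprocal derivative (suffix of gene5 exon i followed by the start of
gene3 exon j) aligns *linearly* across the junction of the direct-order
reference `gene5_i + gene3_j`, which is always present in the combinatorial
set. Circles versus linear fusions are therefore distinguished by
classification, not by alignment.

## Split alignment

Each read (both orientations) is placed end-to-end as two contiguous
ungapped segments: segment A ends at or before the reference junction,
segment B starts at or after it. The aligner maximizes
`score = matches − mismatches` over all references, orientations, split
points and segment offsets. Ties are broken deterministically (more
matches, lexicographically smallest reference id, forward orientation).

* Candidate placements are found by exact k-mer seeding (`seed_len`,
  default 15 nt): each shared k-mer proposes one diagonal, and the optimum
  over all compatible diagonal pairs and split points is computed exactly
  from per-diagonal prefix-match profiles. For total reference size below
  `exhaustive_below` (default 20 kb) every valid diagonal is enumerated
  instead, which makes the search provably exhaustive; the test suite pins
  the seeded path to the exhaustive path on error-free junction reads and
  the exhaustive path to an independent brute-force oracle.
* Segments are ungapped and cover the whole read; indel tolerance is
  delegated to the mismatch budget. This is a documented simplification:
  the bundled simulations are error-free, and on real data short clips
  would be absorbed as mismatches.
* `N` bases count as mismatches (conservative).
* A read whose best score is attained on references of two *different* gene
  pairs is flagged ambiguous and dropped (paralog guard). Mates of a
  fragment are aligned independently and deduplicated by read-id stem
  during aggregation.

Junction-quality filters, applied after alignment (so the tuning sweep can
re-filter stored alignments): total aligned length at least
`min_total_aligned` (50 nt), each junction-side overlap at least
`min_overlap` (5 nt), at least `min_matches` (5) matching bases in the
shorter segment, and at most `max_mismatch_frac` (0.17) mismatches over the
alignment. The first failing criterion is reported as a reason code.

## Classification

For a gene pair with declared direct breakpoints (p, q) and reciprocal
breakpoints (s, r) — several per pair are allowed; the compatibility
envelope uses `p_max`, `q_min`, `r_min`, `s_max` — a read crossing the
junction of a direct-order reference `gene5_i + gene3_j` is classified:

1. **fusion** (direct derivative) if (i, j) equals a declared (p, q);
2. **alternative fusion** (direct) if `i <= p_max` and `j >= q_min`;
3. **f-circRNA** (reciprocal derivative) if `i >= r_min` and `j <= s_max` —
   the read spans a backsplice joining gene5 exon i back to gene3 exon j on
   the reciprocal derivative;
4. **ambiguous** otherwise (reported read-level, excluded from calls).

Reciprocal-order references are handled symmetrically with (s, r) in the
role of (p, q). Whenever `r_min > p_max` and `s_max < q_min` — which holds
for every context derived from a balanced translocation, where the
reciprocal junction is adjacent to the direct one — the linear and
backsplice regions are provably disjoint; the test suite checks this
exhaustively on exon grids up to 40 × 40. If a user supplies overlapping
bounds the rules are applied in the order above.

Three breakpoint input modes are supported. With breakpoints for both
derivatives they are used as given. With only the direct breakpoints the
reciprocal junction is inferred per breakpoint as `r = p + 1`,
`s = q − 1` (a side is disabled when the inferred exon falls outside the
gene, e.g. `q = 1`). With only a gene pair (*discovery mode*, including
scans of a known-fusions catalogue) classification is two-pass: every
junction-crossing read is a candidate; the single most-supported junction
over both gene orders is promoted to putative breakpoint (ties: higher
count, smaller exon-number sum, lexicographic), the context is rebuilt with
the adjacency inference, and all reads are re-classified, so candidates
compatible with a backsplice of the promoted junction become f-circRNAs.
Promoting one junction overall (rather than one per gene order) is a
deliberate choice: promoting both orders independently would turn every
backsplice-supported junction into a spurious "fusion" of the other
derivative. Newly discovered junctions are best confirmed by re-running
with the discovered breakpoints declared.

Names follow the donor–acceptor convention with gene initials: `K9-A4` for
a linear fusion, `f-circK10-A2` for a circle backsplicing exon 10 of the
5' partner to exon 2 of the 3' partner.

## Quantification and reports

Calls aggregate evidence per (gene pair, derivative, class, exon pair),
counting distinct fragments. Junction coordinates are strand-aware: donor =
last transcribed base of the upstream exon, acceptor = first transcribed
base of the downstream exon (backsplice donor/acceptor for f-circRNAs);
CSV positions are 1-based, BED output 0-based half-open. Support is also
reported as NR, the count normalized over 10 million input reads
(`n / total * 1e7`, 2 decimals); the denominator defaults to the number of
input reads and should be set to the upstream count of linearly unmapped
reads when only a subset is supplied. Reports (call-level CSV, read-level
CSV, per-translocation text summaries, BED junctions, JSON summary) are
deterministically ordered and byte-stable.

## The synthetic benchmark

`simulate_scenario()` generates the evaluation conditions as first-class,
tested code:

* four scenario kinds — `single_breakpoint` (4 gene pairs),
  `reciprocal` (4), `multiple_breakpoints` (4, two direct breakpoints per
  pair with their adjacent reciprocal junctions), `paralog` (6, each
  partner accompanied by a decoy copy at 5% per-base divergence);
* junction styles `annotated` (fusion breakpoints at exon boundaries) and
  `not_annotated` (breakpoints in the middle of the fused exons; backsplice
  junctions always sit at annotated splice sites since backsplicing uses
  them);
* error-free reads of 100 and 150 nt; per-junction coverage 4x for fusion,
  2x for alternative-fusion, 2x for backsplice reads, placed by uniform
  tiling of the split point over [0.2, 0.8] of the read (exact expected
  counts, deterministic truth); alternate reads are reverse-complemented;
* synthetic genes of 7–9 exons, exon lengths 260–400 nt (long enough that
  every tiled read fits both flanks in either junction style), introns
  80–200 nt, genes on either strand;
* alternative-fusion junctions use adjacent exon shifts of the declared
  breakpoint (p − 1), the natural model for a nearby second breakpoint;
* a background of non-fusion reads: fragments of separate background
  transcript models plus uniform-random sequence; paralog scenarios add
  decoy fragments (exon-interior and unspliced exon/intron boundary reads).
  Ordinary splice-junction reads of a decoy are *not* simulated because
  they align linearly upstream and would never reach this tool's input.

Every junction read carries one truth record; background and decoy reads
carry none. A property test verifies that no background read contains a
seed-length junction context in either orientation.

What the generator does **not** emulate: sequencing errors and quality
scores, insert-size structure, real exon-length and homology distributions,
and — most importantly — the homology structure of a real linearly
unmapped background, which in real samples contributes false-positive
pressure that random sequence cannot. Passing benchmarks here therefore
demonstrate correctness of the mechanics (alignment optimality,
classification rules, bookkeeping) rather than real-data precision.

## Evaluation

Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
`F1 = 2PR/(P+R)` (zero-denominator conventions: each quantity is 0 when
its denominator is 0) are computed at two levels: *read* level (a true
positive is a predicted read present in truth with matching gene pair and
class) and *junction* level (exact exon-pair identity, no coordinate
tolerance — references are exon-resolved, so coordinate slack would be
artificial). Both are reported everywhere; the headline benchmark numbers
use the read level, the unit in which the simulation truth is defined and
in which correctly identified fusion reads are counted. Junction-level
metrics are stricter on false positives (a single spurious read creates a
whole spurious junction against a small number of true junctions) and are
the right lens for call-level comparisons.

`run_benchmark()` simulates all 16 battery configurations (4 kinds × 2
junction styles × 2 read lengths), each with 10,000 background reads, runs
detection at default parameters and scores every configuration (combined
and per transcript kind, both levels). `parameter_sweep()` re-filters the
stored alignments over the 60-combination tuning grid (minimum junction
overlap 1–10, 15, 20 nt × minimum matches 4, 5, 10, 15, 20) pooled over the
battery; recall is monotone non-increasing along both axes by construction.
The battery sizes (a few hundred junction reads plus 160,000 background
reads in total) were chosen so a full benchmark plus sweep completes in a
few minutes on one CPU while every scenario kind and style is exercised.

## Numerical and design choices

* All randomness flows through explicit integer seeds; each battery
  configuration derives a sub-seed, so configurations are independent and
  reproducible individually.
* Alignment tie-breaks, discovery-mode promotion tie-breaks, call sorting
  and report ordering are all total orders: identical inputs give
  byte-identical outputs.
* The minimum-matches filter applies to the shorter junction-side segment
  (with equal overlaps, the smaller match count), the reading most
  consistent with applying the thresholds "at the size of the shorter
  overlap".
* Reads shorter than `2 * min_overlap` are rejected with a status rather
  than an error; empty evidence produces an explicit zero-fusion report.

## Known limitations

* No indel handling within segments; no soft-clipping (whole-read
  placement); spliced alignments across more than two segments are out of
  scope.
* Genomic (intronic) breakpoints are reported at exon resolution only.
* f-circRNAs whose backsplice joins two exons of the same gene but whose
  circle contains the fusion junction are indistinguishable from linear
  fusion reads at the junction level and are not called.
* Discovery mode promotes a single dominant junction per gene pair; minor
  concurrent breakpoints surface as alternative fusions and need a
  follow-up run with declared breakpoints.
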