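---
title: "Methods: predicting and analysing HERV-mediated NAHR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting and analysing HERV-mediated NAHR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hervnahr)
```

## The model

Non-allelic homologous recombination (NAHR) between two paralogous sequences
on one chromosome deletes (or, in the reciprocal product, duplicates) the
segment between them. The classical substrate is a pair of directly oriented
low-copy repeats; this package screens for an analogous substrate made of
human endogenous retrovirus (HERV) elements. A qualifying pair must offer
the recombination machinery what any NAHR substrate offers: co-orientation,
proximity on the scale of viable CNVs, and long, high-identity homology.

The screen's tunable parameters, their defaults, and the reasoning:

| parameter | default | why |
|---|---|---|
| `min_length` | 4,000 bp | full-length-like elements; fragments shorter than this rarely contain the long internal homology NAHR needs |
| `min_sep`, `max_sep` | 10 kb, 10 Mb | below 10 kb a CNV is unlikely to be array-detectable and candidate counts explode; above 10 Mb a CNV is presumed too deleterious to observe |
| `min_identity` | 0.94 | matches the identity conventions used for segmental-duplication (LCR) NAHR substrate maps |
| `min_aln_length` | 2,000 bp | excludes pairs whose only high-identity alignment is between their ~450-bp LTRs |
| `max_join_gap` | 5,000 bp | RepeatMasker splits one interrupted element into fragments sharing a join id; gaps up to a few kb are nested insertions, larger gaps indicate distinct elements. The joined-fragment track's own tolerance is not published; this default is a package decision and is configurable |
| LCR exclusion | identity > 0.94, copies 5 kb–10 Mb apart, direct orientation | pairs overlapping such segmental duplications are classical NAHR substrates already; excluding them keeps predictions HERV-specific |

Separation is measured between inner edges (end of the proximal element to
start of the distal one) — the reading of "distance between elements" that
corresponds to the deletable segment; the alternative outer-edge and
start-to-start conventions differ only by element lengths and are not
exposed.

## Alignment conventions

Pairs are aligned with the Smith–Waterman local algorithm via
`Biostrings::pairwiseAlignment` — the same engine named by the original
screening protocol — under match +1, mismatch −1, gap open −10, gap
extension −25. Only the gap-extension penalty is fixed by that protocol;
the others are declared defaults, recorded in every output header. Identity
is the fraction of identical columns over *all* alignment columns (gap
columns count against identity); this is the conservative reading of
"identical positions over aligned positions", and a gap-excluded mode is
available (`alignment_identity(aln, gap_excluded = TRUE)`). `N` mismatches
every base, including `N`.

Two numerical notes. First, tie-breaking among equal-scoring alignments is
the engine's deterministic traceback; for weak optima on unrelated sequence
multiple co-optimal alignments with different identities exist, so tests
that require exact identity agreement with the independent
dynamic-programming oracle use fixtures with a planted homologous segment,
where the optimum is unique. Second, with gap penalties this heavy the
optimal alignment of two sequences whose true history contains two nearby
opposite-sense indels runs *through* them as a mismatch block rather than
opening two gaps; the synthetic generator spaces indel events ≥ 150 bp
apart so that the planted alignment is also the score optimum (see below).

Internally all coordinates are 1-based inclusive, the Bioconductor
convention used by the IRanges/GenomicRanges machinery backing the interval
operations; UCSC rmsk and BED files (0-based half-open starts) are
converted at the I/O boundary, bijectively, and every report is 1-based.

## Breakpoint mapping

The two elements of a pair differ at scattered *cis*-morphisms (paralogous
sequence variants): substitutions and short indels, each indel run counted
as one event anchored at its first affected base. A junction read across a
CNV breakpoint follows the proximal element (A), switches template at the
crossover, and continues as the distal element (B). `map_junction` aligns
the read to each element, calls the read's allele at every cis-morphism,
and bounds the crossover by the last A-allele and first B-allele
cis-morphism. The four reported bounds are

* `start_max`, `start_min`: the A-side (proximal) coordinates of those two
  cis-morphisms — the maximal and minimal extent of the rearranged segment's
  start;
* `stop_min`, `stop_max`: their B-side (distal) coordinates.

The uncertainty widths are `start_min − start_max` and
`stop_max − stop_min`; the CNV size is `stop_min − start_min`, the minimal
rearranged segment — the one size convention that reproduces all four
published locus sizes from the published bounds (outer-coordinate spans do
not). Reported coordinates use the outer span `chrom:start_max-stop_max`.

A cis-morphism is *informative* only where the read covers it
unambiguously. Substitution alleles are read directly off the aligned base.
Indel alleles are called from the presence or absence of the inserted bases
in a small window around the event, because a local aligner may shift a gap
by a few bases inside repetitive context; a window holding no junction gap
means the insertion is present, a window holding at least the event length
of gap means it is absent, and anything else is flagged ambiguous and
skipped — never used as a bound. Reads matching one element throughout
raise a "no crossover" error; alleles that interleave (A after B) raise a
"possible complex event" error rather than a fabricated interval.

## The clustering test

At a locus with `n` observed breakpoints, the statistic is the median of
the `choose(n, 2)` pairwise distances between the breakpoints' proximal
cis-morphisms. The null conditions on local homology: candidate positions
are alignment columns whose 50-bp windowed identity is at least the minimum
observed at the real breakpoints, `n` positions are drawn uniformly without
replacement, each is mapped to the nearest cis-morphism at or upstream of
it ("next most proximal"; positions upstream of the first cis-morphism are
excluded from sampling), and the statistic is recomputed; 10,000 such sets
form the empirical distribution by default. Clustering means a *small*
median distance, so the p-value is lower-tail, with the standard add-one
correction `(1 + #{null ≤ obs}) / (1 + n_sets)` — never zero. The RNG seed
is a required argument and is logged in the result.

The published per-locus p-values (4.4 × 10⁻³ at 11q24, 0.028 at 1q41,
0.032 at 2p12, 2.3 × 10⁻⁴ at 3q13.2q13.31) derive from hg19 sequence and
are not reproduced by the offline test suite; moreover 2.3 × 10⁻⁴ is not an
integer multiple of 1/10,000, so the original p-value convention (add-one
or not) cannot be inferred — the convention here is simply documented. What
the suite *does* establish is calibration: under uniform placement on
eligible positions the rejection rate at α = 0.05 is 0.05 ± 0.01 (1,000
replicates of 1,000 sets), and planted tight clusters give p < 0.01.

## Hotspot-motif analysis

The PRDM9 recombination-hotspot motif is the degenerate 13-mer
`CCNCCNTNNCCNC`. No published weight matrix accompanies it, so the PWM
construction is a declared convention: each column gives probability 0.85
to the specified base (split across the allowed bases for degenerate codes,
uniform for `N`), the remainder split over the others; weights are log-odds
against a uniform background, then shifted per column so the minimum
achievable score is 0 — this makes "fraction of the maximum possible score"
well-defined. A hit is a window scoring strictly above 85% of the maximum,
on either strand; windows containing `N` are skipped; overlapping hits all
count. With 8 specified columns the 0.85 threshold admits at most one
specified-base mismatch, giving an analytic background rate of
`2 · P(X ≥ 7), X ~ Bin(8, ¼)` ≈ 7.6 × 10⁻⁴ per base on uniform sequence,
which the tests verify empirically.

Two enrichment statistics are provided. Breakpoint clusters (± 500 bp,
clipped and merged) are tested with a one-sided exact Poisson test of the
observed hit count against `background_rate × interrogated length`, the
background rate coming from length-matched sequences sampled uniformly from
the genome. Per-element motif densities (hits/kb) are compared either
one-sample against a scalar genome-wide average (Wilcoxon signed rank) or
two-sample against a reference element set (rank sum). The one-sample exact
signed-rank p for 12 elements is bounded below by 1/4096 ≈ 2.4 × 10⁻⁴,
which is *above* the published 1.9 × 10⁻⁴ for that comparison — the
original analysis evidently used the normal approximation; both exact and
approximate modes are exposed (`exact =`) without presuming which to match.

## The synthetic world

`make_genome` plants element pairs with known truth so that every stage has
a recovery test. What it emulates: the element architecture (two identical
~450-bp LTRs flanking an internal sequence carrying a large env-like
deletion — the structure shared by CNV-mediating elements), pairs at
configurable divergence and separation on either strand, RepeatMasker-style
fragmented annotations sharing a join id, recombinant junctions switching
template at a chosen alignment column, probe grids whose uncertainty
intervals bracket planted CNV breakpoints by construction, and planted
hotspot-motif copies.

Generator decisions, fixed once:

* **Divergence is an alignment-column budget.** A pair at divergence *d*
  differs at `round(d · L)` alignment columns, 10% of the budget spent on
  indel columns (geometric lengths, mean 2 — the mixed substitution/indel
  landscape real element pairs show), the rest on substitutions placed
  uniformly. Planted identity is therefore `1 − d` by construction, which
  is what "a pair planted at 94.5% identity" must mean for threshold-
  boundary recovery tests to be meaningful.
* **Indel events are spaced ≥ 150 bp apart.** Under the −10/−25 gap
  penalties, a score-optimal aligner converts two opposite-sense indels
  closer than ~80 bp into a mismatch run, which would silently lower
  realized identity ~0.5–1 point below target; the spacing guarantees the
  planted alignment is the score optimum.
* Background base composition is uniform 25% (configurable) — a neutral
  null for motif-rate calibration; one pair per synthetic chromosome keeps
  candidate enumeration equal to planted truth.

What the generator does **not** emulate: hg19 base composition and repeat
context, retroviral phylogeny (pairs are independent draws, so cross-pair
identity is background-level), assembly gaps, or multi-pair chromosomes
with interleaved elements. A green recovery test therefore establishes the
correctness of the screening logic and statistics at desk scale, not the
genome-scale figures (170 pairs, 70 regions, 12.1% coverage), which require
the real rmsk/segdup/FASTA inputs and are supported by `run_pipeline` but
not asserted offline — the under-specified fragment-joining gap and
alignment defaults make only approximate agreement expectable there.

## Other design decisions

* **CNV input dialect**: calls arrive as a TSV of four probe-bound
  coordinates per call (`start_max ≤ start_min ≤ stop_min ≤ stop_max`),
  mirroring the published table structure, rather than as raw aCGH data —
  segmentation is out of scope. Matching is *strict* by default when a pair
  table is supplied (the proximal and distal elements must form an emitted
  pair); lenient any-element matching is the fallback when no pair table is
  given, since which convention the original cross-reference used is
  ambiguous.
* **Probe placement**: five probes immediately outside each element edge,
  stepping outward, skipping repeat-masked positions; a side with no room
  within a 10-kb search window (or at a contig edge) is reported
  unplaceable rather than erroring — a testable operationalization of
  elements that "could not be targeted because of genome structure".
* **Pipeline configuration is JSON** (jsonlite), not YAML — no YAML parser
  is guaranteed in the runtime environment; every output carries package
  version, parameters and input MD5 checksums, and contains no timestamps,
  so identical configurations give byte-identical outputs.

## Known limitations

* Minus-strand pairs are aligned and reported in forward-genome
  coordinates; junction reads are assumed to be supplied in forward
  orientation.
* `map_junction` assumes a single template switch; genuine complex events
  (A→B→A) are detected and refused, not modelled.
* The screen aligns every candidate pair; on genome-scale inputs enable the
  `same_family_only` pre-screen to bound runtime (cross-family alignments
  essentially never reach 94%/2 kb).
* Monte-Carlo p-values are bounded below by `1/(n_sets + 1)`; published
  values smaller than that at a given `n_sets` cannot be matched exactly by
  construction.
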