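---
title: "Methods: binding-site annotation, shuffle-null enrichment and expression integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-site annotation, shuffle-null enrichment and expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifmap)
```

This vignette documents the statistical procedures implemented in
**hifmap**, the conventions adopted where the underlying methods admit more
than one reasonable choice, what the synthetic-data generator does and does
not emulate, and the package's known limitations.

## The problem

A CUT&RUN or ChIP experiment for a transcription factor — the motivating
case is HIF1α, the oxygen-labile subunit of hypoxia-inducible factor 1,
activated in cell culture with the prolyl-hydroxylase inhibitor DMOG —
yields a set of genomic intervals (peaks) where the factor was bound. On
their own those intervals say nothing about regulation. The questions this
package answers are:

1. Are the peaks placed non-randomly with respect to gene anatomy
   (promoters, gene bodies, distance to transcription start sites) and
   chromatin accessibility?
2. Is binding associated with transcriptional response, overall and as a
   function of binding distance?
3. Which genes pass a defensible "dependent target" rule?

## Coordinate and annotation conventions

All coordinates are 0-based half-open (BED convention) internally; GTF
input is converted on read. One consistent convention removes the largest
single source of off-by-one drift in this kind of pipeline.

**Peak reference point.** Distances are measured from a single point per
peak: the narrowPeak summit (column 10, when non-negative) or else the
integer midpoint `floor((start + end)/2)`. The summit is the better
estimate of the protein–DNA contact for high-resolution assays, so it is
the default; the choice is recorded in the pipeline metadata so results
are auditable, and midpoint-only input simply falls back to the midpoint
rule.

**TSS.** For a `+` gene the TSS is `gene_start`; for a `-` gene it is
`gene_end − 1`, the last base of the half-open span.

**Nearest-gene assignment.** Each peak is assigned to the gene with
minimal `|ref_point − tss|` among genes on the same chromosome, by a
sorted-TSS binary search. Exactly equidistant candidates (including
distinct genes sharing a TSS coordinate) resolve to the lexicographically
smallest `gene_id` — an arbitrary but deterministic rule, which is what
matters for reproducibility; the tests verify equivalence against an
all-pairs brute-force scan. Peaks on chromosomes with no annotated gene
get an infinite distance, are excluded from distance-bin counts, and are
reported in the log. The signed distance is orientation-corrected so that
positive means downstream of the TSS in the direction of transcription.

**Distance bins** are 0–3 kb, 3–10 kb, 10–100 kb and >100 kb with upper
edges closed (`d = 3000` falls in 0–3 kb). Edge handling is not dictated
by the method itself; the closed-upper convention is declared in the
output metadata and used consistently everywhere, including the generator.

**Feature classes** are mutually exclusive with promoter precedence:
promoter if the reference point is within 3 kb of any TSS, else gene body
if it falls inside any gene span, else intergenic. Promoter precedence is
what makes the three percentages a partition of the peak set.

**Open chromatin.** A peak overlaps open chromatin when its full interval
shares at least 1 bp with an accessibility region (half-open semantics, so
`[100,200)` and `[200,300)` do not overlap). The alternative rule — the
reference point itself inside a region — is available as
`mode = "summit"`; any-overlap is the standard intersection semantics of
interval tools and the default.

## The shuffle null

Enrichment questions need a reference distribution. The package uses a
random-placement null that preserves each interval's length exactly:
chromosome drawn with probability proportional to its length (restricted
to chromosomes that can hold the interval), start uniform on
`[0, chrom_len − len]`, replicate sets independent given the seed.
Shuffled intervals may overlap each other and there is no exclusion list —
this mirrors the default behavior of the standard interval shuffler and
keeps the null model interpretable.

The number of replicates defaults to 100. A single draw reproduces the
classical one-shot procedure; averaging over replicates stabilizes the
expected counts `E` and is cheap at these scales. If a category is
unreachable on the given genome (for example >100 kb distances when TSSs
tile the genome densely), its expectation is 0 in every replicate; such
jointly-empty categories are dropped from the tests rather than producing
a 0/0 statistic, and an observed count with zero expectation raises an
error directing the user to increase replicates.

Per category the package reports:

* **rpd**, the relative percentage difference `100·(O − E)/E`. An
  alternative reading (difference of percentage points of the two
  distributions) would change only the axis scale, not signs or ranks; the
  formula used is written into the output metadata.
* A **goodness-of-fit χ²** across categories, `Σ (O − E′)²/E′` with `E′`
  rescaled so `ΣE′ = ΣO`, hence `df = k − 1` even when replicates drop
  unannotatable intervals. No Yates correction is applied for k-category
  GOF tests.
* Per-category 1-df χ² on the in/out split, Bonferroni-corrected over the
  categories tested (8 cells for the joint distance × accessibility
  table).

## Expression integration

Differential-expression calls use `|log2FC| > 0.6` and `p < 0.05` by
default (both configurable; a stricter 0.7 threshold is a common variant
and simply a parameter here). The DE table is an *input*: the package
deliberately does not fit count models.

"Bound gene" means *nearest-neighbor* of at least one peak — the
assignment direction is peak → gene, so a gene bound at 2 kb and 50 kb
carries both stratum flags, while the *stratified* association tests use
exclusive strata keyed to the gene's minimal assigned distance (≤3 kb,
3–10 kb, 10–100 kb) so that the per-stratum counts partition the bound
genes. A window-based alternative ("any peak within X kb") is a different
question — it inflates bound fractions near gene-dense regions — and is
intentionally not the default.

The 2×2 association tests are Pearson χ² without continuity correction
(df = 1); with counts of the magnitude this pipeline produces the
correction changes nothing of interest, and the flag `correct = TRUE` is
available. Degenerate tables (a zero margin) raise an error naming the
margin instead of returning NaN. The tests compare the χ² p-value against
a doubled one-sided hypergeometric mid-p, which is the exact quantity the
Pearson statistic approximates.

Fold-change magnitudes (|log2FC|, bound vs unbound) are compared with a
two-sided Mann–Whitney U. For groups of at most 8 the p-value is computed
by complete enumeration of all label assignments of the pooled sample —
correct under ties, and verified in the tests against an independent
permutation oracle; larger samples use the normal approximation with tie
correction.

**Target rule.** A dependent target is a DEG with at least one assigned
binding site within 100 kb of its TSS. The 100-kb window is the
conventional upper bound for which distance-stratified association remains
detectable; it is a parameter (`target_window`), not a constant. Against
an optional known-hypoxia symbol list, matching is exact and
case-insensitive — no ortholog mapping is attempted.

## Motif check

The consensus scan counts occurrences of an IUPAC pattern (default
`RCGTG`, the hypoxia-response element core; `ACGTG` is a one-character
config change) in peak sequence, both strands, overlapping matches
counted, `N` never matching a non-`N` symbol. Enrichment is matches/kb
against the same shuffle null with an add-one empirical p-value, whose
floor is `1/(R + 1)`. This is a validation aid, not motif discovery: no
position-weight matrices, no background Markov model, no E-values.

## The synthetic-data generator

`simulate_dataset()` emits a genome, non-overlapping genes (uniform
placement via stick-breaking over the free space), fixed-length
open-chromatin regions (a configurable fraction centered on TSSs, the rest
uniform), peaks, an expression table, a known-hypoxia list and the ground
truth, all as plain-text standard formats, byte-identical under a fixed
seed.

Planted structure, chosen to mirror the qualitative findings the pipeline
is meant to detect:

* a peak is promoter-proximal (uniform within ±3 kb of a random TSS) with
  probability `p_peak_promoter` (default 0.3), otherwise inside a random
  open region with probability `p_peak_open` (0.3), otherwise uniform;
* genes whose minimal nearest-neighbor binding distance is ≤3 kb are
  planted upregulated with probability 0.5; genes bound at 3–10 kb planted
  downregulated with probability 0.4; all others differentially expressed
  (random direction) at a 0.03 baseline;
* planted DE genes draw `|log2FC| ~ N(1.5, 0.2)` and `p ~ Beta(0.02, 1)`;
  others draw `log2FC ~ N(0, 0.2)` and `p ~ U(0, 1)`.

The Beta shape 0.02 makes `P(p < 0.05) ≈ 0.94` for a planted DE gene, so
that planted effects survive the DEG thresholds at a rate compatible with
the ≥90% recovery the validation suite demands; a flatter draw such as
Beta(0.1, 1) would silently misclassify a quarter of the planted genes at
`α = 0.05` and recovery statements would measure the p-value generator,
not the pipeline. This is a property of the simulation design, decided
analytically from the thresholds before any data were generated.

Default scale is 4 × 10 Mb chromosomes, 2000 genes, 1500 peaks — small
enough to run the full pipeline in seconds, large enough that every
stratum is well populated. The generator does **not** emulate: read-level
noise or peak-calling artifacts, GC/mappability structure, realistic gene
length and spacing distributions, correlated replicate structure, or count
-based DE inference. Passing the planted-recovery suite therefore
demonstrates that the statistics detect the effects they are meant to
detect at realistic desk-scale magnitudes — not that any particular real
genome would give the same numbers.

## Validation strategy and problem sizes

The test suite favors oracle equivalence over spot values: nearest-TSS
against an all-pairs scan, overlap flags against an O(n·m) loop, IUPAC
matching against a position-by-position matcher, exact Mann–Whitney
against full permutation enumeration, χ² against term-by-term summation —
each across multiple seeded random fixtures. Calibration checks run the
pipeline under its own null: peaks drawn from the shuffle null keep the
GOF rejection rate at the nominal level (200 seeded runs, three-bin design
with evenly spaced TSSs so every bin has adequate expectation), and
expression simulated independently of binding keeps the 2×2 rejection
rate near 0.05 (200 redraws over a fixed gene/peak layout of 800 genes and
150 peaks). Planted-effect recovery runs 20 full simulations at the
generator defaults and requires each headline signal — promoter-bin
enrichment, open-chromatin association, proximal-binding→up and
3–10 kb→down — in at least 18 of 20. These sizes were chosen so the whole
suite completes in a few minutes on one core while keeping every binomial
check's Monte-Carlo error well inside its acceptance band.

## Known limitations

* The null is placement-only: no GC-, mappability- or blacklist-matched
  controls, so on real genomes enrichment against this null conflates
  biological signal with sequence composition effects to the same degree
  the classical one-shot shuffle does.
* Nearest-neighbor assignment is a heuristic for regulatory linkage;
  enhancer–promoter maps or chromatin conformation data would reassign
  some distal peaks.
* Gene-level only: no transcript models, no alternative TSSs per gene.
* The motif module validates a consensus; it is not a substitute for
  de novo discovery.
* χ² p-values at genome scale are reported as computed; for observed
  tables derived from a single null draw, only directionality and
  significance structure are expected to reproduce across reruns, not
  p-value magnitudes.
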