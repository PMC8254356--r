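# hifmap

Genome-wide integration of transcription-factor binding sites with gene
annotation, chromatin accessibility and differential expression, at desk
scale and fully seeded.

The package targets the common regulatory-genomics question: given a set of
binding sites for an oxygen-regulated factor such as HIF1α (from CUT&RUN or
ChIP peak calls), which genes does the factor plausibly regulate, and is its
binding pattern distinguishable from chance? It is written for analysts who
already have processed peak calls, an open-chromatin BED and a
differential-expression table, and want the downstream integration —
peak-to-gene assignment, null-model enrichment and binding–expression
association — as reproducible, tested functions rather than one-off scripts.

## What it computes

* **Peak annotation.** Each peak's reference point (narrowPeak summit when
  available, else the midpoint) is assigned to the gene with the nearest
  transcription start site (TSS) on its chromosome. Distances *d* are binned
  0–3 kb, 3–10 kb, 10–100 kb, >100 kb (upper edges closed), and each peak is
  classified promoter (*d* ≤ 3 kb to any TSS), gene body (reference point
  inside a gene span) or intergenic, plus an open-chromatin overlap flag
  (≥ 1 bp intersection with an accessibility region).
* **Shuffle null.** Intervals are re-placed uniformly at random
  (chromosome drawn ∝ length, start uniform, lengths preserved) in *R*
  replicates. For every category the enrichment is reported as the relative
  percentage difference rpd = 100·(O − E)/E, with a χ² goodness-of-fit test
  against the null distribution (expectations rescaled to the observed
  total, df = k − 1), per-category 1-df tests, and Bonferroni correction.
* **Expression integration.** Genes are called up/down/non using
  |log2FC| > 0.6 and p < 0.05 (configurable). Binding–DEG association is a
  Pearson 2×2 χ² (df = 1, no continuity correction by default), overall and
  per exclusive distance stratum (≤3 kb, 3–10 kb, 10–100 kb, keyed to each
  gene's minimal assigned-peak distance). Fold-change magnitudes of bound vs
  unbound genes are compared with a two-sided Mann–Whitney U (exact
  enumeration for small groups). A gene is a *dependent target* when it is a
  DEG with at least one assigned site within 100 kb of its TSS; targets can
  be split into known vs novel against a hypoxia gene list.
* **Motif check.** Occurrences of an IUPAC consensus (default the
  hypoxia-response element core `RCGTG`, both strands, overlaps counted) per
  kb of peak sequence, against the same shuffle null, with an
  add-one-corrected empirical p-value.
* **Synthetic data.** A seeded generator emits a toy genome, genes, ATAC
  regions, peaks and an expression table with *planted* structure
  (promoter-biased peaks, accessibility-biased peaks, proximal-binding →
  upregulation, 3–10 kb binding → downregulation), so every stage can be
  validated end to end without any external download.

## Worked example

```r
library(hifmap)
cfg <- sim_config(seed = 42, n_chroms = 2, chrom_length = 1.5e6,
                  n_genes = 150, n_peaks = 200)
d <- simulate_dataset(cfg)
s <- run_pipeline(d$peaks, d$genome, d$genes, d$expression,
                  atac = d$atac, hypoxia = d$hypoxia_genes,
                  out_dir = "run42", seed = 42, n_shuffles = 30)
print(s)
```

prints (abridged):

```
## Distance enrichment vs shuffle null
  category            observed    expected       rpd       p_adj
  0-3kb                    129       56.27    129.3%    8.12e-30
  3-10kb                    39       74.77    -47.8%    5.16e-07
  10-100kb                  32       68.97    -53.6%    1.14e-07

## Distance x accessibility enrichment
  category            observed    expected       rpd       p_adj
  0-3kb:open                56       13.13    326.4%    1.18e-33
  3-10kb:closed             33       68.90    -52.1%    5.52e-07
  ...

## Differential expression
  up 47 | down 9 | non 94
  DEG bound 98.2% vs non-DEG 58.5% (chi2 p = 1.04e-07)

## Targets
  activated 46 + repressed 9 = 55 dependent targets
  known hypoxia 22 | novel 33
```

Reading it: 129 of 200 peaks sit within 3 kb of a TSS versus 56.3 expected
if the same intervals were placed at random — a +129% relative difference,
significant after Bonferroni correction — and binding is strongly skewed
toward open chromatin near TSSs. Downstream, 98.2% of differentially
expressed genes are nearest neighbors of a peak versus 58.5% of unchanged
genes, and 55 genes pass the dependent-target rule (DEG with a site within
100 kb), 22 of which are on the supplied known-hypoxia list. Because the
dataset was simulated with planted effects, these are exactly the signals
the generator put in.

The same pipeline runs from files (`BED`/`narrowPeak`, `chrom.sizes`,
GTF or a 5-column gene TSV, expression TSV) either through `run_pipeline()`
or the thin command-line front-end in `inst/scripts/hifmap`
(`simulate` / `run` / `report` subcommands).

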