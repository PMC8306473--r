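---
title: "Inferring OPC-microglia ligand-receptor crosstalk from bulk RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring OPC-microglia ligand-receptor crosstalk from bulk RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkLR)
```

## The problem

Oligodendrocyte precursor cells (OPCs) exposed to an inflammatory cytokine
cocktail (TNF/IFN&gamma;/IL1&beta;) up-regulate chemokines and growth
factors whose receptors sit on microglia. bulkLR asks, from bulk RNA-seq of
the two populations profiled separately, which ligand-receptor pairs are
plausibly engaged: OPCs of two genotypes (wild type and TNFR2 knockout,
`WT`/`KO`) in non-stimulated and stimulated conditions (`NS`/`St`), against
microglia sampled in the naive state or at acute experimental autoimmune
encephalomyelitis (`naive`/`EAE`), with 3-4 biological replicates per
group.

Single-cell tools such as CellPhoneDB answer this question by permuting
cell labels within a joint expression matrix. That machinery does not
transfer to this design: the two populations come from different
experiments, and with 3-4 bulk samples per group a sample-label permutation
has far too few arrangements to resolve small p-values. bulkLR therefore
implements the bulk adaptation described below.

## The interaction score and its null

For a ligand gene $l$ measured in one OPC group and a receptor gene $r$
measured in one microglia condition, the interaction score in that
*context* is

$$ S(l, r) = \tfrac{1}{2}\left(\overline{x}_l + \overline{y}_r\right), $$

where $\overline{x}_l$ is the ligand's average log-FPKM over the OPC
replicates and $\overline{y}_r$ the receptor's average log-FPKM over the
microglia replicates. A context is one OPC (genotype, condition) group
crossed with one microglia condition; the default run evaluates all eight.

Significance comes from a **gene-role permutation null**: each of the
`n_perm` draws picks a ligand-role gene and a receptor-role gene
independently and uniformly from the *expressed universe* of the context
and scores them with the same formula. Because the two roles read different
matrices, a draw may legitimately assign the same gene id to both roles,
and the exhaustive reference distribution over a universe of $u$ genes has
exactly $u^2$ role assignments (`exhaustive_null()` enumerates it; the test
suite checks the sampled p-values against it on small universes). The
one-sided p-value uses the add-one estimator

$$ p = \frac{1 + \#\{S_\text{null} \ge S_\text{obs}\}}{1 + n_\text{perm}}, $$

so $p$ is never zero, has granularity $1/(n_\text{perm}+1)$, and ties count
as extreme (the conservative convention). High scores mean stronger
putative interaction, matching a dot plot in which a lower p-value draws a
bigger circle (`export_dotplot_data()` emits $-\log_{10} p$ as the size
channel).

Two deliberate consequences of this null are worth stating. First, the
null-score distribution depends only on the universe and the context
matrices, not on which pair is being tested, so `run_interaction_analysis()`
draws one null ensemble per context and compares every pair against it;
p-values within a run are therefore directly comparable, and the whole
table costs one ensemble rather than one per pair. Second, the score is
driven by *absolute* expression: a pair of highly expressed genes scores
high whether or not the ligand responds to stimulation. That is faithful to
the score's definition; condition-dependence shows up by comparing the same
pair across contexts, not within one.

The expressed universe defaults to genes whose mean log expression exceeds
0 (i.e., above the pseudocount floor) on at least one side of the context;
pass `expressed_floor` or an explicit `universe` to change this. No
multiple-testing correction is applied across pairs by default (the dot
plot reads per-pair p-values); `adjust = TRUE` adds a BH column.

## Normalization conventions

* `compute_cpm()`: counts per million; columns sum to $10^6$ exactly.
* `compute_fpkm()`: $c \cdot 10^9 / (L \cdot N)$ for count $c$, gene length
  $L$ bp, library size $N$. The library size is the raw column sum over the
  genes in the matrix; no TMM/effective-library correction is applied.
* `log_transform()`: $\log_2(x + \text{pseudocount})$, default pseudocount
  1 so zeros map to zero. Base 2 matches the log2CPM/log2FC conventions of
  the filtering stage. The transform is recorded on the object and a second
  log is refused, as is a zero pseudocount in the presence of zeros.

"Average log-FPKM" is computed as the mean of the log-transformed replicate
values (mean-of-logs), which is what the scoring stage consumes. If
log-of-means is preferred, average the linear FPKM columns first and
log-transform the result; the score function is agnostic to how the
summary was formed.

## Differential-expression filtering

The package does not re-implement a count-model fit. `simple_de_test()` is
plumbing that makes the pipeline self-contained: per gene, log2FC is the
difference of group means of $\log_2(\text{CPM}+1)$, the abundance column
is the mean over both groups (the edgeR `logCPM` convention), and the
p-value is a two-sided Welch t-test on those values, BH-adjusted. Genes
with zero variance in both groups (including all-zero genes) get $p = 1$
and log2FC 0 rather than propagating NaNs. Any external DE table with
columns (gene, log2FC, log2CPM, p[, p_adj]) can be read with
`read_de_table()` and filtered identically.

`apply_filters()` applies the inclusion rule with inclusive boundaries:
adjusted $p \le 0.05$, $\text{log2CPM} \ge 1$, $|\text{log2FC}| \ge 0.585$
(about 1.5-fold). All three are exposed in `filter_spec()`; setting the two
floors to zero counts DE genes on significance alone, since published
totals may or may not include the abundance/effect floors.

## UpSet decomposition

`upset_decompose()` computes *exclusive* intersections: each gene in the
union is assigned to the one class matching exactly the sets that contain
it. `label_categories()` names the five patterns of the four-comparison
design: blue (genotype effect at baseline only), gray (WT stimulation
response only), orange (KO stimulation response only), pink (genotype
effect under stimulation only) and red, the class of genes differentially
expressed in all three stimulation-involving comparisons. Red defaults to
exclusive semantics - a gene additionally present in the baseline
comparison is excluded - because that is what an UpSet column depicts;
`red_mode = "inclusive"` offers the laxer reading in which the fourth set
is ignored, since a prose phrase like "shared genes" admits either
convention.

## The synthetic-data generator

`simulate_dataset()` emulates the experimental design so every stage is
testable without a download: OPC samples over {WT, KO} x {NS, St} and
microglia over {naive, EAE}, `n_replicates` each (default 3, as in the
study design's n = 3-4). Counts are negative binomial - the standard bulk
RNA-seq model - with mean `baseline_mean` (default 100) and size parameter
`dispersion` (default 10, i.e. a squared biological coefficient of
variation of 0.1), multiplied by per-sample library-size factors drawn
log-normal(0, 0.1) so that normalization is doing real work.

Planted structure:

* `n_de_up`/`n_de_down` genes (defaults 400/300, matching the
  hundreds-per-comparison scale of the motivating design) shift their mean
  by $2^{\pm\text{de\_log2fc}}$ (default $\pm 2$) in stimulated OPCs of
  both genotypes.
* `n_active_pairs` ligand-receptor pairs are planted as interacting: the
  ligand is one of the up-regulated genes; the receptor is constitutively
  elevated in microglia by `receptor_log2_expr` log2 units (default 3 -
  chemokine and fractalkine receptors are among the most abundant
  microglial transcripts) and further shifted up by `de_log2fc` at EAE.
* the pair list is padded to `n_lr_pairs` rows with unique random pairs;
  ground-truth tables record every planted role. `alias_planted = TRUE`
  renames up to three planted pairs to Ccl2/Ccr5, Csf1/Csf1r, Cx3cl1/Cx3cr1
  for readable fixtures.

Gene lengths are uniform on `gene_length_range` (default 500-5000 bp),
which makes FPKM normalization non-trivial and is the dominant source of
between-gene score variation in the null world.

**What the generator does not emulate.** Real transcriptomes spread
baseline expression over orders of magnitude; here every unplanted gene
shares one baseline mean, because the simulation model has a single
`baseline_mean` parameter. Gene length and expression level are independent
here; GC/length biases, batch effects and correlated genes are absent.
Calibration and recovery results on this generator therefore demonstrate
the statistical machinery (type-I control, rank recovery, determinism), not
performance on real tissue.

## Numerical and design choices

* **Seeds.** All generator randomness flows from `simulation_config(seed)`
  via one RNG stream; the component accessors (`simulate_counts()`,
  `simulate_annotation()`, `simulate_lr_reference()`) re-run the same joint
  pass so planted roles stay mutually consistent. `run_interaction_analysis()`
  gives context $i$ the seed `seed + i - 1`. Identical inputs and seeds give
  byte-identical outputs, including the TSVs (doubles are serialized with
  `%.17g`, which round-trips IEEE doubles exactly).
* **Recovery experiments.** The planted-pair recovery check plants exactly
  one effect (one active pair, its ligand the only DE gene) so that it
  measures recovery of a single signal against a clean background; with the
  default planting density, one in five filler pairs would itself carry an
  up-regulated ligand and the experiment would instead measure ranking
  among planted pairs.
* **Degenerate inputs.** Zero-total samples, missing gene lengths, overlapping
  groups, non-log input to the scorer, and pairs absent from the matrices
  are all rejected or skipped with named reasons rather than silently
  propagated.
* **Problem sizes.** The shipped tests and the acceptance script use 2,000
  genes, 200 pairs, 3 replicates, 1,000 permutations per context, and
  20-100 simulation seeds per property; these sizes put Monte-Carlo error
  well inside the asserted tolerances while keeping a full run in the
  low minutes on one core.

## Known limitations

The Welch-on-log2CPM DE plumbing is deliberately underpowered relative to
a real edgeR/DESeq2 fit at n = 3; treat its gene counts as pipeline
exercise, not as inference, and import a proper DE table for real use. The
score's dependence on absolute expression means long-gene/short-gene FPKM
differences move pair rankings; comparing a pair across contexts is robust
to this, comparing different pairs within a context is not. Sample-label
permutation is not offered: with 3-4 replicates per group it cannot resolve
p below about 0.03 even in the best case, which is why the gene-role null
is the default and only mode.
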