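---
title: "Identifying and modelling co-expression of specific neighboring gene pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and modelling co-expression of specific neighboring gene pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sngco)
library(dplyr)
```

## The question

In plant genomes the linear order of genes is not random: adjacent genes are
more often co-expressed than random gene pairs, and lineage-specific
rearrangements occasionally bring two previously separated genes next to
each other. `sngco` analyses such **specific neighboring gene pairs (SNGs)**
— pairs that are linear neighbours in a focal genome (the motivating system
is the tea plant *Camellia sinensis*) but whose orthologs are *not*
neighbours in any of a panel of reference species. The package asks two
questions about these evolutionarily novel neighbours: do they co-express
across tissues more than chance predicts, and which genomic and epigenomic
features (intergenic distance, gene length, open chromatin, H3K27ac,
chromatin contacts, shared function and promoters, shared enhancers,
expression divergence) explain that co-expression?

## SNG identification

Adjacency is purely rank-based: within each chromosome genes are ordered by
start coordinate (ties broken by end, then by gene ID so the ranking is
deterministic), and two genes are neighbours iff their ranks differ by 1.
Strand and intergenic distance play no role in adjacency. For a
focal-adjacent pair, each reference species is classified as

* `adjacent` — *any* ortholog of gene 1 is a neighbour of *any* ortholog of
  gene 2 (the many-to-many OR rule; conservative against false SNG calls),
* `no_ortholog` — either gene has no recorded ortholog there,
* `non_adjacent` — otherwise.

A pair is an SNG when no reference species is `adjacent`. Because orthology
tables in practice have gaps, two policies are exposed and reported per
pair: **strict** (the default) demands `non_adjacent` in *every* species, so
a missing ortholog disqualifies a pair; **lenient** lets `no_ortholog`
species count toward the intersection. The per-species status matrix is part
of the output so the choice is auditable. `find_sngs()` is checked against
an exhaustive all-pairs scan on hundreds of random instances.

## Co-expression statistics

Co-expression is Pearson correlation of raw TPM across tissues exceeding a
threshold (default 0.5). Correlations are computed on raw TPM because that
is the convention this analysis follows; a `log2p1` switch is available
since many pipelines prefer log-space. Genes with constant expression are
*excluded* with a logged count rather than assigned r = 0, which would
silently deflate proportions.

Pairs are binned by intergenic distance (start-to-start, default edges 8 kb
and 50 kb) and by mean transcribed length (default edges 5.5 kb and 9 kb).
Binning is left-closed: a pair at exactly 8 kb falls in the *medium* bin,
matching a "short < 8 kb" definition. Reported percentages are rounded
half-up to 2 decimals only at the reporting layer; all internal arithmetic
is unrounded.

Chance levels come from a randomization null: each iteration draws the same
number of unordered distinct-gene pairs uniformly from the expression
matrix and records the co-expressed proportion; the empirical p-value uses
add-one smoothing, so it is never exactly zero. The default iteration count
is 10,000 (configurable). Proportion error bars are bootstrap standard
errors (1000 resamples with replacement; the estimator converges to
`sqrt(p(1-p)/n)` and is tested against that closed form). Group
comparisons use the Mann–Whitney U test; the package computes U and a
tie-corrected normal-approximation p-value directly because the fully tied
case must return p = 1 rather than NaN, and cross-checks against
`wilcox.test()` in its tests. SNG expression profiles are summarized by
k-means on row-standardized profiles (default k = 4, 25 restarts, fixed
seed) — no specific clustering algorithm is canonical for this step, and
partitioning standardized profiles is the simplest reproducible choice.

## The nine molecular features

For every SNG the feature builder produces: intergenic distance; mean gene
length; ATAC and H3K27ac flags (a gene is flagged when any peak overlaps
its body extended 2 kb upstream of the TSS by at least 1 bp; the pair-level
covariate combines the two per-gene flags with AND by default, OR being
available because the pair-level encoding is genuinely ambiguous);
ICE-normalized Hi-C contact between the 5-kb bins holding the two TSSs
(strand-aware TSS; masked or absent bins yield 0 plus a missingness flag);
the number of exactly shared GO Biological Process IDs; the number of
distinct shared promoter cis-element names; an enhancer-sharing flag; and
the relative expression difference `|e1 - e2| / mean(e1, e2)`, which is
symmetric, scale-invariant and bounded by 2.

Active enhancers are intersections of intergenic H3K27ac peaks (no overlap
with any gene body) with ATAC peaks. Each enhancer records its two nearest
genes by TSS distance, and a pair "shares" an enhancer when those two
nearest genes are exactly the pair — the strictest reading of sharing; the
assignment table is returned so looser definitions can be derived from it.

ICE normalization is plain iterative row-sum correction: divide by the
outer product of the relative marginal bias until the largest relative
deviation drops below tolerance. Zero-marginal bins are masked, not
divided. Because convergence is linear, the tolerance is set at 1e-8 with a
generous iteration cap (2000), which leaves the post-normalization
coefficient of variation of row sums comfortably below 1e-6 and makes the
operation idempotent to the same tolerance.

## The co-expression model

Class balance is enforced by downsampling negatives to the positive count
(the reverse only on request). Each of the default 50 repeats draws a fresh
balanced dataset, makes a *stratified* 80/20 split so both sides keep class
balance, z-scores features on the training split only, fits a logistic
regression by iteratively reweighted least squares (convergence 1e-8 on the
largest coefficient change, perfect separation detected and flagged, tiny
ridge fallback for singular designs), and scores the held-out fifth with a
midrank AUC that equals the exhaustive positive-negative comparison count.
The mean AUC over repeats is the headline number; variable importance is
the repeat-averaged |standardized coefficient / SE|, the same quantity
`caret::varImp` reports for a GLM. Whether negatives should be redrawn
inside every repeat or fixed once is not determined by the procedure's
description, so both modes exist (`refresh_negatives`), with redraw as the
default because it propagates sampling uncertainty into the AUC spread.

Interaction surfaces refit `y ~ distance + feature + distance:feature` and
evaluate predicted probabilities over a grid (five distance quantiles by
low/mid/high feature tertiles). Internally the fit uses z-scored inputs —
an affine reparameterization with identical fitted probabilities — because
the raw-scale interaction design is numerically singular when distance
spans kilobases to megabases.

## Modules and metabolites

Gene- and module-level association with metabolite accumulation (the six
catechins GC, EGCG, ECG, EGC, EC, C by default) uses Pearson correlation
across tissues with t-distribution p-values (n − 2 df). Module construction
is a deliberately simplified signed network: adjacency
`((1 + r)/2)^14`, average-linkage clustering of `1 − a`, a static cut at
99% of the dendrogram height, clusters below 30 genes set to "grey", and
iterative merging of modules whose eigengenes correlate above 0.75. This
approximates the full weighted-network workflow whose dynamic tree-cut
heuristics are out of scope here; assignments from an external run can be
imported with `read_modules()` and pushed through the same downstream
machinery, so the approximation never blocks an audit. Eigengenes are
unit-norm first principal components of row-standardized module expression
with the sign fixed so mean module KME is positive. Hubs are ranked by KME
within module (top 60 by default) and flagged against a transcription
factor list.

## What the simulator emulates — and what it does not

The generators plant known structure in every layer so each stage has a
recoverable truth:

* `simulate_genomes()` builds a focal genome plus references with identical
  gene order except that a reference-specific filler gene is inserted
  between the orthologs of each planted pair. This makes planted pairs
  separated in *every* reference while every other adjacent pair keeps at
  least one adjacent reference — so exact recovery is the correct outcome,
  not a lucky one. A small fraction of non-planted genes (5%) lacks
  orthologs in some species to exercise the missing-ortholog policies.
* `simulate_expression()` gives each disjoint adjacent pair a shared latent
  tissue profile with mixing weight
  `w = clamp(0.75 − 5e-6·d + 2e-5·L, 0, 1)` and TPM equal to the
  exponential of a Gaussian (non-negative, heavy-tailed). Defaults — 8
  tissues, noise SD 0.5 on the log scale — were chosen once as plausible
  multi-tissue RNA-seq conditions: the weight slopes put an appreciable
  co-expression gap between sub-8-kb and over-50-kb pairs without
  saturating either bin.
* `simulate_peaks()` multiplies TPM of peak-carrying genes by a fold
  change (default 1.5) and can plant intergenic ATAC/H3K27ac co-occurrences
  whose count the enhancer caller must recover exactly.
* `simulate_hic()` draws Poisson counts around
  `scale · (1 + |i − j|)^−decay`, the canonical distance decay of contact
  maps.
* `simulate_metabolites()` mixes module eigengenes with noise at a target
  correlation, then rescales linearly (Pearson-preserving) to positive
  accumulation levels.

What the simulator does **not** reproduce: tandem duplications and nested
genes, expression compositionality of real TPM, replicate structure within
tissues, peak width/score distributions, translocations (references differ
from the focal genome only by planted insertions), and trans contacts
beyond a constant background. Green tests therefore certify the
*machinery* — identification logic, estimator calibration, model ordering —
under known truth; they do not certify biological conclusions on any real
genome.

## Numerical and reporting conventions

GFF3 coordinates are 1-based inclusive and are the internal convention
everywhere; BED input/output converts at the boundary. Pair-record TSVs
serialize doubles at 17 significant digits so write-then-read is
bit-exact. Reported percentages round half-up (not banker's rounding) at 2
decimals, set percentages at 1 decimal. Every pipeline run writes its
resolved configuration, including the seed, next to its outputs.

Problem sizes used by the packaged checks — 12-species/200-gene recovery
sweeps, a 1000-gene genome for the distance analysis, 1000–2000-iteration
nulls, 20-repeat model loops on 400 pairs — were chosen as the smallest
instances at which every planted effect is comfortably identifiable; all
counts scale up through the configuration object.

## Known limitations

* The static-cut module procedure under-splits relative to dynamic
  tree-cut heuristics when module sizes are very uneven.
* The randomization null samples pairs with replacement within an
  iteration; at realistic gene counts collisions are negligible.
* Interaction surfaces are descriptive fits on the balanced dataset; they
  are not causal estimates, and their confidence bands are not reported.
* With fewer than ~8 tissues, per-pair correlations are noisy enough that
  only aggregate (binned) statements are stable; the defaults reflect
  that.

## A minimal run

```{r example, eval = FALSE}
sim  <- simulate_genomes(n_species = 12, n_genes = 200,
                         frac_planted_sng = 0.1, seed = 1)
expr <- simulate_expression(sim$annotations$focal, seed = 2)
res  <- run_sng_pipeline(sim$annotations$focal, sim$annotations[-1],
                         sim$orthologs, expr,
                         config = sng_config(seed = 1, n_randomization = 2000),
                         outdir = "sng_run")
res$report$n_sng_pairs
res$distance_bins
plot_bin_summary(res$distance_bins)
```
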