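# sngco

Identification and co-expression analysis of **specific neighboring gene
pairs (SNGs)**: gene pairs that are linear neighbours in a focal plant
genome (the motivating system is tea, *Camellia sinensis*) but whose
orthologs are not adjacent in any of a panel of reference species. Such
pairs mark lineage-specific gene rearrangements, and the package quantifies
whether and why they co-express.

The pipeline, exposed as pipe-friendly functions over tibbles:

1. **Identification** — rank genes along each chromosome, call a
   focal-adjacent pair an SNG when, for every reference species *s*, no
   ortholog of gene 1 is adjacent to an ortholog of gene 2
   (`find_sngs()`, with strict/lenient handling of missing orthologs).
2. **Co-expression statistics** — Pearson r of TPM profiles across tissues
   (co-expressed ⇔ r > 0.5), binning by intergenic distance `|s₁ − s₂|`
   (edges 8 kb, 50 kb) and mean gene length (edges 5.5 kb, 9 kb),
   randomization nulls for the co-expressed proportion, bootstrap standard
   errors, Mann–Whitney U tests, k-means profile clusters.
3. **Nine molecular features** per pair — distance, mean length, ATAC and
   H3K27ac peak flags, ICE-normalized Hi-C contact between the 5-kb TSS
   bins, shared GO BP terms, shared promoter elements, shared active
   enhancers (intergenic H3K27ac ∩ ATAC), and relative expression
   difference `|e₁ − e₂| / ((e₁ + e₂)/2)`.
4. **Logistic model** — balanced positives/negatives, 50 repeats of a
   stratified 80/20 split fit by IRLS, mean test AUC
   `P(score⁺ > score⁻)`, variable importance `|β̂/SE|` on standardized
   features, and distance × feature interaction surfaces.
5. **Metabolite association** — gene- and module-level Pearson correlation
   with metabolite accumulation (catechins GC, EGCG, ECG, EGC, EC, C),
   simplified signed co-expression modules (adjacency `((1+r)/2)^14`),
   eigengenes, KME hub ranking, TF flagging.

A linked synthetic-data generator (`simulate_genomes()`,
`simulate_expression()`, `simulate_peaks()`, `simulate_hic()`,
`simulate_module_expression()`, `simulate_metabolites()`) plants known
structure in every layer, so each stage is testable end to end without any
external download.

## Worked example

```r
library(sngco)

sim  <- simulate_genomes(n_species = 12, n_genes = 200,
                         frac_planted_sng = 0.1, seed = 1)
expr <- simulate_expression(sim$annotations$focal, seed = 2)
res  <- run_sng_pipeline(sim$annotations$focal, sim$annotations[-1],
                         sim$orthologs, expr,
                         config = sng_config(seed = 1, n_randomization = 2000,
                                             n_model_repeats = 10))
res$report$n_sng_pairs
#> [1] 20
res$report$coexpression_proportion_pct
#> [1] 75
res$report$null_p_value
#> [1] 0.0004997501
res$distance_bins
#> # A tibble: 3 × 5
#>   label  n_pairs n_coexpressed proportion bootstrap_se
#>   <chr>    <int>         <int>      <dbl>        <dbl>
#> 1 short        5             4      0.8          0.180
#> 2 medium      15            11      0.733        0.117
#> 3 long         0             0     NA           NA
```

The 20 identified pairs are exactly the pairs the simulator planted
(`sim$truth$true_sng_pairs`). 75% of them are co-expressed (r > 0.5),
against a randomization-null mean near 13%, hence the smoothed empirical
p-value of 1/2001 — the planted adjacent-pair effect is detected. The
binned summary shows the planted distance decay: sub-8-kb pairs co-express
more often than 8–50-kb pairs, with bootstrap standard errors alongside.
`plot_bin_summary()`, `plot_null_distribution()`, `plot_feature_auc()`,
`plot_interaction_surface()` and `plot_module_metabolite()` draw the
corresponding figures; `tidy()`/`glance()` methods expose fitted models in
broom shape.

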