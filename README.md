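# tnfomics

Longitudinal blood multi-omics analysis of anti-TNF therapy response in
inflammatory bowel disease (IBD). Patients starting anti-TNF therapy are
profiled at up to seven timepoints (baseline, 4 h, 24 h, 72 h, week 2,
week 6, week 14) by RNA-seq and at baseline/week 2/week 6 by EPIC-style DNA
methylation arrays, and classified at week 14 as remitters (HBI ≤ 4 for
Crohn's disease, partial Mayo ≤ 2 for ulcerative colitis) or non-remitters.
The package implements the full analysis chain as tested library functions
plus numbered analysis scripts, and ships a synthetic cohort generator with
planted ground truth so every stage's recovery can be scored.

The analysis chain:

1. **Normalization** — median-of-ratios size factors.
2. **Differential expression** — per-gene negative binomial GLMs for each
   timepoint vs baseline (patient blocking, moment dispersion shrunk toward
   a mean-dispersion trend, Wald *t* test), plus case-only longitudinal
   testing with the six-parameter impulse model
   `f(t) = (1/h1)[h0+(h1−h0)σ(β(t−t1))][h2+(h1−h2)σ(−β(t−t2))]`
   against a constant-mean model (likelihood ratio, χ²₅); DEG sets combined
   at FDR 0.05.
3. **Co-expression network** — signed adjacency `((1+r)/2)^β` on remission
   DEGs at baseline, scale-free soft-threshold selection (target fit 0.9),
   topological-overlap clustering with an adaptive tree cut (min module size
   15), eigengene merging (cut height 0.2), kME, and Spearman module–trait
   correlation.
4. **Module preservation** — permutation Z-summary (density + connectivity
   statistics) of baseline modules in week-2/6 data per outcome group;
   modules with `Z < 2` in remitters but `Z > 10` in non-remitters are the
   therapy-disrupted modules; kME-shift ranking of the genes driving the
   loss.
5. **Differential methylation** — ordered probe QC filter, paired moderated
   *t* with combined rank (|Δβ|, log-quotient, p) and an automatic rank
   cutoff; DMR aggregation and chi-square category representation.
6. **Cis integration** — DMPs within ±5 kb of DEG transcription start
   sites, Spearman correlation over patient/timepoint-matched samples,
   permutation FDR (patient-identity shuffling), canonical-negative sign
   classification and module over-representation of DNAm-linked genes.
7. **Outcome prediction** — random-forest models on baseline + week-2
   features (DEGs, DMPs, DNAm-linked DEGs, eigengenes, clinical covariates)
   with shadow-importance feature selection, 10-fold cross-validated AUC and
   bootstrap confusion statistics.

## Worked example

Simulate the default cohort (24 patients, 2000 genes, 5000 probes, planted
modules/DMPs/cis pairs) and run the whole pipeline:

```r
library(tnfomics)
out <- run_pipeline(analysis_config(rng_seed = 11), out_dir = "pipe")
rec <- evaluate_recovery(out$truth, out)
rec$modules$ari
#> [1] 0.8532544
rec$disruption$flagged_modules       # detected disrupted modules, truth labels
#> [1] "M1" "M2"
rec$cis[c("sensitivity", "frac_negative")]
#> $sensitivity
#> [1] 0.9752066
#> $frac_negative
#> [1] 0.661157
out$prediction$auc
#> [1] 1
```

Reading: module detection recovers the planted partition (adjusted Rand
index 0.85); the preservation contrast flags exactly the two modules whose
latent loadings were attenuated in remitters; 97.5% of planted cis CpG–gene
pairs are recovered at FDR 0.05 with 66.1% showing the canonical negative
(methylation-up / expression-down) correlation against a planted 2/3; and
the week-2 expression of DNAm-linked DEGs separates remitters from
non-remitters perfectly under 10-fold cross-validation.

The same chain is available as stepwise drivers:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
...
Rscript analysis/08_evaluate.R     # writes results/recovery.tsv
```

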