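---
title: "Models and methods behind tnfomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tnfomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tnfomics` implements a longitudinal blood multi-omics workflow for anti-TNF
therapy response in inflammatory bowel disease: two cohorts of patients
(remitters and non-remitters at week 14), RNA-seq counts at seven timepoints
from baseline to week 14, and EPIC-style methylation beta values at baseline,
week 2 and week 6. This vignette explains the statistical models, the
parameters that matter, the synthetic cohort the package tests itself
against, and the design decisions taken where the methodology was genuinely
open.

## Normalization and pairwise differential expression

Counts are normalized with the median-of-ratios method: reference genes are
those with a positive geometric mean across samples; each sample's size
factor is the median of its count ratios against those geometric means.
Pairwise differential expression compares each post-baseline timepoint
against baseline within one outcome group with a per-gene negative binomial
GLM (log link, log size factors as offset). Because samples are longitudinal
within patients, the model includes a patient blocking factor; the original
analysis does not state its design formula, so blocking is our choice and is
the package default.

Dispersion is a gene-wise method-of-moments estimate pooled over conditions,
shrunk 50/50 (linear weighting, `shrink_weight`) toward a log-linear
mean-dispersion trend fitted across genes. This is deliberately simpler than
empirical-Bayes machinery: at ten patients per group it is stable, and the
50/50 weight makes the estimator's behavior easy to reason about. The
timepoint coefficient is tested by a Wald statistic referred to a
*t* distribution with residual degrees of freedom rather than a normal: the
patient factor consumes roughly half the observations, and on planted-null
simulations the normal reference was visibly anticonservative (about 9% of
null genes below p = 0.05) while the *t* reference restores the nominal 5%.

## Impulse-model longitudinal differential expression

The longitudinal test fits each gene's mean trajectory with the six-parameter
impulse curve, a product of two sigmoids,

$$f(t) = \frac{1}{h_1}\,\bigl[h_0 + (h_1 - h_0)\,\sigma(\beta(t - t_1))\bigr]
              \bigl[h_2 + (h_1 - h_2)\,\sigma(-\beta(t - t_2))\bigr],$$

with plateau levels $h_0, h_1, h_2 > 0$, onset/offset times $t_1 < t_2$ in
hours, and slope $\beta > 0$. The functional form follows the published
impulse-model method this step emulates. Per gene the negative binomial likelihood with mean
$s_j f(t_j)$ and fixed moment dispersion is maximized by Nelder-Mead from
five deterministic starts built from per-timepoint mean normalized counts
(peak, dip, flat, monotone up, monotone down), followed by one restart at the
incumbent optimum — Nelder-Mead restarts recover much of what its adaptive
simplex loses, and on null simulations the restart moves the rejection rate
from just under 3% to 4%, inside the nominal band. The likelihood-ratio
statistic against the constant-mean model is referred to $\chi^2_5$ (five
extra parameters). Transition parameters are only weakly identified under the
null, which makes $\chi^2_5$ mildly conservative; we keep it because it is
the cited method's convention. Non-convergent genes are flagged, not silently
dropped.

DEG sets combine pairwise and longitudinal calls at FDR 0.05. Whether genes
must reach significance in both analyses or in either is ambiguous in the
original description, while the combined reporting of the two analyses
suggests a union; the package defaults to the union with provenance flags
and offers `deg_combination = "intersection"`.

## Signed co-expression network

Networks are built on the remission DEG set, baseline samples only, from
Pearson correlations of $\log_2(x+1)$ normalized counts. The signed
adjacency is $a_{ij} = ((1 + r_{ij})/2)^\beta$; the soft power is the
smallest grid value whose connectivity distribution attains a scale-free fit
above 0.9 (the discovery cohort attained it at 16). On a focused DEG subset
of a few hundred genes the connectivity distribution need not look scale-free
at any power — with 24 baseline samples the correlation noise floor dominates
— so when the target is unreached the pipeline falls back to the canonical
signed power 16 (`network_power_fallback`) rather than to a low best-fit
power that barely separates signal from noise. `pick_soft_threshold()` itself
keeps its documented contract (best-fit power plus a warning flag) for direct
use.

Genes are clustered by average linkage on 1 − TOM (topological overlap;
`tree_distance = "adjacency"` switches to 1 − adjacency, since the original
description is ambiguous about which tree it cut). The published dynamic hybrid tree
cut is replaced by a deterministic adaptive variant: the tree is cut at a
descending ladder of merge-height quantiles and the cut kept is the one
yielding the most *valid* clusters, where validity means at least
`min_module_size` (15) members and mean within-cluster correlation above a
power-independent floor (`min_module_cor = 0.2`, so pure-noise branches never
become modules). Because hierarchical branches absorb weakly-correlated
hangers-on, members whose correlation with their own module eigengene falls
below `kme_floor = 0.45` are released to "unassigned" (two refinement
passes). Over-split modules are healed by the standard eigengene merge:
modules whose eigengene dissimilarity (1 − correlation) is below
`merge_cut_height = 0.2` are merged iteratively, closest pair first, with
eigengenes recomputed after each merge. Eigengenes are first principal
components of gene-standardized module expression, scaled to unit variance
and sign-oriented against the module mean profile so results do not depend on
the linear-algebra backend. Module-trait association uses Spearman
rank correlation, the natural choice for skewed clinical covariates, with
significance stars at 0.05 / 0.01 / 0.001.

## Module preservation

Preservation of baseline modules in week-2/week-6 data per outcome group uses
a permutation Z-summary with a four-statistic subset of the published suite:
two density statistics (mean intramodule correlation and mean intramodule
signed adjacency in the test data) and two connectivity statistics
(reference-test correlation of intramodular connectivity, and of the
vectorized intramodule correlation matrices). Each statistic is standardized
against `n_permutations` (default 100) random same-size gene sets from the
test universe; `z_density` and `z_connectivity` are medians of their pairs,
`z_summary` their mean. Classes follow the conventional thresholds — below 2 not
preserved, 2 to 10 moderate, above 10 high — with boundary values assigned to
"moderate" (closed interval). A module counts as differentially preserved
when its non-remission class strictly exceeds its remission class at either
week. The kME-shift ranking recomputes eigengenes on the reference membership
within each dataset and ranks genes by kME loss (baseline minus remission
test). The test-side adjacency reuses the reference soft power, and null gene
sets are drawn from the whole test universe, matching the cited method's
module-label permutation.

## Differential methylation

Probes are filtered in a fixed order — SNP overlap, unreliable measurement,
context-specific probes, sex chromosomes, missing values — with each probe
attributed to the first criterion that removes it and per-criterion counts
logged. DMP calling between baseline and week 2 or 6 is paired within
patients (a design choice; the source does not state pairing, but the samples
are longitudinal). Three statistics are computed per probe: the mean paired
beta difference, the log2 quotient of state means with pseudo-count 0.01
(avoiding division by zero near beta = 0), and a moderated paired *t*: probe
variances are shrunk 50/50 toward the grand median variance and the statistic
referred to a *t* with $2(n-1)$ degrees of freedom — when the prior carries as
much weight as the data, moderated-*t* theory doubles the residual degrees of
freedom. Probes are ranked on each statistic (1 = most extreme) and combined
by the maximum rank, the conservative convention (`rank_combination =
"mean"` is available). The automatic significance cutoff — undocumented in
the original framework — is made explicit and testable here: $r^*$ equals the
number of probes with BH-adjusted p below the FDR threshold, and probes with
combined rank at most $r^*$ are significant. $r^* = 0$ is a legitimate
outcome. Regions score as the mean combined rank of their members and need at
least two surviving probes. Category representation uses the chi-square test
on the 2×2 membership table.

## Cis integration

Candidate pairs are significant DMPs within ±5000 bp (inclusive) of a DEG's
transcription start site, on 0-based coordinates with strand-aware signed
distances (positive = downstream in gene orientation). Per pair, Spearman's
rho is computed over samples matched by patient and timepoint across the two
layers (the three shared timepoints), pooled across outcome groups by default
since the source does not state which samples entered the correlations (a
group-restricted mode exists). Significance uses a permutation FDR: the
methylation layer's patient identities are shuffled (timepoints kept), all
pair |rho| recomputed, and the pooled null across pairs and permutations
yields add-one empirical p-values (never zero), BH-adjusted across pairs. The
pooled null was chosen over per-pair nulls for runtime — per-pair nulls at
hundreds of permutations times thousands of pairs would dominate the
pipeline — and patient-level shuffling preserves within-patient temporal
autocorrelation and any shared time trends under the null, so correlations
explained purely by parallel mean trajectories do not count as signal. Signs
classify as canonical negative (rho < 0: methylation up, expression down) or
positive; module over-representation of DNAm-linked genes again uses the 2×2
chi-square.

## Outcome prediction

Feature matrices hold one row per patient and only baseline and week-2
columns — later timepoints are excluded by construction so the remission
endpoint (week 14) cannot leak into the features. Layers: expression of a
gene set (DEGs or DNAm-linked DEGs), DMP betas, module eigengenes, and the
clinical covariates CRP, IL-6, tryptophan and activity score (age and gender
are deliberately not features, matching the source analysis). Feature
selection fits a 500-tree random forest (permutation importance, seeded) and
keeps features whose importance exceeds the 95th percentile of pooled
importances from ten label-permuted shadow forests — a data-driven surrogate
for the unstated original cutoff that yields feature counts in the tens.
Cross-validated AUC uses stratified folds (default 10), a seeded
random-forest classifier, out-of-fold probabilities, a threshold-sweep ROC
and trapezoidal AUC. Selection runs inside each training fold by default;
`paper_mode = TRUE` reproduces single-step selection before cross-validation,
which is optimistic but matches the original workflow. Confusion statistics
(accuracy, sensitivity, specificity, PPV, NPV) come with patient-bootstrap
standard errors (100 replicates) and an exact Clopper-Pearson 95% CI for
accuracy.

## The synthetic cohort and what it does (not) show

`simulate_cohort()` emulates the discovery cohort's statistical structure
with planted ground truth. Defaults: 12 patients per outcome group; RNA at
baseline/4h/24h/72h/2w/6w/14w; methylation at baseline/2w/6w; 2000 genes,
5000 probes. Counts are negative binomial with lognormal library sizes
(sd 0.15 on the log scale) and per-gene dispersion uniform on 0.1–0.5.
Planted structure:

* **450 DE genes** (300 remission-specific, 150 shared) follow impulse
  trajectories with peak |log2 fold change| uniform on 1.5–3 — anti-TNF
  induces strong early blood transcriptional responses, so multi-fold peak
  changes are the realistic regime — onset uniform within the first 200 h and
  offset 150–1500 h later.
* **6 co-expression modules of 50 genes** partition the remission-specific
  DEGs; module genes share a per-sample latent factor with loadings uniform
  on 0.6–0.9 of the log scale. Factors are standardized within each
  group × timepoint cell so the planted module strength is exactly the
  configured loading in every condition rather than subject to small-sample
  variance luck. Two modules are disrupted: loadings multiplied by 0.1 at
  weeks 2 and 6 in remitters only — connectivity loss, not expression loss.
  Planting all module genes inside an equally sized DE set would leave the
  DEG-restricted network with no background genes, making both
  soft-threshold selection and the unassigned class degenerate; planting 450
  DE genes with 150 module-free ones keeps the network universe realistic.
* **400 DMPs** with target |delta beta| 0.2 on top of logit-scale noise
  (sd 0.3) and a patient effect (sd 0.2): 200 shift at weeks 2 *and* 6 in
  remitters (persistent), 200 at week 2 only in non-remitters (transient),
  mirroring the observed persistence asymmetry between outcome groups.
* **150 cis pairs** (100 negative, 50 positive — the planted 2/3 canonical
  fraction): the probes are remission-persistent DMPs placed within ±4.8 kb
  of their gene's TSS; their M-value noise is coupled (weight 0.7) to the
  gene's standardized log-expression *residual* after removing group × time
  means, so uncoupled candidate pairs share only mean-level trends, which the
  permutation null retains. The probes' DMP shifts take the canonical
  orientation relative to the gene's expression trend, and cis probes carry
  no independent patient effect so the realized coupling equals the
  configured value.
* **30 predictive genes** outside the DE set carry a constant ±1.0 log-scale
  group offset, visible at baseline and week 2.

What passing the recovery suite shows: the pipeline's inference machinery
correctly recovers structure of the planted kind at realistic effect sizes
and sample sizes, with calibrated error rates on the planted-null streams.
What it does not show: robustness to array artifacts (dye bias, batch,
cross-reactive probes), cell-type composition shifts (in real whole blood a
dominant driver), unmodeled confounding, or outliers — none of which the
generator emulates. Absolute discovery counts from the real cohorts are not
reproducible from this package.

## Numerical choices and problem sizes

Tie-breaks and degenerate inputs: ranks use `ties.method = "min"` in the
combined-rank table (permutation-equivariant); empirical p-values use the
add-one convention; eigengene signs are oriented against the module mean;
module labels order by size with first-gene position as a deterministic
tie-break; zero-variance genes standardize to zero within eigengene
computation; probes or pairs with constant data report missing statistics
with warnings rather than errors. All stochastic steps (permutation nulls,
folds, forests, shadow runs, the simulator) take explicit seeds, and child
seeds for pipeline stages derive deterministically from the configured
`rng_seed`, so a rerun with the same seed is byte-identical.

The shipped tests and the acceptance script exercise the default cohort (24
patients, 2000 genes, 5000 probes), planted-null simulations of 500 genes and
5000 probes, and 100-permutation nulls; the full pipeline completes in a few
minutes on one CPU at those sizes. These sizes were chosen to match the
emulated study's scale while keeping the recovery experiments quick to rerun.

## Known limitations

The adaptive tree cut is simpler than the published hybrid dynamic cut and
will differ on real data with nested or highly unbalanced modules. The
four-statistic Z-summary omits the medianRank and quality statistics of the
full preservation suite. The impulse fit uses a fixed moment dispersion
rather than joint estimation. The automatic DMP rank cutoff is this package's
explicit surrogate for an undocumented selection rule, and recorded in output
metadata as such. DMR region maps must be supplied externally; the package
does not derive promoter/island/enhancer definitions from a genome.
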