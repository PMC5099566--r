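---
title: "Reference-gene stability and biomarker evaluation for serum miRNA qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability and biomarker evaluation for serum miRNA qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnorm)
```

## The problem

Serum miRNA levels measured by qPCR are reported as quantification cycles
(Cq): the PCR cycle at which fluorescence crosses a threshold, inversely
proportional to the log2 of template abundance. Raw Cq confounds biology
with technical variation — input serum volume, extraction yield, reverse
transcription efficiency — so targets are quantified *relative* to
endogenous reference genes. But no serum miRNA is universally stable:
reference genes must be screened and validated per study. `mirnorm`
implements that screening-and-evaluation workflow: QC, candidate
selection, stability ranking, relative quantification, and diagnostic
evaluation, together with a generator of synthetic studies whose ground
truth makes every step testable.

## Sample quality control

Two artefacts dominate serum qPCR quality: hemolysis and failed
extraction. Red blood cells are rich in miR-451a, so lysis inflates it
selectively; the hemolysis index ΔCq = Cq(miR-23a-3p) − Cq(miR-451a) grows
with contamination, and a sample passes only if ΔCq is *strictly* below 7
cycles — the boundary value 7.0 fails. The threshold is configurable;
the strictness of the boundary is deliberate and tested. miRNA naming for
the markers varies between assay catalogues (miR-451a vs miR-451a-5p), so
the marker names are plain arguments, never resolved by alias.

Extraction consistency is monitored through a synthetic spike-in
(cel-miR-39) added in fixed quantity before isolation. Stability of its Cq
is the criterion, but no universally agreed numeric rule exists; we use
|Cq − median across samples| ≤ 1.5 cycles, a robust single-outlier rule,
configurable via `max_abs_dev`. With fewer than three samples the median
is meaningless and the check warns and passes everyone.

QC operates on raw Cq — the markers are themselves miRNAs, so any
normalisation would corrupt the check — and failing samples are excluded
from *all* downstream group statistics. Filtering is idempotent.

## Candidate screening

Candidates come from a linear-scale expression matrix (e.g. a summarised
microarray) under three criteria:

1. **Highly expressed in all samples.** Operationalised as detection
   (intensity > 0) in every sample and a pooled mean at or above the 75th
   percentile of gene means. Both knobs (`min_detect_frac`,
   `expr_quantile`) are explicit because "highly expressed" has no
   standard number.
2. **No differential expression** between the two groups: two-sided Welch
   t on log2 intensities with p > 0.05. Welch is the default because
   equal-variance assumptions buy nothing here; a pseudocount of 1 guards
   zeros.
3. **Low variation**: the gene's worst coefficient of variation — the max
   of pooled and per-group CVs, computed on linear intensities — must rank
   within the `cv_rank_k` (default 10) smallest among genes passing 1–2.
   A zero mean makes the CV undefined and counts as a fail.

`differential_expression()` applies the classic microarray filter: linear
fold change FC ≥ 2 (boundary inclusive) or ≤ 1/2, together with raw
p ≤ 0.05 from the same Welch test. Benjamini–Hochberg adjusted p values
are reported alongside for transparency, but the significance flag uses
the raw p — the filter is a screening heuristic, not an inference, and its
type-I behaviour under the null is verified by simulation (fraction of
null genes at p ≤ 0.05 stays at 0.05 ± 0.02 over 2000 genes).

Ties in the CV ranking keep input order; the whole selection is invariant
to sample order.

## geNorm

Cq converts to relative quantities per gene as Q = E^(Cq_min − Cq) with
amplification efficiency E = 2 by default (perfect doubling; no per-assay
efficiencies are assumed). Each gene's maximum Q is 1.

For genes j and k, V_jk is the sample standard deviation (n − 1) of
log2(Q_j/Q_k) across samples, and the stability value M_j is the mean of
V_jk over all partners k. M is invariant to per-gene rescaling of Q and to
sample permutation — both properties are tested against a brute-force
double-loop oracle at 1e−10. Ranking is stepwise: recompute M on the
surviving set, remove the worst gene, repeat until two remain; those two
are the most stable pair. All ties break by input order, and the final
pair receives ranks 1 and 2 by their full-set M so that ranks stay a
permutation of 1..G.

The pairwise variation V(n/n+1) is the SD across samples of
log2(NF_n/NF_{n+1}), where NF_n is the geometric mean of the top-n genes'
quantities. The recommended number of reference genes is the smallest n
with V(n/n+1) < 0.15 — the original heuristic, exposed as `v_threshold`.

## NormFinder

NormFinder decomposes log-scale expression within each group into gene,
sample and residual terms. We center each group's matrix by gene and
sample means and estimate the per-gene intragroup variance with a
small-sample bias correction derived for heterogeneous gene variances
under that two-way centering:

E[RSS_i/(n−1)] = σ²_i (1 − 2/G) + σ̄²/G,

giving σ̂²_i = (z_i − z̄/(G−1)) · G/(G−2) with z_i = RSS_i/(n−1); negative
estimates are floored at zero (a small-sample artefact). The intergroup
deviation d(i,g) is the gene-by-group interaction of the sample-centered
group means, shrunk towards zero by the empirical-Bayes factor
τ²/(τ² + v(i,g)), where v(i,g) = σ̂²(i,g)/n_g is the sampling variance of
d and τ² = max(0, mean(d²) − mean(v)) the moment estimate of the true
deviation variance. The stability value is the group average of
|d_shrunk| + √v; in single-group mode it reduces to the estimated residual
SD. The estimators are validated by parameter recovery: in a designed
scenario (one gene at σ = 0.1 cycles with no group bias among nine at
σ = 0.5 with balanced biases spanning ±1 cycle; 2 × 12 samples), the
designed gene is ranked first in well over 90 % of seeds and the
seed-averaged variance estimates land within 25 % of truth.

One identifiability caveat is worth stating plainly: d(i,g) is defined
*relative to the candidate panel's average shift*. If most of the panel
moves together between groups, that common movement is indistinguishable
from a group effect and is not attributed to any single gene — a gene with
truly zero bias then appears to deviate by minus the panel mean. Stability
screening therefore works best on panels whose group effects roughly
cancel; a systematically shifted panel degrades every model-based ranking,
not just this implementation.

## Comprehensive ranking

geNorm and NormFinder ranks are aggregated by their geometric mean —
the usual comprehensive-ranking convention — sorted ascending, ties broken
by lower geNorm M and finally input order. The whole chain (simulate → QC
→ stability → aggregate) recovers a designed stable reference as
comprehensive rank 1 in ≥ 90 % of 200 seeded runs of the benchmark
scenario `reference_recovery_config()`.

## Relative quantification (2^−ΔΔCt)

The per-sample reference Cq is the arithmetic mean of the reference
genes' Cq — identical to a geometric-mean normalisation factor in linear
space, and consistent with single-reference use when one gene is chosen.
ΔCq = Cq_target − Cq_ref; ΔΔCq subtracts the calibrator group's mean ΔCq
(a per-sample calibrator is available via `calibrator_sample`); relative
expression is E^−ΔΔCq. Contracts, all tested exactly: a global per-sample
Cq shift cancels; the calibrator group's geometric mean is 1 per gene;
with E = 2, log2 of the output equals −ΔΔCq.

## Biomarker evaluation

Group differences use one-way ANOVA (textbook between/within sums of
squares; constant data yield F = 0, p = 1 rather than NaN) plus pairwise
Welch t tests against the control group with Holm adjustment within gene.

ROC analysis is empirical: the curve runs over all distinct thresholds,
and the AUC by trapezoid equals the Mann–Whitney estimator with ties
counted ½ (asserted to 1e−12 on a thousand random instances). Confidence
intervals and the p value against AUC = 0.5 use DeLong's paired
nonparametric variance from placement values; a stratified bootstrap is
available for very small samples. At n = 20/20 the asymptotic DeLong
interval shows the known mild undercoverage (≈ 93 % empirical for a
nominal 95 %), which stays within the ± 3-point calibration band we test.
Because the motivating biomarkers *fall* in disease, orientation `"auto"`
flips the score sign when the raw AUC is below 0.5 and records the flip —
an inverted AUC is never silent. The Youden-optimal cutoff maximises
J = sensitivity + specificity − 1 over midpoints between adjacent distinct
scores (sentinels beyond the range included); ties prefer higher
sensitivity, then the lower cutoff; all-equal scores give the degenerate
(100 %, 0 %) point with J = 0.

Covariate-adjusted association with a continuous outcome (BMD) is
implemented as partial correlation: regress marker and outcome on the
covariates with intercept, Pearson-correlate the residuals, and test with
t = r√(df/(1−r²)), df = n − 2 − k. With k = 0 this is exactly Pearson;
collinear covariates are rejected by name. The alternative reading of
"multiple correlation with adjustment" — the multiple-R of a joint
regression — answers a different question (variance explained by marker
plus covariates jointly) and was deliberately not chosen: the partial r
isolates the marker's own association, which is the quantity a biomarker
claim needs. Note that when a covariate (age, say) almost separates the
groups, adjustment legitimately absorbs group-driven signal; that is a
feature of the question being asked, not a bug.

## The synthetic-data generator

`simulate_cq_study()` draws Cq_gj = base_g + load_j + effect_g(group_j) +
ε_gj, with ε ~ N(0, σ²_g) and a per-sample load shift load_j ~ N(0,
load_σ²) shared by all genes — normal noise on the Cq scale is the
multiplicative error model qPCR assumes. Hemolysis affects only the
RBC-marker gene (its Cq drops by a uniform draw from 3–8 cycles in a
configured fraction of samples), which isolates what the QC test must
detect. The spike-in ignores load and group effects, mimicking its
addition in fixed quantity after collection. Covariates follow per-group
normal models and BMD is a linear function of group plus noise. Presets:
`"ovx_rat"` (2 × 8), `"clinical"` (19/7/10 with age/weight/height and
BMD; group BMD and age means follow typical postmenopausal cohorts;
weight ~ N(62, 8) kg and height ~ N(158, 6) cm are generic cohort
values), `"bedrest_monkey"` (9/6). Defaults: load_σ = 0.5 cycles,
hemolysis fraction 5 %, marker gap 5.5 cycles, spike-in σ = 0.1 cycles.

What the generator does *not* emulate: plate/positional effects,
amplification-efficiency differences between assays, non-normal heavy
tails, correlated miRNA co-regulation, and missingness mechanisms
(undetermined wells must be injected explicitly). Passing tests on this
generator therefore demonstrate algorithmic correctness and statistical
calibration under the stated model, not robustness to every artefact of
real serum data.

## Numerical and design choices

* Amplification efficiency fixed at E = 2 unless overridden; the Q
  transform anchors each gene's maximum at 1, so Cq differences only ever
  enter as within-gene contrasts.
* Missing Cq: stability analysis requires complete profiles (pairwise
  log-ratios demand them), so genes with missing values are dropped with a
  message; `read_cq_table()` alternatively imputes the max cycle number.
  Both policies are exposed because there is no principled universal
  choice for "undetermined" wells.
* Tie-breaking is deterministic everywhere, with input order as the final
  fallback.
* Variance estimates floored at zero; degenerate inputs (constant
  matrices, single-class labels, empty calibrators) either take documented
  defined values or fail fast with named errors.
* Problem sizes used by the test suite and acceptance script — 100
  matrices for the geNorm oracle, 100 seeds for NormFinder recovery, 200
  end-to-end runs, 500 coverage replicates, 1000 ROC instances, 2000 null
  genes — were chosen to keep Monte-Carlo error comfortably inside each
  tolerance.

## Limitations

The stability algorithms assume complete, roughly log-normal data and a
candidate panel without a common group shift (see the identifiability
caveat above). DeLong intervals are asymptotic and mildly anticonservative
below ~20 per class; use the bootstrap there. The DE filter mirrors
screening practice (raw p plus fold change) and makes no multiplicity
claim. Efficiency correction beyond a single global E (standard-curve /
per-assay efficiencies) is out of scope.
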