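# mirnorm

Reference-gene stability and biomarker evaluation for serum miRNA qPCR
studies.

Circulating miRNAs are promising non-invasive disease markers (the
motivating application is osteoporosis: estrogen-deficiency and
mechanical-unloading bone loss), but qPCR quantification of serum miRNA is
only as good as its normalisation. There is no universal endogenous control
for serum, so every study must screen its own candidate reference genes,
rank their stability, and only then quantify targets and judge their
diagnostic value. `mirnorm` implements that workflow end to end for R
users working with Cq (quantification-cycle) tables:

* **Sample QC** — hemolysis index ΔCq = Cq(miR-23a-3p) − Cq(miR-451a), with
  the strict pass rule ΔCq < 7 cycles, and a spike-in (cel-miR-39)
  consistency check (|Cq − median| ≤ 1.5 cycles by default).
* **Candidate screening** — from a linear intensity matrix, genes that are
  (1) highly expressed in all samples, (2) not differentially expressed
  between groups (Welch t on log2 intensities, p > 0.05), and (3) of low
  coefficient of variation within and between groups. Differential
  expression uses the classic FC ≥ 2 and p ≤ 0.05 filter.
* **Stability ranking** — geNorm (M_j = mean over partners k of the SD of
  log2 Q_j/Q_k; stepwise exclusion; pairwise variation V(n/n+1) with the
  0.15 heuristic for the optimal number of references) and NormFinder
  (model-based decomposition into intragroup variance σ²(i,g) and
  intergroup deviation d(i,g), stability = mean over groups of |d| +
  √(σ²/n)), aggregated into a comprehensive rank by the geometric mean of
  the two ranks.
* **Relative quantification** — 2^−ΔΔCt against one or more reference
  genes, calibrated to a control group (or sample).
* **Biomarker evaluation** — one-way ANOVA plus Welch/Holm pairwise tests,
  empirical ROC curves with DeLong 95% CIs and p vs AUC = 0.5,
  Youden-optimal cutoffs with sensitivity/specificity, and
  covariate-adjusted partial correlation with a continuous outcome such as
  bone mineral density.
* **Synthetic studies** — a generator for Cq studies with per-sample load
  shifts, gene-specific noise, group effects, hemolysis contamination and
  spike-ins, with exported ground truth; presets `"ovx_rat"`, `"clinical"`,
  `"bedrest_monkey"`.

## Worked example

```r
library(mirnorm)

sim <- simulate_cq_study(preset_config("clinical", seed = 42))
qc  <- qc_report(sim$cq)                    # 34/36 samples pass QC
cq  <- qc_filter(sim$cq, qc)
ann <- sim$annotation[sim$annotation$sample_id %in% colnames(cq), ]

fit <- reference_stability(cq, ann, genes = sim$truth$reference_genes)
summary(fit)
#> Recommended reference gene (comprehensive rank 1): miR-25-3p
#> geNorm most stable pair: miR-25-3p + miR-140-5p
#> Pairwise variation series:
#>    V2/3    V3/4    V4/5    V5/6    V6/7    V7/8    V8/9
#> 0.12670 0.11550 0.10310 0.08400 0.07542 0.08072 0.09079
#> Optimal number of reference genes: 2

rel <- delta_delta_ct(cq, c("miR-30b-5p", "miR-103-3p"),
                      refs = fit$table$gene[1], ann = ann,
                      calibrator = "normal")
roc_analysis(rel$rel_expr["miR-30b-5p", ], ann$group != "normal")
#> ROC analysis (16 cases vs 18 controls, low scores predict case)
#> AUC = 0.986 (95% CI 0.960-1.000, p = 3.39e-286, delong)
#> Optimal cutoff (Youden): case if score <= 0.6911; sensitivity 100.0%,
#> specificity 88.9%, J = 0.889
```

The stability summary says miR-25-3p is the most reliable normaliser in
this simulated cohort and that two reference genes suffice (first V value
below 0.15). The ROC output reads: the biomarker's relative expression
separates bone-loss cases from controls with AUC 0.986, and calling
"case" whenever normalised expression falls at or below 0.69 catches every
case while keeping 88.9 % of controls negative. `adjusted_correlation()`
relates expression to BMD after removing age, weight and height — note
that in cohorts where age alone separates the groups, adjustment
legitimately absorbs most of the group-driven signal.

The same pipeline runs from a shell via the thin wrapper:

```sh
exec/mirnorm simulate --preset clinical --seed 1 --out-dir sim/
exec/mirnorm run --config pipeline.yaml
```

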