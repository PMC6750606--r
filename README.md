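# omegacmr

Quantitative cardiac MR tissue characterization and genotype-stratified
omega-3 trial analysis after acute myocardial infarction.

## The problem

Adverse left-ventricular remodeling after an acute myocardial infarction is a
key driver of heart failure. Trials of high-dose omega-3 fatty acids track it
with quantitative CMR — the 6-month change in LV end-systolic volume index
(LVESVi), diffuse non-infarct fibrosis by extracellular volume fraction
(ECV), and infarct size on late gadolinium enhancement (LGE) — and the
therapeutic response plausibly depends on FADS2 (rs1535) genotype, because
the delta-6 desaturase it encodes controls conversion of dietary precursors
into active arachidonic and eicosapentaenoic acids. `omegacmr` provides the
full analysis chain for such a study, for imaging scientists and trial
statisticians:

* **Relaxometry** — per-segment Look-Locker inversion-recovery fitting,
  `S(TI) = A − B·exp(−TI/T1*)`, with the correction `T1 = T1*·(B/A − 1)`.
* **ECV mapping** — OLS of myocardial R1 = 1/T1 on blood-pool R1 across
  contrast states; pairs with blood R1 ≥ 3.5 s⁻¹ are excluded
  (fast-water-exchange failure); `ECV = λ·(1 − HCT)`; non-infarct ECV is the
  mean over LGE-negative AHA segments.
* **Infarct quantification** — threshold at remote mean + 2 SD, mass in grams
  and % of LV mass at 1.05 g/mL.
* **Lipid genetics** — omega-3 index (EPA% + DHA%), ArA/LA
  desaturase-activity surrogate, allele frequencies and the Hardy-Weinberg
  chi-square.
* **Trial statistics** — genotype-stratified 6-month changes with Welch or
  pooled t-tests, responder odds ratios for ≥ 10 % LVESVi improvement,
  Spearman correlations of fatty-acid changes with remodeling, ANOVA /
  chi-square baseline comparisons, Bonferroni-adjusted paired Wilcoxon visit
  tests, racial-subgroup filtering, median splits, biomarker–CMR regression.
* **Synthetic data** — imaging phantoms and trial cohorts with embedded
  ground truth, so every stage is testable end to end without patient data.

## Worked example

```r
library(omegacmr)

# 1. fit a segment's inversion-recovery curve and correct it
ti  <- seq(0.1, 3.0, by = 0.2)
fit <- fit_inversion_recovery(ir_curve(ti, 1000 - 1800 * exp(-ti / 1.5),
                                       label = "seg01"))
fit
#> <ir_fit 'seg01': A=1000 B=1800 T1*=1.5 s T1=1.2 s SSE=0 conv=TRUE>

# 2. ECV from serial R1 pairs; the 1-minute pair (blood R1 4.5) is excluded
p <- r1_pairs(c(0.53, 2.22, 1.67, 1.25, 4.5),
              c(0.83, 1.80, 1.48, 1.25, 2.9),
              c("pre", "5min", "15min", "25min", "1min"))
estimate_ecv(p, hct = 0.40)
#> <ecv_fit: lambda=0.5725 ECV=0.344 (HCT=0.400, n=4, 1 excluded)>

# 3. genotype distribution check
hwe_chi_square(genotype_table(156, 122, 34))
#> <hwe_test: chi-square=1.840 df=1 p=0.175>

# 4. stratified treatment effect in a large synthetic cohort
sc <- generate_cohort(cohort_config(n_patients = 40000, freq_g = 0.5, seed = 1))
stratified_effect(sc$cohort, "lvesvi", genotype = "GG")
#> <stratified_effect lvesvi/GG: drug -4.30+/-5.59 (n=4954) vs placebo 1.17+/-4.17 (n=4940), p=0>
responder_odds(sc$cohort, genotype = "GG")
#> <responder_odds (>=10% LVESVi improvement): drug 1.07 (2560/2394), placebo 0.134 (585/4355), OR=8.0>
```

The fitted T1 of 1.2 s is a typical native myocardial value at 3 T; the ECV
of 0.344 sits in the diffuse-fibrosis range seen after infarction, and the
excluded pair shows the blood-R1 guard working. In the synthetic GG stratum
the drug arm loses ≈ 4.3 mL/m² of LVESVi while placebo gains ≈ 1.2 — the
generator's configured genotype-dependent treatment effect, recovered by the
stratified estimator — and the responder odds ratio is correspondingly large.

An end-to-end run (phantom → T1 → ECV → infarct → cohort → stratified
tables + JSON report):

```r
run_pipeline(run_config(outdir = "out", seed = 1))
```

or from a shell, `Rscript inst/scripts/run-pipeline.R --seed 1 --outdir out`
(use `--cohort-csv` / `--column-map` to analyse an external cohort table
instead of simulating one).

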