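---
title: "Methods: quantitative CMR tissue characterization and genotype-stratified trial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative CMR tissue characterization and genotype-stratified trial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omegacmr)
```

## Scope

`omegacmr` implements the quantitative analysis chain used in post-infarction
remodeling trials that combine cardiac MR tissue characterization with
pharmacogenetic stratification: segment-level T1 relaxometry, extracellular
volume fraction (ECV) mapping, infarct quantification on late gadolinium
enhancement (LGE), red-cell fatty-acid indices with rs1535 (FADS2) genotype
handling, and the stratified treatment-effect statistics that compare a
high-dose omega-3 arm against placebo within each genotype. A synthetic
phantom-and-cohort generator with embedded ground truth makes every stage
testable without patient data.

## Relaxometry

Each Look-Locker acquisition yields, per myocardial segment and for the blood
pool, an average signal intensity at a series of inversion times. The package
fits the three-parameter inversion-recovery model

$$S(TI) = A - B\,e^{-TI/T_1^*}$$

by bounded nonlinear least squares (Levenberg–Marquardt via `minpack.lm`),
then applies the Look-Locker correction

$$T_1 = T_1^*\,(B/A - 1),$$

which compensates for the apparent shortening of relaxation under repeated
small-angle readouts. Choices that matter:

* **Units.** Seconds everywhere internally. The blood-pool exclusion rule is
  stated in s^-1^, so R1 in s^-1^ and T1 in seconds keep every formula
  unit-free of conversions; readers of millisecond data should divide by
  1000 on input.
* **Initialisation.** `A0 = max(signal)`, `B0 = max - min`,
  `T1*0 = median(TI)`, with `T1*` bounded to (0, 10] s. For physiologic T1
  (roughly 0.2–2.5 s at 3 T) these are within the basin of attraction in all
  generated cases; the convergence flag is reported rather than raised so a
  pipeline over many segments can audit failures afterwards.
* **Tolerance.** The LM iteration runs to a relative SSE change of 1e-12
  (tighter than the 1e-9 contract) so that noise-free phantoms are recovered
  to better than 1e-6 relative error.
* **Polarity.** The model is fit to signed signals. Magnitude data with
  polarity restoration is a different estimation problem and is out of scope;
  the generator produces signed signals accordingly.
* **Resolution.** Fitting is per segment-averaged curve, not per pixel;
  pixel-wise mapping is a non-goal.

The correction is undefined when `A <= 0` or `B <= A` (a non-physical
recovery); `correct_look_locker()` raises a domain error, and a fit whose
optimum lands there reports `t1 = NA` rather than a fabricated value.

## ECV mapping

With gadolinium as an extracellular tracer in fast water exchange, myocardial
R1 = 1/T1 is linear in blood R1 across contrast states, with slope equal to
the contrast partition coefficient $\lambda$:

$$R_{1,\mathrm{myo}} = \lambda\,R_{1,\mathrm{blood}} + c, \qquad
  \mathrm{ECV} = \lambda\,(1 - \mathrm{HCT}).$$

`fit_partition_coefficient()` regresses myocardial on blood R1 (OLS with an
intercept — the protocol fits a regression line, not a ratio) over the
pre-contrast and serial post-contrast pairs, excluding pairs whose blood R1
is **not below 3.5 s^-1^**: at high blood gadolinium concentration the
fast-exchange assumption fails and retaining those pairs biases $\lambda$
(and hence ECV) downward. The boundary is read literally — exactly 3.5 s^-1^
is excluded. Excluded pairs are returned for audit, never silently dropped.
At least two retained pairs are required; the module accepts any pair set and
leaves per-patient versus per-segment pooling to the caller.

ECV outside [0, 1] is non-physical; it is flagged with a warning and
returned unclipped, because silent clipping would hide calibration problems.
`aggregate_noninfarct_ecv()` averages ECV over LGE-negative segments of the
AHA 16-segment model to give the global non-infarct (diffuse fibrosis)
estimate.

## Infarct quantification

`segment_infarct()` thresholds myocardial pixels at

$$\mathrm{mean}(\mathrm{remote}) + k\cdot\mathrm{SD}(\mathrm{remote}),
  \qquad k = 2 \text{ by default},$$

with the sample SD (n−1) of an explicit remote-myocardium mask, classifying
intensities **at or above** the threshold as infarct (the inclusive reading
of "≥ 2 SD"). Mass is pixel count × pixel area × slice thickness × density,
with myocardial density 1.05 g/mL — the standard literature value, used
because the acquisition protocol does not state one. No connectivity or
feature-size filtering is applied. A remote region with zero SD is
degenerate and raises an error rather than producing an infinite-precision
threshold.

## Fatty-acid indices and genotype handling

* **Omega-3 index**: EPA% + DHA% of total RBC fatty acids, as delivered by
  the assay; no re-normalisation is applied.
* **Desaturase-activity surrogate**: the product/precursor ratio ArA/LA.
  rs1535 G is the minor allele; G carriers desaturate less, so the expected
  ordering is AA > AG > GG.
* **Hardy-Weinberg check**: the 1-df asymptotic chi-square comparing observed
  genotype counts with n·p², 2npq, n·q² from the observed allele
  frequencies. This is the standard test, but exact and asymptotic HWE
  p-values can differ noticeably at modest minor-allele counts, so the
  package reports the statistic and its asymptotic p-value and leaves any
  exact-test comparison to the analyst. Expected cells below 1 attach a
  warning.

## Trial statistics

All endpoint analyses are complete-case on absolute 6-month changes
(`followup - baseline`); exclusion counts are reported. Design choices, each
configurable:

* **t-test flavour**: Welch by default (robust to unequal arm variances),
  pooled-variance Student as an option.
* **Responder**: relative improvement `(baseline - followup)/baseline >= 10%`.
  The 10% criterion could also be read as absolute; relative is the common
  remodeling-trial convention and the fraction is a parameter.
* **Odds ratios**: per-arm odds responders/non-responders, OR =
  odds~drug~/odds~placebo~. Zero non-responder cells give infinite odds,
  flagged; the Haldane–Anscombe 0.5 correction is available but off by
  default so the arithmetic matches published per-arm odds exactly.
* **Log transforms**: natural log, applied to changes as
  `log(followup) - log(baseline)`; non-positive values are excluded with
  bookkeeping.
* **Multiplicity**: Bonferroni only in the paired visit tests
  (`paired_visit_test()`, p × comparisons capped at 1), matching a design
  where only the per-subgroup visit comparisons were adjusted; stratified
  contrasts are reported unadjusted at the 0.05 convention.
* **Correlations**: Spearman between fatty-acid changes and the LVESVi
  change; invariant to monotone transforms, ties handled by midranks.
* **Subgroups**: `subgroup_filter()` restricts to one racial category
  (sensitivity analysis in the predominant subgroup); `median_split()`
  dichotomises at the median with ties assigned to "low".

## The synthetic generators

### Phantom

`generate_phantom()` draws IR curves from the signal model with configured
T1s at a fixed B/A (default 1.8 — a typical effective inversion under
Look-Locker readout; any value > 1 behaves identically after correction).
Blood T1 defaults (1.9 s pre-contrast; 0.45/0.60/0.80 s at 5/15/25 min
post-contrast at 3 T) keep blood R1 below 3.5 s^-1^; myocardial R1 is
generated **exactly on** the line $\lambda R_{1,\mathrm{blood}} + c$
(default $\lambda = 0.57$, c chosen so native myocardial T1 is 1.2 s, HCT
0.40, hence ECV = 0.342, i.e. 34.2% — the diffuse-fibrosis range seen after
infarction). An optional 1-minute timepoint has blood R1 = 4.5 s^-1^ and a
myocardial R1 generated *off* the line (attenuated to 80% of the linear
prediction) to emulate the fast-exchange failure the exclusion rule guards
against: a correct pipeline recovers $\lambda$ exactly anyway.

The LGE slice is an annulus on a 32×32 grid with a planted 90° infarct
sector at remote mean + 6 SD. The remote sector carries a deterministic
±1 SD alternating texture, so its sample SD is positive even in the
noise-free configuration — this is what makes the noise-free closure test
exact (threshold = mean + 2·SD sits strictly between normal myocardium and
the planted infarct). Gaussian noise is added on top when configured.

Not emulated: motion, partial-volume and surface-coil shading artifacts,
B1/inversion-efficiency errors, pharmacokinetic contrast dynamics. Passing
tests therefore demonstrate correctness of the estimation chain, not
robustness to acquisition artifacts.

### Cohort

`generate_cohort()` draws, per patient: genotype from Hardy-Weinberg
proportions at the configured minor-allele frequency (default 190/624, the
allele frequency implied by the published 156/122/34 split); arm at the
configured randomisation ratio; ArA/LA from Normal(2.01/1.76/1.62, 0.35) by
genotype; and a 6-month change for every endpoint from
Normal(mean~genotype,arm~, sd~genotype,arm~) with the published stratified
change summaries as defaults. Baselines come from log-normal or Normal
distributions matched to the published baseline tables (e.g. LVESVi median
≈ 35–38 mL/m² by genotype, NT-proBNP median ≈ 470 pg/mL). Only the GG
biomarker-change cells are pinned by published summaries; the AA/AG cells
default to arm-similar values consistent with the published overall-cohort
means, chosen once and documented here.

Drug-arm EPA and DHA rises (defaults +2.0% and +2.2% of RBC fatty acids,
versus ≈ 0 under placebo) share a Gaussian-copula latent variable with the
LVESVi change: for a target Spearman $\rho_s$ the latent correlation is
$2\sin(\pi\rho_s/6)$. The O3I rise is EPA + DHA, so its coupling is implied
rather than separately configured. Because the observed whole-cohort rank
correlation also contains the between-arm separation (placebo patients rise
little and remodel differently), the achieved correlation differs from the
residual-scale target and is verified empirically in the tests, never
assumed.

Two deliberate unrealisms: endpoint changes are drawn independently of
baseline (so a small baseline infarct can yield a negative follow-up size,
and large NT-proBNP reductions can occur at small baselines — such records
are retained so that the configured change distributions stay exact, while
ingest validation of *external* cohorts enforces non-negativity); and
endpoints are mutually independent within patient apart from the configured
fatty-acid coupling, because within-patient cross-endpoint correlations are
not published. Both limit how far cohort-level realism claims can go; they
do not affect estimator correctness, which is what the closure and recovery
tests establish.

Each generator consumes a single integer seed and one generator stream, so
regeneration with an identical configuration is bit-identical.

## Numerical and testing choices

* Noise-free closure: IR parameters to 1e-6 relative, $\lambda$ to 1e-8,
  infarct mask exact equality.
* Statistical cross-checks run against independently coded oracles:
  closed-form OLS sums, direct $\sum(O-E)^2/E$ arithmetic, the textbook
  Welch t with Welch–Satterthwaite df, Pearson-on-midranks for Spearman,
  and exact signed-rank enumeration over all $2^n$ sign assignments at
  n = 8.
* Recovery studies use 100 phantom replicates at 4 segments and 1% signal
  noise, and stratified cohorts of 40,000 patients at minor-allele
  frequency 0.5 (≥ ~5,000 per genotype × arm cell) — sizes at which
  Monte-Carlo error is well below the effects of interest while a full test
  run stays fast.
* `run_pipeline()` writes tidy CSV intermediates and a JSON report carrying
  the package version, seed and a config hash, with no timestamps, so a
  rerun with the same configuration is byte-identical.

## Known limitations

Segment-average (not pixel-wise) relaxometry; signed-signal fitting only;
single-compartment fast-exchange ECV outside the exclusion rule; 2-SD
thresholding only (no FWHM family); no covariate adjustment, interaction
tests or longitudinal modelling — the stratified contrasts mirror a
stratum-wise post-hoc design; the asymptotic HWE test only. External
spreadsheet ingest requires an explicit column map because deposited column
vocabularies vary; validation flags internally inconsistent records rather
than correcting them.
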