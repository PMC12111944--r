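---
title: "Methods: non-invasive steatosis and fibrosis assessment with hepindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-invasive steatosis and fibrosis assessment with hepindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepindex)
```

## The clinical problem

Metabolic dysfunction-associated steatotic liver disease (MASLD) is the
most common chronic liver disease, and the patients who need specialist
referral are those with significant steatosis (grades S2–S3) and, above
all, severe fibrosis (stages F3–F4). Liver biopsy is impractical as a
screening tool, so the work-up rests on cheap blood- and
anthropometry-based indices, with vibration-controlled transient
elastography (VCTE) as the non-invasive reference: the controlled
attenuation parameter (CAP, dB/m) proxies liver fat, and liver stiffness
(kPa) proxies fibrosis.

`hepindex` implements that pipeline end to end: the five index
calculators, elastography-based grading/staging, eligibility screening,
ROC-based cut-off derivation, and a two-stage classification cascade that
uses metabolic indices (TyG, VAI) to shrink the indeterminate "grey zone"
left by the conventional fibrosis scores (NFS, FIB-4). A calibrated
synthetic cohort generator makes the whole pipeline testable without
patient-level data.

## Indices and their units

For a subject with fasting glucose FBG and triglycerides TG (both mg/dL),
waist circumference WC (cm), BMI (kg/m²), HDL cholesterol (mmol/L where
molar, mg/dL as measured), the package computes:

* **TyG** $= \log(\mathrm{FBG} \times \mathrm{TG} / 2)$. The logarithm
  base is an explicit parameter (`tyg_base`), default natural. Published
  TyG cut-offs vary widely between sources, largely because of
  inconsistent base conventions; rather than silently adopting one, the
  calculator exposes the choice. All rank-based quantities downstream
  (Spearman correlations, ROC curves, AUROC, and therefore the cascade
  thresholds' ordering) are identical under either base, because the two
  scales differ by the positive constant $\ln 10$.
* **VAI** (sex-specific), e.g. for men
  $\frac{WC}{39.68 + 1.88\,BMI}\cdot\frac{TG}{1.03}\cdot\frac{1.31}{HDL}$
  with TG and HDL in mmol/L; at the anchor constants every factor is 1.
* **LAP** $= (WC - 65)\times TG$ for men, $(WC - 58)\times TG$ for women
  (TG in mmol/L). A waist below the anchor gives a non-positive value,
  which is returned with a warning rather than masked.
* **NFS** $= -1.675 + 0.037\,\mathrm{age} + 0.094\,BMI +
  1.13\,[\mathrm{IFG/diabetes}] + 0.99\,AST/ALT - 0.013\,\mathrm{PLT} -
  0.66\,\mathrm{albumin}$, albumin in g/dL. (Cohort tables sometimes label
  albumin "mg/dL" with values near 3–4; those magnitudes are only
  physiologic on the g/dL scale, which is what the score expects and what
  the package assumes.)
* **FIB-4** $= \mathrm{age}\times AST / (\mathrm{PLT}\times\sqrt{ALT})$.

Laboratory TG and HDL arrive in mg/dL; the package converts with the
molar factors 88.57 and 38.67 mg/dL per mmol/L inside `compute_panel()`.
Indices are computed per subject only when every input is present — a
missing input yields an explicit `NA`, never an imputed or zero value.

## Grading, staging and eligibility

CAP maps to steatosis grades with lower-bound-inclusive cut-offs
S1 ≥ 294, S2 ≥ 310, S3 ≥ 331 dB/m (S2–S3 = significant steatosis), and
stiffness to fibrosis stages with F2 ≥ 8.2, F3 ≥ 9.7, F4 ≥ 13.6 kPa
(F3–F4 = severe). A VCTE examination is reliable when IQR/median < 30%
over at least 10 valid readings.

Eligibility screening is deliberately a *separate* operation from
severity grading: the steatosis screen for MASLD inclusion is CAP
> 248 dB/m (and/or positive ultrasound), which sits *below* the S1
boundary — a subject can be steatotic for inclusion purposes yet grade
S0 on the severity scale. CAP exactly 248 satisfies neither the strict
`>` inclusion nor the strict `<` control rule and is classified
ineligible. Exclusions (toxic alcohol intake, aminotransferases above
five times the upper limit of normal — ULN configurable, default 40 U/L,
since no single ULN convention is universal) are evaluated first and
recorded as machine-readable reasons. Because the subject record carries
a combined IFG-or-diabetes flag (the NFS input) rather than a diabetes
diagnosis, eligibility infers type 2 diabetes from FBG ≥ 126 mg/dL or
HbA1c ≥ 6.5%, the standard diagnostic thresholds; isolated impaired
fasting glucose counts only as a cardiometabolic risk factor.

## The two-stage grey-zone cascade

Stage 1 applies the published NFS/FIB-4 rules jointly: rule out severe
fibrosis when NFS ≤ −1.455 **and** FIB-4 ≤ 1.3; rule in when NFS > 0.676
**and** FIB-4 > 2.67; everything else is the grey zone. Stage 2
re-examines only grey-zone subjects with the TyG/VAI severe-fibrosis
cut-offs (rule-in 5.61 / 6.21, rule-out 2.65 / 1.67). Two design choices
were genuinely open:

* **Combination rule at stage 2.** The source material states that TyG
  *and* VAI were used without specifying the logic. The default is
  `both` (conjunction), mirroring the explicit AND of stage 1; `either`
  is available, and conflicting signals (one index ruling in while the
  other rules out) are always left unclassified.
* **Boundary convention.** Rule-out comparisons are inclusive (`<=`),
  rule-in strict (`>`), exactly as printed for NFS/FIB-4, and applied
  uniformly to TyG/VAI.

Stage 2 never relabels a stage-1 classified subject, so the unclassified
fraction can only fall. Two practical points: the cascade runs on
whatever analysis set it is given (e.g. the significant-steatosis
subgroup) rather than hard-coding a cohort filter, and the stage-2
cut-offs live on the decimal-like TyG scale on which published TyG
cut-offs in the 2.65–5.61 range are quoted — a panel computed with the
natural-log default sits near 8–10 and will trivially exceed the TyG
rule-in bound, so compute the panel with `tyg_base = "decimal"` (or
supply rescaled cut-offs) when applying these published constants to
real data. `evaluate_cascade()` judges correctness against
the elastography reference (rule-out correct ⇔ reference below F3,
rule-in correct ⇔ F3–F4, stage-2 counts pooled) and all rendered
percentages are one-decimal, rounded half-up — a single convention
applied everywhere, including cells where source tables round
inconsistently.

## ROC machinery

`roc_curve()` uses the empirical convention *positive call = score ≥
threshold*; the AUC is the Mann–Whitney concordance probability with
ties counted ½ (midranks). The optimal cut-off maximises Youden's
Se + Sp with ties broken toward the lower threshold. Rule cut-offs are
explicit constrained scans: rule-out maximises specificity subject to a
sensitivity floor (default 0.80), rule-in maximises sensitivity subject
to a specificity floor (default 0.74); the floors are parameters because
sources rarely state them, and the defaults are consistent with the
sensitivity/specificity ranges that published severe-fibrosis cut-off
tables exhibit. Degenerate thresholds whose optimised quantity is zero
(a rule-in that calls nobody) are never returned. Paired AUCs are
compared with the DeLong covariance construction; proportions get Wilson
intervals; Spearman correlations get Fisher-z intervals. These interval
choices are stated here because the source analysis names none. No
multiple-testing correction is applied, matching the source analysis.

Group comparisons follow the stated routing rule: Kolmogorov–Smirnov
normality gate per group, Student's t-test when both pass, Mann–Whitney
otherwise, Pearson's χ² for categorical variables; the report records
which test ran. Backward-stepwise logistic regression removes the
largest-Wald-p predictor while p > 0.10, stopping if AIC worsens by more
than the usual two-unit indistinguishability band — the strict "never
worsens" variant would make predictors with p ∈ (0.10, 0.157)
unremovable (their removal raises AIC), contradicting the printed
exclusion threshold. A consequence worth stating plainly: with exclusion
at p > 0.10, each pure-noise predictor *survives* with probability ≈ 0.10
by construction, so backward selection with these printed thresholds
cannot remove all of several noise predictors much more than ~73% of the
time (0.9³ for three), and the test suite's selection-consistency check
documents this honestly rather than overstating the procedure's
consistency.

## The synthetic cohort generator

No subject-level data are distributable, so the generator emulates the
*statistical structure* of the study cohort (n = 178, 55.1% male):

* **Marginals** (whole-cohort): normal for age 52.79 ± 12.56, BMI
  31.4 ± 5.3, waist 109.1 ± 11.4, HDL 44.3 ± 10.6, platelets 225 ± 38.7,
  albumin 3.3 ± 1.23, cholesterol 203.2 ± 46.6, LDL 149 ± 32.8;
  log-normal (moment-matched) for TG 198.2 ± 148.9, AST 42.3 ± 23.7,
  ALT 53.1 ± 39.6; log-normal quantile-matched to median 114.5
  [110–120] for FBG. CAP and stiffness use stratum-wise inverse CDFs so
  the steatosis (0.31, 0.05, 0.213, 0.427) and fibrosis (0.455, 0.27,
  0.174, 0.101) prevalence vectors hold in expectation, uniform within
  stratum bins (stiffness capped at 35 kPa — a realistic ceiling for a
  metabolic-disease cohort well inside the 75 kPa device limit).
  Physiologic bounds are enforced by clipping, and clip counts are
  recorded.
* **Dependence** is a Gaussian copula. Pairwise targets are stated as
  Spearman correlations and converted exactly to latent Pearson entries
  by $2\sin(\pi\rho_s/6)$; only pairwise rank information is published,
  so no tail-dependence structure is claimed. Indices are *not* drawn
  directly: they are computed from the generated raw measurements, so a
  correlation target like Spearman(TyG, grade) = 0.66 constrains the
  couplings of TG, FBG, HDL, WC and BMI to the latent CAP and stiffness
  axes. Those couplings (TG 0.691, HDL −0.814, WC 0.180, BMI 0.110 to
  the CAP axis; fibrosis-axis scaling 0.833; residual TG–HDL −0.364;
  CAP–stiffness 0.757) were calibrated numerically once, by Nelder–Mead
  against the six published index–severity correlations (TyG/VAI/LAP ×
  steatosis 0.66/0.76/0.61, × fibrosis 0.53/0.63/0.51), then frozen in
  the default specification. Residual pairs not structurally specified
  are filled with the one-factor product of axis couplings, which keeps
  the assembled matrix positive definite; if a user-modified
  specification is not PD it is repaired with `Matrix::nearPD()` when
  close, and rejected with an error when far. After freezing, the mean
  absolute deviation of the six realised correlations is ≈ 0.01 at
  n = 20,000 across seeds.
* The VAI target of 0.76 is close to the structural maximum: TyG at 0.66
  pins the TG coupling, TG dominates the VAI composite's variance, and
  the remaining headroom comes almost entirely from the HDL channel,
  which is why the calibrated HDL coupling is strong (−0.81) and the
  residual TG–HDL correlation sits near its positive-definiteness bound.
* **What the generator does not emulate:** measurement error in CAP/TE,
  probe-selection effects, within-stratum CAP shape (the published
  cohort mean CAP of 322.5 dB/m reflects a right-heavy within-bin
  distribution the uniform fill does not reproduce), missingness
  mechanisms beyond none, diabetes prevalence as a separate entity from
  the FBG marginal, and any longitudinal structure. Passing calibration
  therefore shows the *pipeline* behaves correctly under the published
  dependence structure — not that the generator is a digital twin of the
  study population.

Determinism: identical specification and seed give byte-identical
tables; the generator saves and restores the caller's RNG state.

## Problem sizes and numerical choices

The shipped checks use n = 5,000 for calibration assertions (±0.05 on
rank correlations; at that n the Monte-Carlo standard error of a
Spearman estimate is below 0.015), n = 20,000 × 3 seeds for the
convergence check, 1,000 replicates at n = 200 for the DeLong type-I
experiment, and 100 replicates at n = 2,000 for selection consistency —
sizes at which the assertions are stable across seeds while the whole
suite runs in seconds. Formula calculators are validated against
independent transcriptions at 10⁻⁹ relative error on 1,000 random
inputs; ROC quantities against exhaustive brute-force scans on fixtures
of up to 50 subjects, where enumeration is exact.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(default_cohort_spec(), seed = 1, n = 178)
panel <- compute_panel(co)
staged <- stage_cohort(co)

# discrimination of significant steatosis
roc <- roc_curve(panel$vai, staged$significant_steatosis)
optimal_cutoff(roc)

# two-stage severe-fibrosis cascade
res <- run_cascade(panel)
evaluate_cascade(res, staged)
```

## Known limitations

* The cascade's cut-offs are constants from a single derivation cohort;
  the package applies them, it does not revalidate them.
* The eligibility module covers only the rules expressible from the
  tabular record (alcohol, aminotransferases, steatosis evidence,
  metabolic criteria); chart-only exclusions (viral hepatitis,
  malignancy, cardiac congestion) must be applied upstream.
* Rule cut-off floors are conventions, not estimates; report them with
  any derived thresholds.
* The generator reproduces first- and second-order structure only
  (marginals plus pairwise rank dependence).
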