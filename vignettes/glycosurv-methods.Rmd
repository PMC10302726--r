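---
title: "Methods: plasma glycoproteomic survival-biomarker modelling in glycosurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma glycoproteomic survival-biomarker modelling in glycosurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`glycosurv` implements an end-to-end analysis for targeted plasma
glycoproteomics panels measured by scheduled MRM mass spectrometry in a
survival cohort — the setting of pre-treatment plasma profiling of
metastatic melanoma patients receiving immune checkpoint inhibitors (ICI).
The package covers quantification (drift correction, internal-standard
calibration, relative abundance, site occupancy, concentration
normalization), glycan-structure feature engineering (fucosylation,
sialylation, occupancy-weighted monomer weights), univariate Cox screening
with FDR control, a repeated cross-validated L1-penalized Cox classifier
dichotomized at a concordance-maximizing risk-score threshold, and layered
Kaplan–Meier / hazard-ratio evaluation. A synthetic-cohort simulator with
planted hazard effects makes every stage testable without raw MS data.

Peak integration, chromatography and pathway enrichment are out of scope:
raw per-analyte abundances are the package's atomic input.

# Quantification model

Each protein in the panel carries one designated non-glycosylated
*reference peptide* paired with a spiked stable-isotope heavy standard.
With light intensity $L$, heavy intensity $H$ and known spike amount $s$,
the peptide concentration is the single-point calibration
$C_\mathrm{pep} = (L/H)\,s$.

Glycopeptides are normalized according to how many glycan species are
observed at their site:

* **Site occupancy** (more than two species at the site): the fractional
  abundance $\mathrm{occ}_g = I_g / \sum_{g'} I_{g'}$ over all species at
  the site. Occupancies at a site sum to 1 by construction.
* **Relative abundance** (one or two species): the ratio of the
  glycopeptide intensity to the reference-peptide intensity.

The *approximate glycopeptide concentration* ("normalized abundance") is
the product of occupancy or relative abundance with $C_\mathrm{pep}$. The
default panel structure mirrors a 596-feature assay: 443 occupancy-based
and 78 relative-abundance-based glycopeptide concentrations plus 75
peptide concentrations; the relative-abundance family additionally exposes
the ratios and occupancies themselves.

**Drift correction.** Reference pooled-plasma injections interspersed with
test samples carry no biological variance, so per analyte their trace over
injection order estimates within-run drift. The correction curve is a
piecewise-linear interpolation through the QC intensities, extrapolated
flat at the run ends; all intensities are divided by it. This choice is
deterministic, exactly inverts a linear trend, is idempotent, and leaves
post-correction QC intensities at 1. Correction is applied *before*
internal-standard normalization (an explicit pipeline-order choice; the
ratio-based features are largely insensitive to it because the shared
drift multiplier cancels in every within-injection ratio).

**Missingness.** No normalized value is fabricated: a missing or
non-positive heavy standard, reference peptide, or site aggregate makes
the derived feature missing. Imputation (median within the fitting set)
is deferred to the modelling stage.

# Glycan features

Compositions are encoded as four counts — hexose, HexNAc, fucose, sialic
acid — in a compact four-digit code (`"5402"`), with a delimited extended
form (`"H12N4F1S2"`) for counts above 9, which the digit code cannot
express. Classification (fucosylated, sialylation level, di-sialylated
O-glycopeptide) is a pure function of composition and linkage;
"complex-type" is carried as an annotation because composition alone
under-determines topology.

The **monomer weight** of a site is the occupancy-weighted expected count
of one monosaccharide, $\sum_g \mathrm{occ}_g \cdot n_{\mathrm{mono}}(g)$.
It is linear in the occupancies and bounded by the site's maximum count.
Monomer weights are computed only at occupancy-normalized sites: at one-
or two-glycan sites occupancy is undefined and renormalizing ratios would
impose an arbitrary denominator, so those sites are excluded. When
non-glycosylated forms of a site are present in the manifest they enter
the occupancy denominator. The default fucose panel takes one feature per
N-linked occupancy site (51 under the default panel).

# Outcome groups and screening

*Early failure* (EF) is death within 6 months of treatment start
(boundary inclusive); *sustained control* (SC) requires follow-up
reaching 36 months with neither progression nor death in those 36 months.
A patient censored before 36 months cannot be asserted progression-free
through month 36 and is labelled *other*; the three labels partition the
cohort.

Screening fits, per feature, a Cox proportional-hazards model with the
standardized log2 feature plus age and sex (Efron tie handling), and
reports Wald statistics for the feature coefficient, Benjamini–Hochberg
q-values across converged fits, and a scaled-Schoenfeld-residual
proportional-hazards p-value. Features are log2-transformed with a
half-minimum offset (intensity-like data are approximately log-normal;
the offset keeps zeros representable) and standardized, so hazard ratios
are per SD of the log feature. Constant features are skipped, never
imputed into significance. EF-vs-SC differential testing defaults to age-
and sex-adjusted logistic regression of group membership on the feature
(a rank-based Wilcoxon mode is available); the original study does not
name its test, so both are exposed and neither is asserted as canonical.

# Classifier

Patients are split 40/30/30 into training/validation/test within strata
of regimen × subtype × outcome group (largest-remainder rounding; strata
smaller than three patients are pooled with a warning).

The classifier is an L1-penalized Cox regression over the standardized
log2 features. The penalty path has 100 log-spaced values from the
smallest all-zero penalty down to 1% of it. The penalty is chosen to
maximize the *mean held-out Harrell concordance* of the linear predictor
over 5-fold cross-validation repeated 10 times (both counts
configurable); mean held-out partial-likelihood deviance is available as
an alternative objective. Ties prefer the larger (sparser) penalty. The
final model is refit on the full training set at the chosen penalty.

Risk scores are dichotomized into "likely" / "unlikely to benefit" at the
threshold maximizing the Harrell concordance of the *binary* indicator,
searched over all midpoints between consecutive sorted unique training
scores, ties toward the smallest threshold. Whether the original
procedure maximized the binary or the continuous-score concordance, and
on the training set or its CV folds, is ambiguous; binary/training-set is
implemented because the threshold's only purpose is to form two groups.
The threshold, penalty, feature scaling and FDR pre-filter are computed
on the training set only and reused unchanged on validation, test and
external cohorts — verified by an information-hygiene test that perturbs
held-out data and checks the serialized model is unchanged.

The fucose-model variant applies the same machinery to the site-level
fucose monomer weights that pass an FDR<0.05 univariate pre-filter on the
training set, using the same split. Age and sex are not penalized
covariates in either classifier; adjustment happens at evaluation.

With a single pre-filter survivor the fit is unpenalized (a one-feature
model needs no selection); with none, an explicit null model is returned
that scores every patient 0 and labels all as likely to benefit.

# Evaluation

Groups are summarized with events/N, Kaplan–Meier median OS (median =
smallest time with survival ≤ 0.5; "not reached" is encoded explicitly)
with complementary log-log confidence intervals, the between-group Cox
hazard ratio with Wald CI, and the log-rank p-value. Clinical covariates
are screened for retention at p<0.15 by likelihood-ratio tests both with
and without adjustment for the classifier prediction; retained covariates
enter a multivariate Cox model with conventional reference levels (LDH
<ULN, ECOG 0, M0, cutaneous, first-line, BRAF wild-type). Missing
covariate categories are kept as explicit levels by default
(complete-case analysis by flag). Nested models are compared with the
partial likelihood-ratio test; every fitted model can be checked with
scaled-Schoenfeld proportional-hazards diagnostics. Table-style outputs
report unadjusted hazard ratios; adjusted ones live in the multivariate
table.

# Synthetic cohorts

The simulator emulates the *structure* of the study data, not its
content:

* **Panel**: configurable counts of occupancy/relative-abundance
  glycopeptides and proteins; compositions sampled over hexose 3–9,
  HexNAc 2–6, fucose 0–2, sialic 0–4 (sialic ≤ HexNAc), a biologically
  plausible envelope for plasma N-glycans.
* **Abundances**: per-analyte log-normal baselines; per-patient
  biological variation (CV 0.25); shared smooth injection-order drift
  (spline through 4 knots, log-amplitude 0.15); multiplicative
  measurement noise (CV 0.10); QC-pool injections every 10 test samples
  plus both run ends (the QC cadence is unreported in the motivating
  study and is a config knob).
* **Survival**: Weibull proportional hazards by inverse-transform
  sampling (closed form, testable against the analytic median), shape
  0.6 — an early-failure-heavy hazard; censoring is exponential
  loss-to-follow-up (rate 0.010/month) plus a 78-month administrative
  horizon. Progression is the death time times a Beta-distributed
  fraction, so progression never follows death. Defaults were chosen
  once so a 202-patient cohort shows ~56% deaths, median OS near 40
  months, and EF/SC groups near 40 and 56 patients; when EF/SC targets
  are set, the baseline scale and progression-fraction mean are
  calibrated by deterministic numeric integration and root finding —
  never by relabeling. The EF integral is computed by parts because the
  Weibull hazard is singular at $t = 0$ for shape < 1.
* **Planted effects**: each planted feature gets a latent standard-normal
  patient trait that shifts the targeted analyte(s) on the log scale
  (fucose-site effects shift fucosylated species up and afucosylated
  species down, moving the site's fucose weight). For an independently
  planted feature the event-generating linear predictor is the planted
  log-HR times the *realized* standardized log2 feature, so the planted
  coefficient is exactly the per-SD log hazard ratio a downstream Cox
  fit estimates. Features may instead share a named trait: they then
  co-vary through one latent driver that enters the hazard once, the way
  real prognostic panels co-vary — many detectable features without
  inflating the total risk heterogeneity (independent planting of many
  features creates a frailty that visibly attenuates every marginal
  hazard ratio). When planted heterogeneity is strong, the optional
  joint calibration (`calibrate_median`) root-finds the Weibull shape so
  the *marginal* median OS still matches its target while the scale
  meets the early-failure target. One master seed expands into
  per-stage substreams, making every stage individually reproducible.

What the simulator does **not** emulate: peak-shape artifacts, missing
values from detection limits, correlated protein modules, batch-to-batch
(as opposed to within-run) effects, and treatment-specific effect
modification. Tests passing on these cohorts therefore demonstrate the
*procedures* — calibration, recovery, information hygiene, determinism —
not performance on real plasma data.

# Numerical and design notes

* Occupancy closure is enforced to 1e-9; monomer-weight inputs must sum
  to 1 within 1e-6 or an error is raised (unnormalized input).
* The lasso active set is not strictly monotone along the path: single
  features occasionally drop as the penalty relaxes (one predictor
  replacing another); tests allow these single-feature exchanges.
* Cox Wald p-values are mildly anti-conservative at a few hundred
  patients (fraction of null p<0.05 about 0.053 at n=200); pooled
  Kolmogorov–Smirnov uniformity still holds at the 1% level.
* Screening uses a formula-free Cox fitting path when PH diagnostics are
  disabled; it is verified to agree with the standard interface to 1e-9.
* Large simulation studies in the test suite use 200 replicates for null
  calibration (n=200, ~500 features), 50/25 replicates for recovery
  (n=400, 596 features, 10 planted at log-HR log 2 per SD), 25
  replicates for the fucose scenario (n=400, 3 sites at log 3 per SD —
  an effect magnitude consistent with features discoverable in a
  79-patient training set), and 3 CV repeats inside those loops; the
  pipeline default remains 10 repeats.

# Known limitations

* Relative-abundance sites are excluded from monomer weights (occupancy
  undefined there).
* No competing risks, time-varying covariates, elastic-net variants, or
  absolute survival-probability calibration.
* The EF/SC differential test and several boundary conventions
  (inclusive 6-month EF boundary, event-free through exactly 36 months
  for SC) are implementation choices where the motivating study is
  silent; all are documented above and configurable where sensible.
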