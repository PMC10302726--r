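# glycosurv

Survival-biomarker modelling for targeted plasma glycoproteomics panels.

## The problem

Scheduled-MRM plasma glycoproteomics assays quantify hundreds of
glycopeptides — tryptic peptides carrying a glycan of known composition at
a known site — alongside non-glycosylated peptides and spiked heavy
standards. In an immunotherapy cohort with right-censored overall-survival
(OS) follow-up, the analysis questions are: which normalized glycopeptide
features are prognostic, does a sparse multivariate risk score separate
patients likely vs unlikely to benefit from treatment, and is glycan
*fucosylation* specifically informative?

`glycosurv` implements that analysis end to end, for analysts building or
evaluating such assays:

* **Quantification** — pooled-QC within-run drift correction; peptide
  concentration from heavy-standard ratios, `C = (light/heavy) × spike`;
  relative abundance `RA = I_glyco / I_refpep` for sites with ≤ 2 glycan
  species; site occupancy `occ_g = I_g / Σ I_g'` for sites with > 2
  species; concentration normalization `occ (or RA) × C_pep`.
* **Glycan features** — four-digit composition codes (Hex, HexNAc, Fuc,
  NeuAc), structural classification, and occupancy-weighted *monomer
  weights* `Σ_g occ_g · n_mono(g)` (the fucosylation signal).
* **Screening** — per-feature age- and sex-adjusted Cox regression
  (Efron ties) on standardized log2 features, Benjamini–Hochberg FDR,
  Schoenfeld proportional-hazards diagnostics, early-failure vs
  sustained-control differential testing.
* **Classifier** — stratified 40/30/30 splitting; L1-penalized Cox over a
  100-value penalty path with the penalty chosen by repeated 5-fold
  cross-validated Harrell concordance; risk scores dichotomized at the
  concordance-maximizing threshold (fixed thereafter); a fucose
  monomer-weight variant restricted to FDR-significant sites.
* **Evaluation** — Kaplan–Meier medians with log-log CIs, dichotomized
  hazard ratios with log-rank p, covariate retention at p<0.15,
  multivariate Cox adjustment, partial likelihood-ratio model comparison.
* **Synthetic cohorts** — a simulator that emulates the assay structure
  (596 concentration-normalized features: 443 occupancy-based + 78
  relative-abundance-based glycopeptides + 75 peptides; 51 N-linked
  occupancy sites) and a ~202-patient cohort with Weibull
  proportional-hazards survival, planted per-feature log hazard ratios,
  injection-order drift and QC-pool injections.

See `vignettes/glycosurv-methods.Rmd` for the full model description,
parameter defaults and design rationale.

## Worked example

```r
library(glycosurv)

planted <- data.frame(
  selector = c("occ_glycopeptide", "ra_glycopeptide", "peptide",
               "fucose_site"),
  n = c(6, 2, 2, 3),
  beta = c(rep(log(2), 3), log(2.5)),      # HR per SD of each feature
  trait = c("prognostic", "prognostic", "prognostic", "fucosylation"))
cfg <- simulation_config(seed = 11, planted = planted,
                         calibrate_median = TRUE)
res <- run_pipeline(cfg)
print(res)
```

```
Glycoproteomic survival pipeline run (seed 11 )
 cohort: 202 patients, 596 concentration-normalized features
 screen: 44 features at FDR < 0.05 
 classifier: 4 features selected ( ok )
  training: HR = 13.57 (6.31, 29.21), p = 2.58e-11
  validation: HR = 3.88 (1.90, 7.95), p = 0.000208
  test: HR = 2.61 (1.25, 5.42), p = 0.0102
```

Reading the output: the simulated 202-patient cohort carries ten
co-varying prognostic concentration features (HR 2 per SD through a
shared latent driver) and three fucose monomer-weight sites (HR 2.5 per
SD through a second driver); the Weibull baseline is calibrated so the
cohort shows the expected marginals (~56% deaths, median OS ~40 months,
~40 early-failure and ~56 sustained-control patients). The univariate
age- and sex-adjusted screen flags 44 of 596 features at FDR < 0.05
(the planted ones plus their co-varying mates); the penalized Cox
classifier (fit on the 40% training split) selects a sparse 4-feature
panel whose dichotomized risk score separates "unlikely to benefit" from
"likely to benefit" patients with hazard ratio 13.6 on the training
split (optimistic by construction), 3.9 on validation and 2.6 on the
held-out test split — the training/held-out gap is the expected selection
optimism, and held-out CIs excluding 1 show genuine signal recovery.
`res$report` holds every statistic as a JSON-serializable list (per-split
events/N, KM medians with CIs, the fucose-model section, multivariate
adjustments).

A thin command-line wrapper is installed at
`inst/scripts/glycosurv.R` (`simulate`, `quantify`, `run-all`).

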