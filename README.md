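# serolong

Serum proteomic biomarkers of longevity: peptide-to-protein Bayesian
meta-analysis with selection-bias correction, stability selection, and
survival linkage.

## The problem

In a longitudinal cohort of older men (baseline ages 73–84), baseline
serum was profiled by label-free LC-MS, yielding log10 abundances for
thousands of tryptic peptides mapping to a few hundred proteins. Men who
reached the 90th percentile of expected age for their birth cohort are
compared with men who died earlier. Peptide data of this kind are noisy,
missing not at random (low-abundance peptides escape detection), and
internally correlated (peptides of one protein share its biological
variation). `serolong` implements the full analysis chain for this
setting, for statisticians and computational biologists who want each
stage as a tested, reusable function rather than a one-off script:

1. **Normalization & QC** — per-sample median offsets estimated from
   peptides detected in every pooled-serum technical control; robust
   multivariate outlier screening of participants.
2. **Peptide associations** — per peptide, on observed rows:
   `log10 abundance ~ mu + b1*alive90th + b2*age + b3*cumhazard + site
   + imputed + error`; `10^b1` is the fold difference in long-lived
   men. Abundance-dependent missingness is corrected with a Heckman
   two-step (selection probit with a protein-block-mean exclusion
   variable, inverse Mills ratio plus a protein-level error control in
   the outcome equation, two-step-corrected standard errors).
3. **Protein meta-analysis** — peptide effects `y_i ~ N(theta_i, s_i^2)`
   with `theta_i ~ N(mu, tau2)`, priors `mu ~ N(0,1)`,
   `tau2 ~ InvGamma(1/100, 1/100)`; Gibbs-sampled (burn-in 2500,
   `10000 x max(1, log10(k))` retained draws, adaptive doubling). The
   protein's *meta-p* is the posterior probability the sign of `mu` is
   wrong.
4. **Stability selection** — delete-half jackknife over the whole
   pipeline; tier 1 = bootstrap meta-p < 0.1 and |fold| ≥ 1.1; tier 2 =
   |fold| > 1.05, meta-p < 0.2, top-third empirical-Bayes rank.
5. **Downstream biology** — crossed-random-effects protein abundances
   (participant and peptide BLUPs), Gower/Ward/Duda–Hart protein
   clustering, standardized abundance scores with Spearman health-index
   correlations, all-subsets logistic regression with BIC-weighted
   Bayesian model averaging and (cross-validated) ROC AUC, age-adjusted
   Cox hazard ratios per SD with spline age adjustment and
   tertile-by-age hazard curves, and a death-proximity factor analysis
   (one-factor measurement model, 2SLS structural model instrumenting
   time-to-death, Epanechnikov local-linear smoothing).
6. **Synthetic cohorts** — a generator that emulates the assumed data
   structure (latent inflammation factor, block-correlated proteins,
   MNAR detection, survival and health linkage) so every stage is
   testable against known ground truth.

The methods vignette (`vignettes/serolong-methods.Rmd`) documents the
models, priors, reconstruction choices and limitations.

## Worked example

A small end-to-end run on a synthetic cohort (200 participants, 24
proteins of which 6 carry true effects, ~100 peptides):

```r
library(serolong)
cfg <- sim_config(n_participants = 200, n_proteins = 24,
                  n_signal_proteins = 6, mean_peptides = 4, seed = 17)
res <- run_pipeline(cfg, out_dir = "demo", B = 25,
                    mcmc = mcmc_config(burn_in = 500,
                                       base_samples = 2000))
```

which logs, stage by stage:

```
[serolong] simulate: n=200, proteins=24, seed=17
[serolong] outliers: excluding 3 participant(s)
[serolong] fit-peptides: 92 peptides (heckman=TRUE)
[serolong] meta: 24 proteins
[serolong] jackknife: B=25
[serolong] select: 1 tier-1, 1 tier-2
[serolong] classify: reducing 5 -> <=14 proteins
[serolong] classify: in-sample AUC 0.692, 5-fold CV AUC 0.659
[serolong] survival: hazard ratios for 5 proteins
```

At n = 200 only the strongest planted effect clears the tier-1 rule
(|fold| ≥ 1.1 with bootstrap meta-p < 0.1) — the rule is calibrated for
a ~1200-person cohort — so the downstream stages fall back to the five
lowest-meta-p proteins, which classify longevity at a cross-validated
AUC of 0.66 at this small size. `demo/` then contains every stage table
(`tiers.tsv`, `protein_meta.tsv`, `hazard_ratios.tsv`,
`health_correlations.tsv`, ...) plus a `manifest.json` recording
parameters, seeds and row counts; rerunning with the same config is
byte-identical.

At full study scale (`sim_config(seed = ...)` defaults: n = 1196, 224
proteins, ~3800 peptides, 25 planted effects with folds −1.10 to −1.22)
the jackknife-backed tier-1 rule recovers ≳80% of planted signal
proteins with no false positives among nulls, and the model-averaged
14-protein classifier lands near AUC 0.62 — see the acceptance script
below.

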