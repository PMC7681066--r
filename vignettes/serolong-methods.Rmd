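---
title: "Methods: serum proteomic biomarkers of longevity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum proteomic biomarkers of longevity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`serolong` implements a complete statistical pipeline for discovering
serum protein biomarkers of longevity from label-free, peptide-level
mass-spectrometry data in a longitudinal cohort of older men, together
with a synthetic cohort generator that reproduces the data structure the
analysis assumes. This vignette is the package's own account of the
models, the parameters that matter, the numerical choices, and the
limits of what the test suite demonstrates.

## The scientific setting

A cohort of community-dwelling men aged 73–84 at baseline is followed
for over a decade. Men who reach the 90th percentile of expected age for
their birth cohort are labelled long-lived (`alive90th = 1`); men who
die earlier are the comparison group. Baseline serum is profiled by
LC-MS, yielding log10 abundances for thousands of tryptic peptides, each
mapping to one protein. Peptide measurements are noisy, partially
missing in an abundance-dependent way (low-abundance peptides fall below
the detection limit more often), and peptides of one protein share the
protein's biological variation. The analytic questions are: which
proteins differ between long-lived and shorter-lived men; how stable are
those differences under resampling; do the selected proteins predict
longevity, mortality, health status; and do they drift as death
approaches.

## Normalization protects the design contrast

Per-sample technical offsets are estimated as the median, over peptides
detected in every pooled-QC run, of each sample's deviation from the
peptide's cross-sample median, and subtracted from all observed values.
Medians of this kind absorb a slice of real biology: when a coherent
set of proteins is genuinely lower in one group, the sample medians of
that group shift, and subtracting the offsets leaks part of the group
difference out of *every* peptide (in cohort-scale simulations the leak
is ~0.007 log10 — a sixth of the smallest effect of interest). The
normalizer therefore accepts the outcome label and centers the
estimated offsets within each group before subtraction, in the same
spirit as design-aware batch correction: between-group contrasts are
untouched, within-group technical variation is still removed. Group-free
behaviour is retained when no labels are passed.

## Peptide-level association model

For each peptide, on the observed rows,

```
log10 abundance ~ mu + b1*alive90th + b2*age + b3*cumhazard
                  + site indicators + imputed indicator + error
```

`cumhazard` is the population (life-table) cumulative hazard of death at
the participant's baseline age, a birth-cohort adjustment that absorbs
differential hazard at the same age across enrolment years; the
generator computes it from a Gompertz hazard calibrated to older US
men (`h(t) = A e^{0.09 t}`, `h(77) = 0.05/yr`). The antilog of `b1` is
the fold difference in the long-lived group; fits use least squares with
pivoting so aliased columns (for instance a site absent among a
peptide's observed rows) are dropped rather than crashing the fit.

## Selection correction for abundance-dependent missingness

Detection of a peptide depends on its abundance, so the observed rows
are a selected sample and naive fits attenuate group differences. The
package uses a Heckman-type two-step correction:

1. **Selection probit.** The observation indicator is regressed (probit)
   on the outcome covariates plus an *exclusion variable*: the
   participant's mean peptide-centered abundance over the protein's
   other peptides, a proxy of the protein level that predicts detection.
2. **Augmented outcome model.** The outcome model is refit with the
   inverse Mills ratio from step 1 *and* with the covariate-residualized
   exclusion variable as an additional control. Standard errors carry
   the usual two-step correction for the estimated probit.

The second regressor is a deliberate design choice. Selection here acts
on the abundance itself, so the outcome error contains a protein-level
component that the exclusion variable predicts; omitting it makes the
inverse Mills ratio a monotone proxy of the protein level — which
carries the entire group effect — and drives the corrected `b1` toward
zero. Conditioning on the *residualized* block mean (orthogonal to the
label and the other covariates) leaves the longevity estimand untouched
while completing the observed-data regression that the selection model
implies: given covariates and block mean, the expected observed outcome
is linear in both plus the inverse Mills ratio term.

Three guards keep the correction honest, because the two-step estimator
deliberately trades variance for bias and should only be paid for where
there is bias to remove:

* peptides at least 99% observed bypass the correction;
* the correction only engages when the probit z-statistic of the
  exclusion variable exceeds `min_excl_z` (default 2): with an
  irrelevant instrument the inverse Mills ratio is numerically collinear
  with the covariates and the "corrected" estimate is pure noise;
* a pretest on the *implied selection bias*: omitting the correction
  term biases the label coefficient by approximately the inverse-Mills
  coefficient times the group difference in the inverse Mills ratio.
  When that estimated quantity is below `min_bias` (default 0.005 log10,
  an order of magnitude under the selection threshold of 0.041), the
  uncorrected fit is reported. This rule is self-calibrating: under
  MCAR or weak selection the group difference in the Mills ratio is
  tiny and the correction stands down; under strong
  abundance-dependent selection both factors are material and the
  correction engages.

In strong-MNAR simulations (~45% missing, retention probit slope 6 per
log10) the corrected estimator removes most of the naive attenuation
bias (Monte-Carlo bias about −0.010 versus +0.021 naive at a true effect
of −0.06) at the price of extra variance; the package's validation
compares absolute Monte-Carlo bias, the quantity a bias correction
targets. Under MCAR the corrected and naive fits agree essentially
everywhere.

## Protein-level Bayesian meta-analysis

Peptide estimates `y_i` with squared standard errors `s_i^2` (treated as
known) are combined per protein under

```
y_i ~ N(theta_i, s_i^2)   theta_i ~ N(mu, tau2)
mu ~ N(0, 1)              tau2 ~ InvGamma(1/100, 1/100)
```

on the log10 scale. The inverse-gamma prior is read as applying to the
*between-peptide* variance `tau2` (a hierarchical, random-effects model);
the alternative reading — a common error variance — would contradict the
"known sampling variance" assumption. All full conditionals are
conjugate and the chain is a plain Gibbs sampler (compiled, seeded
through R's RNG). Chain sizes follow the sizing rule: burn-in 2500,
retained samples `10000 * max(1, log10(k))` for `k` peptides.
Convergence is checked with a Geweke z-score (|z| < 2 on the meta-effect
chain) plus an effective-sample-size floor (1000); on failure the chain
is doubled, up to 3 times. The reported quantities are the posterior
mean of `mu` (meta-effect), its signed fold change
(`10^x`, negative when lower in the long-lived), central 95% credible
bounds, the posterior mean of `tau2`, and the **meta-p**: the posterior
probability that the sign of the meta-effect is wrong,
`min(P(mu > 0), P(mu < 0))`. This is a Bayesian sign-error probability
already tempered by the priors, not a frequentist p-value, and it is not
multiplicity-corrected.

A note on correlated peptides: peptides of one protein share the
protein's biological noise, so their sampling errors are positively
correlated while the model treats them as independent. This makes the
nominal posterior overconfident for high-peptide-count proteins — one
reason the pipeline never interprets the full-cohort posterior alone but
passes everything through resampling.

## Stability selection

The delete-half jackknife reruns peptide fits and meta-analysis on `B`
replicates (reference analysis: 200), each dropping a uniformly random
half of participants, stratified by the longevity label, drawn without
replacement. The phrase "bootstrap of jackknife replicates sampled with
replacement" is ambiguous; the without-replacement delete-half scheme is
the default and a with-replacement variant is a switch. Per protein the
replicate summary is the *median* meta-effect and median meta-p (robust
to skewed replicate distributions; the mean is a config option), and a
protein is `stable` when its full-cohort estimate lies inside the
replicate 2.5–97.5% band.

Selection rules:

* **Tier 1:** bootstrap meta-p < 0.1 and |bootstrap log10 meta-effect| ≥
  0.041 (|fold| ≥ ~1.10).
* **Tier 2:** |fold| > 1.05, meta-p < 0.2, and a top-third rank under an
  empirical-Bayes ranking, excluding tier-1 members.

The ranking is the posterior expected rank of |mu|: at each posterior
draw proteins are ranked by |mu|, and the per-protein average rank
orders them (ties broken by meta-p, then id). This is a simple stand-in
for full r-value machinery; it favors strong and certain effects but,
like any |mu|-based rule, can favor uncertain wide posteriors when
peptide counts are very unbalanced — acceptable for a secondary tier.

## Per-participant protein abundances, clustering, scores

Protein abundances per participant come from a crossed-random-effects
model per protein, `abundance ~ 1 + (1|participant) + (1|peptide)`, fit
on observed cells with `lme4`; the participant's level is the fixed
intercept plus the participant BLUP (total prediction minus the peptide
BLUP). Singular fits fall back to participant means of peptide-centered
values. Estimates are computed once on the full cohort and reused by all
downstream stages.

Clustering standardizes each protein, computes Gower dissimilarity
between protein profiles (participants as variables; on standardized
continuous profiles this is range-normalized Manhattan distance), and
agglomerates with Ward's linkage (`ward.D2`; Ward on non-Euclidean
dissimilarities is a heuristic, accepted deliberately). The number of
clusters comes from a Duda–Hart stopping rule scanning k upward and
stopping at the first split whose `Je(2)/Je(1)` ratio is not
significantly small. The classical critical value assumes many
observations per dimension; protein-profile clustering is the opposite
regime (a few hundred profiles in ~10^3 dimensions), where the closed
form grossly over-splits. The package therefore calibrates the null by
Monte Carlo — Ward's best-split ratio for a single spherical Gaussian
cluster of the same shape (default 25 simulations, level 0.05) — with
the classical formula available via `rule = "classical"`.

The abundance summary score z-scores each selected protein, sums the
z-scores per participant, and z-scores the total; cluster subscores are
means of member z-scores. Health-status associations are Spearman
correlations of the score with self-rated health, the SF-12 physical
component, the Healthy Aging Index, and the frailty index.

## Longevity classification

Starting from the tier-1 set, a backward elimination on the between-group
Mahalanobis separation (pooled covariance, ridge fallback) drops, at
each step, the protein whose removal costs the least separation, and
stops when any removal would lose more than `tol` (default 2%) of the
full-set separation — the package's concrete reconstruction of "a
smaller subset separated the groups just as well". All nonempty subsets
of the reduced set (cap 2^16 models) are then fit by age-adjusted
maximum-likelihood logistic regression; models are weighted by
`exp(-BIC/2)` (unit-information approximation to posterior model
probabilities under a uniform prior), and per-participant probabilities
are weight-averaged. Discrimination is summarized by the midrank
(Wilcoxon) AUC with a DeLong variance. Because in-sample AUC is
optimistic, the pipeline also reports a stratified K-fold
cross-validated AUC (default 5 folds) in which all models are refit and
reweighted per training fold; the protein subset itself is chosen once,
so the CV answers "how well does this signature classify", not "how well
does subset search generalize".

## Mortality and death proximity

Each protein's mortality association is a Cox partial-likelihood fit of
time to death on the standardized abundance, age-adjusted through a
natural cubic spline with 3 knots (10th/50th/90th percentiles); the
hazard ratio is per 1 SD. "Semiparametric with cubic splines" is read as
spline-adjusted partial likelihood, not a spline baseline-hazard
parametric model. Tertile-by-age curves interact tertile indicators with
the age spline and evaluate top- and bottom-versus-middle hazard ratios
on an age grid with delta-method bands; grid ages with an empty nearby
stratum are reported missing.

The death-proximity analysis is staged rather than a joint SEM, for
transparency: (1) a one-factor maximum-likelihood measurement model
summarizes the protein set into factor scores per decedent (single
proteins are used standardized; Heywood cases are clamped by the
factoring routine and flagged); (2) a structural model regresses the
factor score on baseline age and time to death, instrumenting time to
death with SF-12 physical health and the population cumulative hazard
(two-stage least squares, first-stage F reported, weak-instrument flag
below F = 10); (3) structural-model predictions are smoothed along
time to death with an Epanechnikov local-linear kernel (bandwidth: a
widened Silverman-type rule, `2 * 0.9 * min(sd, IQR/1.34) * n^(-1/5)`),
and the reported slope is the average local derivative, with the
structural coefficient's test providing the p-value. Censored
participants are excluded by default (the curve is a function of
observed time to death); including them censored at the horizon is a
sensitivity switch.

## The synthetic cohort generator

Every stage is exercised against simulated cohorts with known truth. The
generator's defaults mirror the study conditions: 1196 participants aged
73–84 (prevalence 554/1196 long-lived), 224 proteins measured by 2–58
peptides (right-skewed counts, mean ~17, ~3800 peptides in total), 25
signal proteins with log10 effects spaced evenly over magnitudes
0.041–0.0853 (folds −1.10 to −1.22, all lower in long-lived men), 12
correlation blocks with within-block correlations spanning 0.33–0.89
(signal proteins spread over 5 blocks), 102 pooled-QC technical
replicates at 10% technical CV, and probit-in-abundance missingness.

One latent standard-normal "inflammation" score per participant drives
everything: the longevity label through a logistic link (slope −0.5,
intercept solved for the prevalence), survival through a log-hazard term
(0.4 per unit score on an exponential time-to-death, censored at 15
years, with an age trend), the four health indices through noise tuned
to the target Spearman magnitudes (0.127–0.192), and the signal proteins
through loadings chosen so each protein's *implied mean group
difference equals its configured effect exactly* (loading = effect /
latent group separation, the separation computed by numerical
integration). The label slope itself was set, before any testing, so the
latent score separates the groups at AUC ≈ 0.63 — the discrimination
class reported for the real signature — which is what makes the
classifier reproduction check meaningful rather than circular: 25
correlated proteins loading on one factor cannot classify better than
the factor.

What the generator does **not** emulate: raw spectra, retention/drift
time, peptide identification errors, shared-peptide ambiguity,
batch/plate structure beyond site indicators, non-Gaussian abundance
tails, and informative censoring. Passing tests therefore demonstrate
the statistical machinery under its stated assumptions, not robustness
to everything real data can do.

## Numerical choices and problem sizes

Stochastic stages take explicit seeds and derive fixed per-stage,
per-replicate sub-streams, so reruns are byte-identical and stages can
be re-run independently. The test suite and the acceptance script scale
the expensive checks to desk size as the package's own choice of
problem sizes: 50 jackknife replicates (down from the reference 200)
with shortened replicate chains (burn-in 500, 2000 retained samples) at
the full cohort scale; 100-seed bias comparisons for the selection
correction at n = 800; 50-seed coverage checks for the hazard model at
n = 2473. Chain-size and selection thresholds are never scaled.

Known limitations, beyond those noted inline: the meta-model's
independence assumption across peptides; the empirical-Bayes ranking
dialect; the exclusion variable for the selection probit is a
constructed proxy whose validity rests on the protein-level noise being
the dominant driver of detection; and the BIC weights approximate
posterior model probabilities only to O(1) in the prior.
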