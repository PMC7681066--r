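#' Simulation configuration for a synthetic proteomic cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()],
#' [simulate_peptides()] and [apply_missingness()]. Defaults emulate the
#' structure of a discovery cohort of older men: ~1200 participants aged
#' 73-84 at baseline, 224 serum proteins measured through 2-58 tryptic
#' peptides each (~3800 peptides in total), 25 proteins carrying log10
#' group effects of magnitude 0.041-0.085 (fold changes 1.10-1.22, lower
#' in long-lived men), proteins organised into correlated blocks
#' (pairwise r 0.33-0.89), pooled-serum technical controls, and
#' abundance-dependent missingness.
#'
#' A single standard-normal latent "inflammation" score per participant
#' drives the longevity label (logistic link), the survival hazard, the
#' health indices, and the signal proteins (through loadings chosen so
#' that each signal protein's implied mean group difference equals its
#' entry of `signal_log10_effects` exactly).
#'
#' @param n_participants Cohort size.
#' @param age_range Baseline age range in years, `c(lo, hi)`; ages are
#'   uniform on this interval.
#' @param n_proteins Number of proteins.
#' @param peptides_per_protein Integer range `c(lo, hi)` of peptides per
#'   protein; counts are drawn from a right-skewed (negative binomial)
#'   distribution clipped to this range.
#' @param mean_peptides Target mean peptides per protein.
#' @param n_signal_proteins Number of proteins with a true group effect.
#' @param signal_log10_effects Per-signal-protein true log10 group
#'   difference (negative = lower in the long-lived group). Default:
#'   evenly spaced magnitudes 0.041-0.0853, i.e. folds -1.10 to -1.22.
#' @param n_blocks Number of protein correlation blocks (default
#'   `min(12, n_proteins)`).
#' @param block_cor_range Range of within-block target correlations.
#' @param protein_sd Biological between-participant SD of protein
#'   abundance, log10 units.
#' @param age_slope Change in protein log10 abundance per year of age.
#' @param peptide_noise_sd Peptide-specific biological noise SD (log10).
#' @param peptide_intercept_sd SD of peptide mean abundances (log10).
#' @param technical_cv Technical coefficient of variation (fraction) of
#'   a single measurement.
#' @param n_qc_pools Number of pooled-serum technical control runs.
#' @param missingness Named vector `c(intercept=, slope=)` of the probit
#'   retention model: each cell is observed with probability
#'   `pnorm(intercept + slope * (abundance - grand mean))`. A positive
#'   slope makes low-abundance values preferentially missing (MNAR).
#' @param imputed_rate Fraction of observed cells flagged as imputed by
#'   the upstream quantification pipeline.
#' @param label_slope Slope of the logistic model assigning the
#'   longevity label from the latent score (negative: long-lived have
#'   lower scores); the intercept is solved to match `prevalence`.
#' @param prevalence Target fraction of long-lived participants.
#' @param survival_link Log-hazard of death per unit latent score.
#' @param base_log_hazard Log baseline yearly hazard at the age-range
#'   midpoint.
#' @param age_log_hazard Log-hazard slope per year of age.
#' @param horizon_years Administrative censoring horizon.
#' @param health_link Named vector of target Spearman correlations
#'   between the latent score and the four health indices.
#' @param n_sites Number of clinical sites (uniformly assigned).
#' @param seed Integer seed; all stages derive fixed sub-streams.
#'
#' @return An object of class `serolong_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_participants = 200, n_proteins = 30,
#'                   n_signal_proteins = 5, seed = 1)
#' cfg$n_proteins
#' @export
sim_config <- function(n_participants = 1196,
                       age_range = c(73, 84),
                       n_proteins = 224,
                       peptides_per_protein = c(2, 58),
                       mean_peptides = 17.1,
                       n_signal_proteins = 25,
                       signal_log10_effects = NULL,
                       n_blocks = NULL,
                       block_cor_range = c(0.33, 0.89),
                       protein_sd = 0.15,
                       age_slope = 0.004,
                       peptide_noise_sd = 0.1,
                       peptide_intercept_sd = 0.4,
                       technical_cv = 0.10,
                       n_qc_pools = 102,
                       missingness = c(intercept = 1.0, slope = 1.2),
                       imputed_rate = 0.05,
                       label_slope = -0.5,
                       prevalence = 554 / 1196,
                       survival_link = 0.4,
                       base_log_hazard = log(0.05),
                       age_log_hazard = 0.07,
                       horizon_years = 15,
                       health_link = c(self_rated_health = -0.127,
                                       sf12_pcs = -0.135,
                                       healthy_aging_index = 0.155,
                                       frailty_index = 0.192),
                       n_sites = 6,
                       seed = 1L) {
  if (is.null(n_blocks)) n_blocks <- min(12, n_proteins)
  if (is.null(signal_log10_effects)) {
    signal_log10_effects <- if (n_signal_proteins > 0)
      -seq(0.041, 0.0853, length.out = n_signal_proteins) else numeric(0)
  }
  cfg <- structure(list(
    n_participants = as.integer(n_participants), age_range = age_range,
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    mean_peptides = mean_peptides,
    n_signal_proteins = as.integer(n_signal_proteins),
    signal_log10_effects = signal_log10_effects,
    n_blocks = as.integer(n_blocks), block_cor_range = block_cor_range,
    protein_sd = protein_sd, age_slope = age_slope,
    peptide_noise_sd = peptide_noise_sd,
    peptide_intercept_sd = peptide_intercept_sd,
    technical_cv = technical_cv, n_qc_pools = as.integer(n_qc_pools),
    missingness = missingness, imputed_rate = imputed_rate,
    label_slope = label_slope, prevalence = prevalence,
    survival_link = survival_link, base_log_hazard = base_log_hazard,
    age_log_hazard = age_log_hazard, horizon_years = horizon_years,
    health_link = health_link, n_sites = as.integer(n_sites),
    seed = as.integer(seed)), class = "serolong_config")
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the invariants of a [sim_config()] object and fails with an
#' error naming the offending field.
#'
#' @param config A `serolong_config` object.
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  chk <- function(ok, field, why)
    if (!isTRUE(ok)) stopf("invalid configuration field '%s': %s", field, why)
  chk(config$n_participants > 0, "n_participants", "must be positive")
  chk(length(config$age_range) == 2 && diff(config$age_range) > 0,
      "age_range", "must be a non-empty range c(lo, hi)")
  chk(config$n_proteins > 0, "n_proteins", "must be positive")
  chk(length(config$peptides_per_protein) == 2 &&
        config$peptides_per_protein[1] >= 1 &&
        diff(config$peptides_per_protein) >= 0,
      "peptides_per_protein", "must be an integer range with lo >= 1")
  chk(config$n_signal_proteins <= config$n_proteins, "n_signal_proteins",
      "cannot exceed n_proteins")
  chk(length(config$signal_log10_effects) == config$n_signal_proteins,
      "signal_log10_effects", "length must equal n_signal_proteins")
  chk(config$n_blocks >= 1 && config$n_blocks <= config$n_proteins,
      "n_blocks", "must be between 1 and n_proteins")
  chk(all(config$block_cor_range > 0 & config$block_cor_range < 1) &&
        diff(config$block_cor_range) >= 0,
      "block_cor_range", "correlations must lie in (0, 1)")
  chk(config$protein_sd > 0, "protein_sd", "must be positive")
  chk(config$peptide_noise_sd >= 0, "peptide_noise_sd", "must be >= 0")
  chk(config$technical_cv >= 0, "technical_cv", "must be >= 0")
  chk(config$n_qc_pools > 0, "n_qc_pools", "must be positive")
  chk(length(config$missingness) == 2 && all(is.finite(config$missingness)),
      "missingness", "needs finite c(intercept, slope)")
  chk(config$prevalence > 0 && config$prevalence < 1, "prevalence",
      "must lie in (0, 1)")
  chk(config$horizon_years > 0, "horizon_years", "must be positive")
  chk(all(abs(config$health_link) < 1), "health_link",
      "Spearman targets must lie in (-1, 1)")
  chk(config$n_sites > 0, "n_sites", "must be positive")
  chk(is.finite(config$seed), "seed", "must be a finite integer")
  invisible(config)
}

# Mean difference in the latent score between label groups implied by a
# logistic label model with the given slope and prevalence. Deterministic
# (numerical integration); used to convert target group effects into
# factor loadings.
latent_group_separation <- function(slope, prevalence) {
  if (slope == 0) return(0)
  f <- function(a)
    integrate(function(g) plogis(a + slope * g) * dnorm(g), -8, 8)$value -
    prevalence
  a <- uniroot(f, c(-25, 25))$root
  gs <- seq(-7, 7, length.out = 4001)
  w1 <- plogis(a + slope * gs) * dnorm(gs)
  w0 <- (1 - plogis(a + slope * gs)) * dnorm(gs)
  sum(gs * w1) / sum(w1) - sum(gs * w0) / sum(w0)
}

# Intercept of the label model matching the target prevalence.
label_intercept <- function(slope, prevalence) {
  f <- function(a)
    integrate(function(g) plogis(a + slope * g) * dnorm(g), -8, 8)$value -
    prevalence
  uniroot(f, c(-25, 25))$root
}
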