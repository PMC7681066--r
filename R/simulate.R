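#' Simulate a participant table
#'
#' Generates the per-participant phenotype table of a synthetic cohort:
#' baseline age (uniform on the configured range), clinical site, a
#' population birth-cohort cumulative hazard at age (Gompertz), a latent
#' standard-normal "inflammation" score, the longevity label (logistic
#' in the latent score), follow-up time and vital status (exponential
#' survival with log-hazard linear in age and the latent score, censored
#' at the horizon), and four health indices whose Spearman correlation
#' with the latent score is tuned to the configured targets.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `id`, `age`, `cumhazard`, `site`,
#'   `alive90th`, `followup_years`, `died`, `sf12_pcs`,
#'   `self_rated_health`, `healthy_aging_index`, `frailty_index`, and an
#'   attribute `"latent"` holding the latent score (also exposed in the
#'   simulation truth by [simulate_peptides()]).
#' @examples
#' pt <- simulate_cohort(sim_config(n_participants = 100, seed = 7))
#' range(pt$age)
#' @export
simulate_cohort <- function(config) {
  validate_config(config)
  n <- config$n_participants
  with_seed(seed_offset(config$seed, "cohort"), {
    age <- runif(n, config$age_range[1], config$age_range[2])
    site <- factor(sample.int(config$n_sites, n, replace = TRUE),
                   levels = seq_len(config$n_sites))
    g <- rnorm(n)
    a0 <- label_intercept(config$label_slope, config$prevalence)
    alive90th <- rbinom(n, 1, plogis(a0 + config$label_slope * g))
    mid <- mean(config$age_range)
    rate <- exp(config$base_log_hazard +
                  config$age_log_hazard * (age - mid) +
                  config$survival_link * g)
    tdeath <- rexp(n, rate)
    died <- as.integer(tdeath <= config$horizon_years)
    followup <- pmin(tdeath, config$horizon_years)
    followup <- pmax(followup, 1 / 365)
    # Gompertz male mortality: h(t) = A exp(B t); cumulative hazard at age.
    B <- 0.09; A <- 0.05 / exp(B * 77)
    cumhazard <- A / B * (exp(B * age) - 1)
    health <- lapply(names(config$health_link), function(nm) {
      rs <- config$health_link[[nm]]
      rho <- 2 * sin(pi * rs / 6)  # Pearson giving target Spearman
      z <- rho * g + sqrt(1 - rho^2) * rnorm(n)
      switch(nm,
             self_rated_health = 4.2 + 0.7 * z,
             sf12_pcs = 47.7 + 10.8 * z,
             healthy_aging_index = 3.1 + 1.6 * z,
             frailty_index = 1.0 + 0.8 * z,
             z)
    })
    names(health) <- names(config$health_link)
    pt <- data.frame(id = sprintf("S%05d", seq_len(n)), age = age,
                     cumhazard = cumhazard, site = site,
                     alive90th = alive90th, followup_years = followup,
                     died = died, stringsAsFactors = FALSE)
    pt <- cbind(pt, as.data.frame(health))
    attr(pt, "latent") <- g
    pt
  })
}

# Deterministic protein design: block membership, within-block target
# correlations, signal assignment and latent loadings.
protein_design <- function(config) {
  p <- config$n_proteins
  sizes <- tabulate(rep(seq_len(config$n_blocks), length.out = p),
                    nbins = config$n_blocks)
  block <- rep(seq_len(config$n_blocks), times = sizes)
  rho <- if (config$n_blocks == 1) mean(config$block_cor_range) else
    seq(config$block_cor_range[1], config$block_cor_range[2],
        length.out = config$n_blocks)
  ns <- config$n_signal_proteins
  signal <- integer(0)
  if (ns > 0) {
    # Spread signal proteins round-robin over the first few blocks so the
    # associated proteins form a handful of correlated clusters.
    nb <- min(5, config$n_blocks)
    idx_by_block <- split(seq_len(p), block)[seq_len(nb)]
    take <- ceiling(ns / nb)
    pool <- as.integer(t(sapply(idx_by_block, function(ix)
      c(ix, rep(NA_integer_, take))[seq_len(take)])))
    signal <- sort(pool[!is.na(pool)][seq_len(min(ns, sum(!is.na(pool))))])
    if (length(signal) < ns)  # fall back: fill with remaining proteins
      signal <- sort(c(signal, setdiff(seq_len(p), signal)[
        seq_len(ns - length(signal))]))
  }
  sep <- latent_group_separation(config$label_slope, config$prevalence)
  loading <- numeric(p)
  true_effect <- numeric(p)
  if (ns > 0) {
    eff <- config$signal_log10_effects
    loading[signal] <- if (sep != 0) eff / sep else 0
    true_effect[signal] <- if (sep != 0) eff else 0
  }
  data.frame(protein_id = sprintf("PR%03d", seq_len(p)), block = block,
             block_cor = rho[block], loading = loading,
             true_effect = true_effect, stringsAsFactors = FALSE)
}

#' Simulate peptide-level abundances for a cohort
#'
#' Builds the complete (pre-missingness) peptide abundance matrix. Each
#' protein's per-participant abundance is a block-correlated Gaussian
#' (shared block factor with the block's target correlation) plus an age
#' slope plus the latent-score loading; each peptide adds its own mean
#' level, independent biological noise, and technical noise. Pooled-QC
#' control rows are replicate measurements of each peptide's mean level
#' with technical noise only.
#'
#' @param participants Output of [simulate_cohort()].
#' @param config The same [sim_config()] object.
#' @return A `serolong_study` list with elements `participants`,
#'   `peptides` (a `serolong_peptides` object: `abundance` matrix
#'   participants x peptides, `map` peptide-to-protein table, `qc_pool`
#'   replicate matrix, `imputed` flag matrix) and `truth` (protein
#'   design with exact per-protein true effects, the per-participant
#'   latent score, and the complete abundance matrix).
#' @examples
#' cfg <- sim_config(n_participants = 60, n_proteins = 8,
#'                   n_signal_proteins = 2, mean_peptides = 4, seed = 2)
#' st <- simulate_peptides(simulate_cohort(cfg), cfg)
#' dim(st$peptides$abundance)
#' @export
simulate_peptides <- function(participants, config) {
  validate_config(config)
  if (nrow(participants) == 0) stopf("participants table is empty")
  n <- nrow(participants)
  g <- attr(participants, "latent")
  if (is.null(g)) stopf("participants lack the 'latent' attribute")
  des <- protein_design(config)
  p <- nrow(des)
  mid <- mean(config$age_range)
  with_seed(seed_offset(config$seed, "peptides"), {
    lo <- config$peptides_per_protein[1]
    hi <- config$peptides_per_protein[2]
    mu <- max(0.5, config$mean_peptides - lo)
    npep <- lo + pmin(rnbinom(p, size = 1.6, mu = mu), hi - lo)
    # protein-level abundance: block factor + idiosyncratic + signal + age
    u <- matrix(rnorm(n * config$n_blocks), n, config$n_blocks)
    e <- matrix(rnorm(n * p), n, p)
    prot <- matrix(0, n, p, dimnames = list(participants$id, des$protein_id))
    for (j in seq_len(p)) {
      rho <- des$block_cor[j]
      prot[, j] <- des$loading[j] * g +
        config$protein_sd * (sqrt(rho) * u[, des$block[j]] +
                               sqrt(1 - rho) * e[, j]) +
        config$age_slope * (participants$age - mid)
    }
    pep_protein <- rep(seq_len(p), times = npep)
    m <- length(pep_protein)
    pep_id <- sprintf("%s.p%02d", des$protein_id[pep_protein],
                      sequence(npep))
    intercept <- rnorm(m, 6, config$peptide_intercept_sd)
    sd_tech <- sqrt(log(1 + config$technical_cv^2)) / log(10)
    ab <- prot[, pep_protein, drop = FALSE] +
      matrix(intercept, n, m, byrow = TRUE) +
      matrix(rnorm(n * m, 0, config$peptide_noise_sd), n, m) +
      matrix(rnorm(n * m, 0, sd_tech), n, m)
    dimnames(ab) <- list(participants$id, pep_id)
    qc <- matrix(rep(intercept, each = config$n_qc_pools), config$n_qc_pools,
                 m) + matrix(rnorm(config$n_qc_pools * m, 0, sd_tech),
                             config$n_qc_pools, m)
    dimnames(qc) <- list(sprintf("QC%03d", seq_len(config$n_qc_pools)),
                         pep_id)
    imput <- matrix(rbinom(n * m, 1, config$imputed_rate) == 1, n, m,
                    dimnames = dimnames(ab))
    peptides <- new_peptides(ab, data.frame(peptide_id = pep_id,
                                            protein_id =
                                              des$protein_id[pep_protein],
                                            stringsAsFactors = FALSE),
                             qc, imput)
    structure(list(participants = participants, peptides = peptides,
                   truth = list(proteins = des, latent = g,
                                complete_abundance = ab,
                                config = config)),
              class = "serolong_study")
  })
}

#' Apply abundance-dependent missingness to a simulated study
#'
#' Masks each cell of the peptide matrix independently: a cell with
#' abundance `y` is retained with probability
#' `pnorm(intercept + slope * (y - grand mean))`. A positive slope makes
#' low-abundance measurements preferentially missing (MNAR), matching
#' the detection mechanism the Heckman correction assumes. QC-pool rows
#' are never masked.
#'
#' @param study A `serolong_study` from [simulate_peptides()].
#' @param config The same [sim_config()] object.
#' @return The study with `NA`s punched into `peptides$abundance`; the
#'   complete matrix is kept in `truth$complete_abundance`.
#' @export
apply_missingness <- function(study, config) {
  validate_config(config)
  ab <- study$truth$complete_abundance
  if (is.null(ab)) stopf("study lacks the complete abundance matrix")
  a <- config$missingness[[1]]; b <- config$missingness[[2]]
  with_seed(seed_offset(config$seed, "missing"), {
    pr <- pnorm(a + b * (ab - mean(ab)))
    keep <- matrix(runif(length(ab)) < pr, nrow(ab), ncol(ab))
    out <- ab
    out[!keep] <- NA_real_
    study$peptides$abundance <- out
    study$peptides$complete <- FALSE
    study
  })
}

# Constructor + validator for the peptide dataset container.
new_peptides <- function(abundance, map, qc_pool, imputed = NULL) {
  stopifnot(is.matrix(abundance), ncol(abundance) == nrow(map))
  if (anyDuplicated(map$peptide_id))
    stopf("duplicate peptide ids in the peptide-to-protein map")
  if (is.null(imputed))
    imputed <- matrix(FALSE, nrow(abundance), ncol(abundance),
                      dimnames = dimnames(abundance))
  structure(list(abundance = abundance, map = map, qc_pool = qc_pool,
                 imputed = imputed, complete = !anyNA(abundance)),
            class = "serolong_peptides")
}

#' @export
print.serolong_study <- function(x, ...) {
  cat(sprintf(
    "serolong synthetic study: %d participants, %d peptides / %d proteins (%.1f%% missing)\n",
    nrow(x$participants), ncol(x$peptides$abundance),
    length(unique(x$peptides$map$protein_id)),
    100 * mean(is.na(x$peptides$abundance))))
  invisible(x)
}
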