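# Bayesian peptide-to-protein meta-analysis.
#
# Model per protein, given peptide estimates y_i with known sampling
# variances s_i^2 (squared standard errors from the peptide fits):
#   y_i ~ N(theta_i, s_i^2),  theta_i ~ N(mu, tau2),
#   mu ~ N(0, 1) on the log10 scale,  tau2 ~ InvGamma(1/100, 1/100).
# Estimated by Gibbs sampling with an adaptive burn-in of 2500 and an
# initial sample size of 10000 times max(1, log10(#peptides)), with
# convergence checks and adaptive chain expansion.

#' Priors for the protein-level meta-analysis
#'
#' Mildly informative defaults on the log10 abundance scale: the mean
#' peptide association is N(0, 1) a priori and the between-peptide
#' variance is inverse-gamma with shape and scale 1/100.
#'
#' @param mean_prior_mean,mean_prior_var Normal prior on the meta-effect.
#' @param var_prior_shape,var_prior_scale Inverse-gamma prior on the
#'   between-peptide variance.
#' @return A `meta_priors` list.
#' @export
meta_priors <- function(mean_prior_mean = 0, mean_prior_var = 1,
                        var_prior_shape = 1 / 100,
                        var_prior_scale = 1 / 100) {
  stopifnot(mean_prior_var > 0, var_prior_shape > 0, var_prior_scale > 0)
  structure(list(mean_prior_mean = mean_prior_mean,
                 mean_prior_var = mean_prior_var,
                 var_prior_shape = var_prior_shape,
                 var_prior_scale = var_prior_scale),
            class = "meta_priors")
}

#' MCMC settings for the meta-analysis Gibbs sampler
#'
#' @param burn_in Burn-in samples (default 2500).
#' @param base_samples Initial retained sample size before scaling
#'   (default 10000); the actual size is `mcmc_size(n_peptides)`.
#' @param max_expansions Maximum number of chain doublings when the
#'   convergence check fails.
#' @param geweke_limit Absolute Geweke z-score accepted as converged.
#' @param min_ess Minimum effective sample size accepted as converged.
#' @param seed Optional integer seed applied per protein.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(burn_in = 2500, base_samples = 10000,
                        max_expansions = 3, geweke_limit = 2,
                        min_ess = 1000, seed = NULL) {
  stopifnot(burn_in > 0, base_samples > 0, max_expansions >= 0)
  structure(list(burn_in = as.integer(burn_in),
                 base_samples = as.integer(base_samples),
                 max_expansions = as.integer(max_expansions),
                 geweke_limit = geweke_limit, min_ess = min_ess,
                 seed = seed), class = "mcmc_config")
}

#' MCMC sample size for a protein
#'
#' The retained chain length is the base sample size times the base-10
#' log of the peptide count, or times 1 if the count is below 10.
#'
#' @param n_peptides Number of peptides mapped to the protein.
#' @param base_samples Base sample size.
#' @return Integer number of retained samples.
#' @examples
#' mcmc_size(5)    # 10000
#' mcmc_size(100)  # 20000
#' @export
mcmc_size <- function(n_peptides, base_samples = 10000) {
  stopifnot(n_peptides >= 2)
  as.integer(round(base_samples * max(1, log10(n_peptides))))
}

#' Posterior sign-error probability ("meta-p")
#'
#' The posterior probability that the sign of the meta-effect is
#' estimated incorrectly: the smaller of the fractions of posterior
#' samples above and below zero (exact zeros split equally). A Bayesian
#' quantity in `[0, 0.5]`, not a frequentist p-value.
#'
#' @param chain Numeric vector of posterior samples of the meta-effect.
#' @return A probability in `[0, 0.5]`.
#' @export
meta_p <- function(chain) {
  if (length(chain) == 0) stopf("empty posterior chain")
  pos <- mean(chain > 0) + 0.5 * mean(chain == 0)
  min(pos, 1 - pos)
}

#' Signed fold change from a log10 effect
#'
#' `10^x` for `x >= 0`, `-(10^-x)` for `x < 0`; negative values mean
#' lower abundance in the long-lived group. A log10 effect of 0.041
#' corresponds to a fold change of about 1.1.
#'
#' @param log10_effect Numeric vector of log10 effects.
#' @return Signed fold changes (|fold| >= 1).
#' @examples
#' signed_fold_change(c(0.041, 0, -0.08529))
#' @export
signed_fold_change <- function(log10_effect) {
  stopifnot(all(is.finite(log10_effect)))
  ifelse(log10_effect >= 0, 10^log10_effect, -(10^(-log10_effect)))
}

#' Inverse of [signed_fold_change()]
#' @param fold Signed fold changes with |fold| >= 1.
#' @return log10 effects.
#' @export
log10_effect_from_fold <- function(fold) {
  stopifnot(all(abs(fold) >= 1))
  sign(fold) * log10(abs(fold))
}

#' Gibbs-sampled meta-analysis of one protein's peptide effects
#'
#' Combines converged peptide-level estimates for one protein under the
#' hierarchical normal model with known per-peptide sampling variances,
#' returning posterior summaries of the protein meta-effect.
#' Convergence of the meta-effect chain is checked (Geweke z-score and
#' effective-sample-size floor) and the chain is doubled on failure, up
#' to `max_expansions` times.
#'
#' @param effects A `data.frame` of peptide effects for one protein
#'   (columns `beta1`, `se`, and optionally `converged`), as produced by
#'   [fit_all_peptides()].
#' @param priors A [meta_priors()] object.
#' @param mcmc An [mcmc_config()] object.
#' @param keep_chain Keep the retained meta-effect chain in the result?
#' @param fix_tau2 Optional fixed value of the between-peptide variance
#'   (testing hook; `0` collapses the model to its conjugate form).
#' @return A list of class `protein_meta`: `meta_effect` (posterior mean
#'   of the log10 effect), `meta_fold`, `meta_p`, `ci95`, `tau2`
#'   (posterior mean), `n_peptides`, `mcmc_samples_used`, `converged`,
#'   and optionally `chain`.
#' @export
gibbs_meta <- function(effects, priors = meta_priors(),
                       mcmc = mcmc_config(), keep_chain = FALSE,
                       fix_tau2 = NULL) {
  if (!is.null(effects$converged)) effects <- effects[effects$converged, ]
  bad <- !is.finite(effects$se) | effects$se <= 0
  if (any(bad)) {
    warnf("dropping %d peptide(s) with non-finite or zero SE", sum(bad))
    effects <- effects[!bad, ]
  }
  k <- nrow(effects)
  if (k < 2) stopf("protein has %d usable peptide effect(s); need >= 2", k)
  y <- effects$beta1
  s2 <- effects$se^2
  n_keep <- mcmc_size(k, mcmc$base_samples)
  run <- function(n) {
    gibbs_chain_cpp(y, s2, as.integer(n), mcmc$burn_in,
                    priors$mean_prior_mean, priors$mean_prior_var,
                    priors$var_prior_shape, priors$var_prior_scale,
                    if (is.null(fix_tau2)) -1 else fix_tau2,
                    tau2_init = max(var(y), 1e-4))
  }
  do_run <- function() {
    ch <- run(n_keep)
    exp_used <- 0L
    while (exp_used < mcmc$max_expansions &&
           (abs(geweke_z(ch$mu)) > mcmc$geweke_limit ||
            ess(ch$mu) < min(mcmc$min_ess, n_keep / 2))) {
      n_keep <<- n_keep * 2L
      ch <- run(n_keep)
      exp_used <- exp_used + 1L
    }
    list(ch = ch, exp_used = exp_used)
  }
  res <- if (is.null(mcmc$seed)) do_run() else
    with_seed(mcmc$seed, do_run())
  ch <- res$ch
  conv <- abs(geweke_z(ch$mu)) <= mcmc$geweke_limit
  m <- mean(ch$mu)
  structure(list(meta_effect = m, meta_fold = signed_fold_change(m),
                 meta_p = meta_p(ch$mu),
                 ci95 = unname(quantile(ch$mu, c(0.025, 0.975))),
                 tau2 = mean(ch$tau2), n_peptides = k,
                 mcmc_samples_used = length(ch$mu), converged = conv,
                 chain = if (keep_chain) ch$mu else NULL),
            class = "protein_meta")
}

#' Meta-analyze all proteins
#'
#' Runs [gibbs_meta()] for every protein with at least two converged
#' peptide effects (proteins below that are skipped with a message, as
#' singleton peptides are unstable under resampling).
#'
#' @param effects Peptide-effect table from [fit_all_peptides()].
#' @param priors,mcmc See [gibbs_meta()].
#' @param keep_chains Keep per-protein meta-effect chains (needed by
#'   [eb_rank()])?
#' @param seed Integer seed; each protein gets a fixed sub-stream so
#'   results do not depend on evaluation order.
#' @return A `data.frame` with one row per analyzed protein
#'   (protein_id, n_peptides, meta_effect, meta_fold, meta_p, ci_lo,
#'   ci_hi, tau2, mcmc_samples_used, converged); chains, if kept, in
#'   attribute `"chains"`.
#' @export
meta_analyze_proteins <- function(effects, priors = meta_priors(),
                                  mcmc = mcmc_config(),
                                  keep_chains = FALSE, seed = NULL) {
  prot <- unique(effects$protein_id)
  rows <- vector("list", length(prot))
  chains <- if (keep_chains) vector("list", length(prot)) else NULL
  skipped <- character(0)
  for (i in seq_along(prot)) {
    ef <- effects[effects$protein_id == prot[i], ]
    sub <- mcmc
    sub$seed <- if (is.null(seed)) NULL else
      (as.integer(seed) + 7L * i) %% .Machine$integer.max
    m <- tryCatch(gibbs_meta(ef, priors, sub, keep_chain = keep_chains),
                  error = function(e) NULL)
    if (is.null(m)) {
      skipped <- c(skipped, prot[i])
      next
    }
    rows[[i]] <- data.frame(protein_id = prot[i],
                            n_peptides = m$n_peptides,
                            meta_effect = m$meta_effect,
                            meta_fold = m$meta_fold, meta_p = m$meta_p,
                            ci_lo = m$ci95[1], ci_hi = m$ci95[2],
                            tau2 = m$tau2,
                            mcmc_samples_used = m$mcmc_samples_used,
                            converged = m$converged,
                            stringsAsFactors = FALSE)
    if (keep_chains) chains[[i]] <- m$chain
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (length(skipped))
    message(sprintf("skipped %d protein(s) with < 2 usable peptides: %s",
                    length(skipped),
                    paste(head(skipped, 5), collapse = ", ")))
  if (keep_chains) {
    names(chains) <- prot
    attr(out, "chains") <- chains[out$protein_id]
  }
  out
}
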