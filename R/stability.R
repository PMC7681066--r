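# Delete-half jackknife stability analysis and tier selection rules.

#' Delete-half jackknife replicates of the whole estimation pipeline
#'
#' Each replicate drops a uniformly random half of the participants
#' (stratified by longevity label, drawn without replacement), reruns
#' the peptide fits and the protein meta-analysis, and records each
#' protein's replicate meta-effect and meta-p. Per protein, the
#' replicate summary is the median meta-effect (`boot_effect`) and
#' median meta-p (`boot_meta_p`); a protein is `stable` when the
#' full-cohort estimate falls inside the replicate 2.5-97.5% band.
#'
#' @param peptides A `serolong_peptides` object (normalized).
#' @param participants Participant table.
#' @param B Number of replicates (the reference analysis used 200).
#' @param seed Integer seed; replicate subsamples and chains derive
#'   fixed sub-streams from it.
#' @param full Optional precomputed full-cohort meta table from
#'   [meta_analyze_proteins()]; computed here when `NULL`.
#' @param heckman Apply the selection correction within replicates?
#' @param priors,mcmc Passed to the meta-analysis.
#' @param with_replacement Draw the half-samples with replacement
#'   instead of the default without-replacement delete-half scheme.
#' @param summary `"median"` (default) or `"mean"` replicate summary.
#' @param min_obs Minimum observed values per peptide within a replicate.
#' @return A `data.frame` (protein_id, n_peptides, boot_effect,
#'   boot_meta_p, boot_fold, stable, n_replicates, full_effect,
#'   full_meta_p) with the replicate effect and meta-p matrices in
#'   attributes `"replicate_effects"` and `"replicate_meta_p"`.
#' @export
jackknife_replicates <- function(peptides, participants, B = 200,
                                 seed = 1, full = NULL, heckman = TRUE,
                                 priors = meta_priors(),
                                 mcmc = mcmc_config(),
                                 with_replacement = FALSE,
                                 summary = c("median", "mean"),
                                 min_obs = 20) {
  summary <- match.arg(summary)
  if (is.null(full)) {
    eff <- fit_all_peptides(peptides, participants, heckman = heckman,
                            min_obs = min_obs)
    full <- meta_analyze_proteins(eff, priors, mcmc, seed = seed)
  }
  prot <- full$protein_id
  idx1 <- which(participants$alive90th == 1)
  idx0 <- which(participants$alive90th == 0)
  eff_mat <- matrix(NA_real_, B, length(prot),
                    dimnames = list(NULL, prot))
  p_mat <- eff_mat
  n_missing <- 0L
  for (b in seq_len(B)) {
    sub <- with_seed(seed_offset(seed, "jackknife") + b, {
      half <- function(ix) {
        m <- max(1, floor(length(ix) / 2))
        if (with_replacement) sample(ix, m, replace = TRUE)
        else sample(ix, m)
      }
      sort(c(half(idx1), half(idx0)))
    })
    pt_b <- participants[sub, , drop = FALSE]
    eff_b <- fit_all_peptides(peptides, pt_b, heckman = heckman,
                              min_obs = min(min_obs,
                                            max(10, min_obs %/% 2)))
    meta_b <- suppressMessages(
      meta_analyze_proteins(eff_b, priors, mcmc,
                            seed = seed + 1000L * b))
    hit <- match(prot, meta_b$protein_id)
    eff_mat[b, ] <- meta_b$meta_effect[hit]
    p_mat[b, ] <- meta_b$meta_p[hit]
    n_missing <- n_missing + sum(is.na(hit))
  }
  if (n_missing > 0)
    warnf("%d protein-replicate cells were unestimable and recorded as missing",
          n_missing)
  agg <- if (summary == "median") function(x) median(x, na.rm = TRUE)
         else function(x) mean(x, na.rm = TRUE)
  boot_effect <- apply(eff_mat, 2, agg)
  boot_meta_p <- apply(p_mat, 2, agg)
  lo <- apply(eff_mat, 2, quantile, probs = 0.025, na.rm = TRUE)
  hi <- apply(eff_mat, 2, quantile, probs = 0.975, na.rm = TRUE)
  out <- data.frame(protein_id = prot, n_peptides = full$n_peptides,
                    boot_effect = boot_effect,
                    boot_meta_p = boot_meta_p,
                    boot_fold = signed_fold_change(boot_effect),
                    stable = full$meta_effect >= lo &
                      full$meta_effect <= hi,
                    n_replicates = colSums(!is.na(eff_mat)),
                    full_effect = full$meta_effect,
                    full_meta_p = full$meta_p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "replicate_effects") <- eff_mat
  attr(out, "replicate_meta_p") <- p_mat
  out
}

# Pick the effect/meta-p columns of a summary table, preferring the
# bootstrap ones when present.
selection_columns <- function(summaries) {
  eff <- if ("boot_effect" %in% names(summaries)) summaries$boot_effect
         else summaries$meta_effect
  p <- if ("boot_meta_p" %in% names(summaries)) summaries$boot_meta_p
       else summaries$meta_p
  if (is.null(eff) || is.null(p))
    stopf("summaries need (boot_)effect and (boot_)meta_p columns")
  list(effect = eff, p = p)
}

#' Tier-1 protein selection
#'
#' Retains proteins whose bootstrap meta-p is below `max_meta_p` (0.1)
#' and whose absolute bootstrap log10 meta-effect is at least
#' `min_abs_effect` (0.041, i.e. an absolute fold change of about 1.1).
#'
#' @param summaries A summary table with `boot_effect`/`boot_meta_p`
#'   (from [jackknife_replicates()]) or `meta_effect`/`meta_p` columns.
#' @param min_abs_effect Minimum absolute log10 meta-effect.
#' @param max_meta_p Maximum meta-p.
#' @return Character vector of selected protein ids.
#' @export
select_tier1 <- function(summaries, min_abs_effect = 0.041,
                         max_meta_p = 0.1) {
  if (nrow(summaries) == 0) stopf("empty summary table")
  sc <- selection_columns(summaries)
  keep <- !is.na(sc$effect) & !is.na(sc$p) &
    abs(sc$effect) >= min_abs_effect & sc$p < max_meta_p
  summaries$protein_id[keep]
}

#' Tier-2 protein selection
#'
#' Retains proteins not already in tier 1 whose absolute meta-fold
#' change exceeds `min_abs_fold` (1.05), whose meta-p is below
#' `max_meta_p` (0.2), and whose empirical-Bayes rank is within the top
#' third.
#'
#' @param summaries As in [select_tier1()].
#' @param ranks Named integer ranks from [eb_rank()] (1 = strongest).
#' @param min_abs_fold Minimum absolute fold change.
#' @param max_meta_p Maximum meta-p.
#' @param tier1 Optional tier-1 ids to exclude (computed with default
#'   thresholds when `NULL`).
#' @return Character vector of selected protein ids.
#' @export
select_tier2 <- function(summaries, ranks, min_abs_fold = 1.05,
                         max_meta_p = 0.2, tier1 = NULL) {
  sc <- selection_columns(summaries)
  if (is.null(tier1)) tier1 <- select_tier1(summaries)
  rk <- ranks[summaries$protein_id]
  if (anyNA(rk)) stopf("ranks missing for some summarized proteins")
  top3 <- ceiling(length(ranks) / 3)
  keep <- !is.na(sc$effect) & !is.na(sc$p) &
    abs(sc$effect) >= log10(min_abs_fold) & sc$p < max_meta_p &
    rk <= top3 & !(summaries$protein_id %in% tier1)
  summaries$protein_id[keep]
}

#' Empirical-Bayes protein ranking
#'
#' Ranks proteins by the posterior expected rank of their absolute
#' meta-effect: at each retained posterior draw the proteins are ranked
#' by |meta-effect| (1 = largest), and the per-protein average over
#' draws is the ranking score. Smaller expected rank means a stronger,
#' more certain effect. Ties are broken by meta-p, then protein id.
#'
#' @param meta A meta table from [meta_analyze_proteins()] run with
#'   `keep_chains = TRUE` (or with a `"chains"` attribute attached).
#' @param n_draws Number of equally spaced posterior draws to use.
#' @return Named integer vector of ranks (1 = strongest).
#' @export
eb_rank <- function(meta, n_draws = 1000) {
  chains <- attr(meta, "chains")
  if (is.null(chains)) stopf("meta table lacks posterior chains")
  chains <- chains[meta$protein_id]
  L <- min(n_draws, min(lengths(chains)))
  M <- vapply(chains, function(ch)
    abs(ch[round(seq(1, length(ch), length.out = L))]), numeric(L))
  per_draw <- apply(M, 1, function(v) rank(-v, ties.method = "average"))
  expected <- rowMeans(per_draw)  # per_draw is proteins x draws
  ord <- order(expected, meta$meta_p, meta$protein_id)
  setNames(order(ord), meta$protein_id)
}
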