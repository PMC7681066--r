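# One-command orchestration of the full analysis on synthetic data.

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> validate -> normalize -> outlier screen ->
#' peptide fits -> protein meta-analysis -> delete-half jackknife ->
#' tier selection -> protein abundance estimation -> clustering ->
#' summary score + health correlations -> BMA classifier -> per-protein
#' mortality hazard ratios -> death-proximity analysis, writing each
#' stage's table as a TSV under `out_dir` together with a
#' machine-readable JSON manifest. Reruns with the same configuration
#' and seed produce identical outputs.
#'
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param out_dir Output directory.
#' @param B Jackknife replicates.
#' @param heckman Apply the selection correction.
#' @param mcmc An [mcmc_config()].
#' @param classifier_max Maximum classifier subset size (Mahalanobis
#'   reduction target).
#' @param cv_folds Folds for the cross-validated classifier AUC.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, B = 200,
                         heckman = TRUE, mcmc = mcmc_config(),
                         classifier_max = 14, cv_folds = 5) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[serolong] ", msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline halted at stage '%s': %s", name,
            conditionMessage(e)))
  }
  note("simulate: n=%d, proteins=%d, seed=%d", config$n_participants,
       config$n_proteins, config$seed)
  study <- stage("simulate", {
    pt <- simulate_cohort(config)
    apply_missingness(simulate_peptides(pt, config), config)
  })
  write_study(study, file.path(out_dir, "data"))
  viol <- stage("validate", validate_inputs(file.path(out_dir, "data")))
  if (nrow(viol) > 0)
    stopf("pipeline halted at stage 'validate': %d violation(s)",
          nrow(viol))
  pep <- stage("normalize",
               normalize_abundances(study$peptides,
                                    groups = setNames(
                                      study$participants$alive90th,
                                      study$participants$id)))
  out_ids <- stage("outliers", flag_outliers(pep))
  pt <- study$participants
  if (length(out_ids) > 0) {
    note("outliers: excluding %d participant(s)", length(out_ids))
    pt <- pt[!pt$id %in% out_ids, , drop = FALSE]
  }
  note("fit-peptides: %d peptides (heckman=%s)", ncol(pep$abundance),
       heckman)
  effects <- stage("fit-peptides",
                   fit_all_peptides(pep, pt, heckman = heckman))
  write_tsv(effects, file.path(out_dir, "peptide_effects.tsv"))
  note("meta: %d proteins", length(unique(effects$protein_id)))
  meta <- stage("meta", suppressMessages(
    meta_analyze_proteins(effects, mcmc = mcmc, keep_chains = TRUE,
                          seed = config$seed)))
  write_tsv(meta[, setdiff(names(meta), "chains")],
            file.path(out_dir, "protein_meta.tsv"))
  note("jackknife: B=%d", B)
  boot <- stage("jackknife", suppressWarnings(
    jackknife_replicates(pep, pt, B = B, seed = config$seed,
                         full = meta, heckman = heckman, mcmc = mcmc)))
  ranks <- stage("rank", eb_rank(meta))
  tier1 <- stage("select", select_tier1(boot))
  tier2 <- stage("select", select_tier2(boot, ranks, tier1 = tier1))
  tiers <- data.frame(protein_id = boot$protein_id,
                      tier = ifelse(boot$protein_id %in% tier1, "1",
                                    ifelse(boot$protein_id %in% tier2,
                                           "2", "none")),
                      boot_effect = boot$boot_effect,
                      boot_fold = boot$boot_fold,
                      boot_meta_p = boot$boot_meta_p,
                      rank = unname(ranks[boot$protein_id]),
                      stable = boot$stable)
  write_tsv(tiers, file.path(out_dir, "tiers.tsv"))
  note("select: %d tier-1, %d tier-2", length(tier1), length(tier2))
  selected <- if (length(tier1) >= 2) tier1 else
    boot$protein_id[order(boot$boot_meta_p)][seq_len(
      min(5, nrow(boot)))]
  amat <- stage("abundance",
                estimate_protein_abundance(pep, pt, proteins = selected))
  write_tsv(data.frame(id = rownames(amat), amat,
                       check.names = FALSE),
            file.path(out_dir, "protein_abundance.tsv"))
  clus <- if (ncol(amat) >= 3)
    stage("cluster", cluster_proteins(amat, seed = config$seed))
  else NULL
  if (!is.null(clus))
    write_tsv(data.frame(protein_id = names(clus$cluster),
                         cluster = unname(clus$cluster)),
              file.path(out_dir, "clusters.tsv"))
  score <- stage("score", abundance_score(amat, selected, clus))
  write_tsv(data.frame(id = names(score), score = unname(score)),
            file.path(out_dir, "scores.tsv"))
  health <- stage("score", health_correlations(score, pt))
  write_tsv(health, file.path(out_dir, "health_correlations.tsv"))
  note("classify: reducing %d -> <=%d proteins", length(selected),
       classifier_max)
  subset <- stage("classify", {
    s <- mahalanobis_subset(amat, pt$alive90th, selected)
    if (length(s) > classifier_max) {
      # tighten until the subset respects the model cap
      tol <- 0.02
      while (length(s) > classifier_max && tol < 0.5) {
        tol <- tol * 2
        s <- mahalanobis_subset(amat, pt$alive90th, selected, tol = tol)
      }
      if (length(s) > classifier_max)
        s <- s[seq_len(classifier_max)]
    }
    s
  })
  bma <- stage("classify",
               all_subsets_logistic(amat, pt$alive90th, subset,
                                    age = pt$age))
  cv <- stage("classify",
              cv_bma_auc(amat, pt$alive90th, subset, age = pt$age,
                         k = cv_folds, seed = config$seed))
  in_auc <- roc_auc(bma$prob, pt$alive90th)
  note("classify: in-sample AUC %.3f, %d-fold CV AUC %.3f",
       in_auc$auc, cv_folds, cv$auc$auc)
  write_tsv(data.frame(protein_id = names(bma$inclusion),
                       inclusion_probability = unname(bma$inclusion)),
            file.path(out_dir, "model_inclusion.tsv"))
  write_tsv(data.frame(id = pt$id, bma_probability = bma$prob,
                       cv_probability = cv$prob),
            file.path(out_dir, "classifier_probabilities.tsv"))
  note("survival: hazard ratios for %d proteins", length(selected))
  hr <- stage("survival", do.call(rbind, lapply(selected, function(p)
    cbind(protein_id = p,
          protein_mortality_hr(amat[, p], pt)))))
  write_tsv(hr, file.path(out_dir, "hazard_ratios.tsv"))
  prox <- stage("proximity",
                death_proximity_fit(amat, pt, selected))
  write_tsv(prox$curve, file.path(out_dir, "proximity_curve.tsv"))
  manifest <- list(
    package = "serolong",
    seed = config$seed,
    config = unclass(config),
    parameters = list(B = B, heckman = heckman,
                      mcmc = unclass(mcmc)[c("burn_in", "base_samples",
                                             "max_expansions")],
                      classifier_max = classifier_max,
                      cv_folds = cv_folds),
    stages = list(
      simulate = list(participants = nrow(study$participants),
                      peptides = ncol(study$peptides$abundance),
                      missing_fraction =
                        mean(is.na(study$peptides$abundance))),
      outliers = list(flagged = length(out_ids)),
      fit_peptides = list(rows = nrow(effects),
                          converged = sum(effects$converged)),
      meta = list(proteins = nrow(meta)),
      jackknife = list(B = B),
      select = list(tier1 = sort(tier1), tier2 = sort(tier2)),
      classify = list(subset = subset, auc = in_auc$auc,
                      cv_auc = cv$auc$auc),
      survival = list(max_hr = max(hr$hr_per_sd)),
      proximity = list(slope = prox$slope, slope_p = prox$slope_p)),
    outputs = sort(list.files(out_dir, recursive = TRUE)),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(study = study, effects = effects, meta = meta,
                 boot = boot, tier1 = tier1, tier2 = tier2,
                 abundance = amat, clusters = clus, score = score,
                 health = health, subset = subset, bma = bma, cv = cv,
                 hazard = hr, proximity = prox, manifest = manifest))
}
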