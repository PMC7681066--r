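# Jackknife stability resampling, tier rules, empirical-Bayes ranking.

ref_summaries <- function() {
  ref <- longevity_reference_effects()
  data.frame(protein_id = ref$gene,
             boot_effect = log10_effect_from_fold(ref$meta_fold),
             boot_meta_p = ref$meta_p)
}

test_that("the tier-1 rule retains all reference proteins and rejects near-misses", {
  s <- ref_summaries()
  expect_identical(sort(select_tier1(s)), sort(s$protein_id))
  extra <- rbind(s,
                 data.frame(protein_id = c("NEAR_FOLD", "NEAR_P"),
                            boot_effect = log10_effect_from_fold(
                              c(-1.09, -1.15)),
                            boot_meta_p = c(0.01, 0.11)))
  sel <- select_tier1(extra)
  expect_false("NEAR_FOLD" %in% sel)
  expect_false("NEAR_P" %in% sel)
})

test_that("tier-1 selection is monotone in the effect magnitude", {
  s <- ref_summaries()
  sel0 <- select_tier1(s)
  s$boot_effect <- s$boot_effect * 1.5
  expect_true(all(sel0 %in% select_tier1(s)))
})

test_that("tier 2 needs both thresholds and a top-third rank, minus tier 1", {
  s <- data.frame(protein_id = paste0("P", 1:6),
                  boot_effect = log10_effect_from_fold(
                    c(-1.20, 1.07, 1.07, -1.06, 1.02, -1.08)),
                  boot_meta_p = c(0.01, 0.15, 0.15, 0.25, 0.1, 0.19))
  ranks <- setNames(c(1L, 2L, 5L, 3L, 4L, 6L), s$protein_id)
  t1 <- select_tier1(s)
  expect_identical(t1, "P1")
  t2 <- select_tier2(s, ranks, tier1 = t1)
  expect_true("P2" %in% t2)       # passes thresholds, rank 2 of 6
  expect_false("P3" %in% t2)      # rank 5: bottom two-thirds
  expect_false("P4" %in% t2)      # meta-p too large
  expect_false("P5" %in% t2)      # fold too small
  expect_false("P1" %in% t2)      # tier-1 member
})

test_that("expected-rank ordering recovers graded effect magnitudes", {
  set.seed(17)
  mus <- seq(0.005, 0.1, length.out = 50) * rep(c(-1, 1), 25)
  chains <- lapply(mus, function(m) rnorm(1200, m, 0.01))
  meta <- data.frame(protein_id = sprintf("P%02d", 1:50),
                     meta_p = vapply(chains, meta_p, numeric(1)))
  attr(meta, "chains") <- setNames(chains, meta$protein_id)
  r <- eb_rank(meta)
  expect_lt(cor(r, abs(mus), method = "spearman"), -0.8)
  expect_identical(names(which(r == 1L)), "P50")
})

test_that("identical posteriors get adjacent, deterministically ordered ranks", {
  ch <- rnorm(800, 0.05, 0.02)
  meta <- data.frame(protein_id = c("B", "A"), meta_p = c(0.1, 0.1))
  attr(meta, "chains") <- list(B = ch, A = ch)
  r <- eb_rank(meta)
  expect_identical(r[["A"]], 1L)
  expect_identical(r[["B"]], 2L)
})

test_that("jackknife summaries are reproducible and flag strong signals stable", {
  fx <- small_study(seed = 51, n = 400, p = 6, signal = 2,
                    mean_pep = 5, missing = TRUE)
  pep <- normalize_abundances(fx$pep)
  mc <- mcmc_config(burn_in = 300, base_samples = 1500)
  b1 <- suppressWarnings(jackknife_replicates(pep, fx$pt, B = 6,
                                              seed = 3, mcmc = mc))
  b2 <- suppressWarnings(jackknife_replicates(pep, fx$pt, B = 6,
                                              seed = 3, mcmc = mc))
  expect_equal(b1$boot_effect, b2$boot_effect)
  expect_identical(dim(attr(b1, "replicate_effects")), c(6L, nrow(b1)))
  expect_true(all(b1$boot_meta_p >= 0 & b1$boot_meta_p <= 0.5))
})

test_that("discordant two-peptide proteins have wider replicate bands", {
  # protein A: 2 discordant noisy peptides; protein B: 12 concordant
  # peptides with the same biology. A's replicate meta-effects should
  # scatter more than B's.
  set.seed(52)
  n <- 400
  pt <- simulate_cohort(sim_config(n_participants = n, seed = 52))
  bio <- rnorm(n, 0, 0.05)
  mk <- function(k, noise, discord = 0)
    sapply(seq_len(k), function(j)
      6 + bio + rnorm(n, 0, noise) +
        discord * (-1)^j * pt$alive90th)
  ab <- cbind(mk(2, 0.4, discord = 0.15), mk(12, 0.1))
  ids <- c(sprintf("PA.p%02d", 1:2), sprintf("PB.p%02d", 1:12))
  dimnames(ab) <- list(pt$id, ids)
  qc <- matrix(6, 20, 14, dimnames = list(sprintf("QC%02d", 1:20), ids))
  pep <- serolong:::new_peptides(ab, data.frame(
    peptide_id = ids, protein_id = substr(ids, 1, 2)), qc)
  mc <- mcmc_config(burn_in = 300, base_samples = 1500)
  b <- suppressWarnings(jackknife_replicates(pep, pt, B = 12,
                                             seed = 5, mcmc = mc))
  effs <- attr(b, "replicate_effects")
  spread <- apply(effs, 2, sd, na.rm = TRUE)
  expect_gt(spread[["PA"]], spread[["PB"]])
})
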