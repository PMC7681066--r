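# Synthetic cohort generator: configuration contracts, marginal
# structure, ground-truth recoverability, and the missingness model.

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_participants = 0), "n_participants")
  expect_error(sim_config(age_range = c(84, 73)), "age_range")
  expect_error(sim_config(n_proteins = 10, n_signal_proteins = 11),
               "n_signal_proteins")
  expect_error(sim_config(block_cor_range = c(0, 1.2)),
               "block_cor_range")
  expect_error(sim_config(prevalence = 1.2), "prevalence")
})

test_that("simulated ages stay within the configured baseline range", {
  pt <- simulate_cohort(sim_config(n_participants = 500, seed = 5))
  expect_gte(min(pt$age), 73)
  expect_lte(max(pt$age), 84)
})

test_that("same seed and config give byte-identical studies", {
  cfg <- sim_config(n_participants = 80, n_proteins = 6,
                    n_signal_proteins = 2, mean_peptides = 3, seed = 9)
  s1 <- apply_missingness(simulate_peptides(simulate_cohort(cfg), cfg),
                          cfg)
  s2 <- apply_missingness(simulate_peptides(simulate_cohort(cfg), cfg),
                          cfg)
  expect_identical(s1$peptides$abundance, s2$peptides$abundance)
  expect_identical(s1$participants, s2$participants)
  expect_identical(s1$truth$proteins, s2$truth$proteins)
})

test_that("stored truth equals the configured effects exactly", {
  fx <- small_study(seed = 3)
  tr <- fx$st$truth$proteins
  expect_identical(sort(tr$true_effect[tr$true_effect != 0]),
                   sort(fx$cfg$signal_log10_effects))
  expect_true(all(table(fx$pep$map$peptide_id) == 1))
  expect_true(all(fx$pep$map$protein_id %in% tr$protein_id))
})

test_that("health indices hit their target Spearman correlations", {
  targets <- c(self_rated_health = 0.15, sf12_pcs = 0.15,
               healthy_aging_index = 0.15, frailty_index = 0.15)
  rs <- sapply(1:20, function(s) {
    cfg <- sim_config(n_participants = 2000, health_link = targets,
                      seed = s)
    pt <- simulate_cohort(cfg)
    cor(attr(pt, "latent"), pt$frailty_index, method = "spearman")
  })
  expect_lt(abs(mean(rs) - 0.15), 0.05)
})

test_that("survival linkage off makes death independent of the latent score", {
  cfg <- sim_config(n_participants = 3000, survival_link = 0, seed = 21)
  pt <- simulate_cohort(cfg)
  expect_lt(abs(cor(attr(pt, "latent"), pt$died)), 0.05)
})

test_that("null effects give per-protein group differences near zero", {
  fx <- small_study(seed = 11, n = 500, p = 8, signal = 0)
  ab <- fx$st$truth$complete_abundance
  map <- fx$pep$map
  d <- sapply(split(seq_len(ncol(ab)), map$protein_id), function(ix) {
    mean(colMeans(ab[fx$pt$alive90th == 1, ix, drop = FALSE]) -
           colMeans(ab[fx$pt$alive90th == 0, ix, drop = FALSE]))
  })
  n1 <- sum(fx$pt$alive90th == 1); n0 <- sum(fx$pt$alive90th == 0)
  se <- 2 * fx$cfg$protein_sd * sqrt(1 / n1 + 1 / n0)
  expect_true(all(abs(d) < 3 * se))
})

test_that("a planted fold change of -1.2 is recovered by naive group means", {
  diffs <- sapply(1:10, function(s) {
    cfg <- sim_config(n_participants = 1200, n_proteins = 4,
                      n_signal_proteins = 1,
                      signal_log10_effects = -0.0792,
                      mean_peptides = 10, seed = s)
    pt <- simulate_cohort(cfg)
    st <- simulate_peptides(pt, cfg)
    tr <- st$truth$proteins
    sig <- tr$protein_id[tr$true_effect != 0]
    ix <- which(st$peptides$map$protein_id == sig)
    ab <- st$truth$complete_abundance
    mean(colMeans(ab[pt$alive90th == 1, ix, drop = FALSE]) -
           colMeans(ab[pt$alive90th == 0, ix, drop = FALSE]))
  })
  expect_lt(abs(mean(diffs) + 0.0792), 0.01)
})

test_that("block correlation targets are realized", {
  cors <- sapply(1:5, function(s) {
    cfg <- sim_config(n_participants = 1200, n_proteins = 5,
                      n_signal_proteins = 0, n_blocks = 1,
                      block_cor_range = c(0.6, 0.6),
                      peptides_per_protein = c(12, 12),
                      mean_peptides = 12, seed = s)
    pt <- simulate_cohort(cfg)
    st <- simulate_peptides(pt, cfg)
    ab <- st$truth$complete_abundance
    map <- st$peptides$map
    prot <- sapply(split(seq_len(ncol(ab)), map$protein_id),
                   function(ix) rowMeans(ab[, ix, drop = FALSE]))
    cc <- cor(prot)
    mean(cc[upper.tri(cc)])
  })
  # peptide noise attenuates protein-level correlation slightly; the
  # protein signal itself is generated at r = 0.6
  expect_lt(abs(mean(cors) - 0.6), 0.1)
})

test_that("missingness follows the probit retention model", {
  fx <- small_study(seed = 13, n = 400, p = 8, signal = 0)
  cfg0 <- fx$cfg
  # a large, b = 0: nothing missing
  cfg0$missingness <- c(intercept = 10, slope = 0)
  s0 <- apply_missingness(fx$st, cfg0)
  expect_false(anyNA(s0$peptides$abundance))
  # a = 0, b = 0: half the cells missing
  cfg0$missingness <- c(intercept = 0, slope = 0)
  s5 <- apply_missingness(fx$st, cfg0)
  expect_lt(abs(mean(is.na(s5$peptides$abundance)) - 0.5), 0.02)
  # b > 0: missing fraction decreases across abundance deciles
  cfg0$missingness <- c(intercept = 0.5, slope = 1.5)
  sm <- apply_missingness(fx$st, cfg0)
  ab <- fx$st$truth$complete_abundance
  dec <- cut(ab, quantile(ab, 0:10 / 10), include.lowest = TRUE,
             labels = FALSE)
  frac <- tapply(as.vector(is.na(sm$peptides$abundance)), dec, mean)
  expect_true(all(diff(frac) < 0))
  # QC pool rows are never masked
  expect_false(anyNA(sm$peptides$qc_pool))
})
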