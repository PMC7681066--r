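# Per-peptide association models and the selection correction.

test_that("peptide estimates cover a planted effect", {
  hits <- sapply(1:25, function(s) {
    cfg <- sim_config(n_participants = 1200, n_proteins = 3,
                      n_signal_proteins = 1,
                      signal_log10_effects = -0.05, mean_peptides = 3,
                      seed = 100 + s)
    pt <- simulate_cohort(cfg)
    st <- simulate_peptides(pt, cfg)
    eff <- fit_all_peptides(st$peptides, pt, heckman = FALSE)
    tr <- st$truth$proteins
    sig <- tr$protein_id[tr$true_effect != 0]
    e <- eff[eff$protein_id == sig, ][1, ]
    abs(e$beta1 + 0.05) <= 2 * e$se
  })
  expect_gte(mean(hits), 0.85)
})

test_that("permuting the longevity label centers estimates on zero", {
  fx <- small_study(seed = 31, n = 400, p = 6, signal = 3)
  pt <- fx$pt
  set.seed(99)
  pt$alive90th <- sample(pt$alive90th)
  eff <- fit_all_peptides(fx$pep, pt, heckman = FALSE)
  se_mean <- mean(eff$se) / sqrt(nrow(eff))
  # peptides share protein-level noise, so the effective replication is
  # closer to the protein count; allow for that correlation
  expect_lt(abs(mean(eff$beta1)), 6 * se_mean)
})

test_that("constant abundance is flagged as non-converged", {
  fx <- small_study(seed = 4)
  pep <- fx$pep
  pep$abundance[, 1] <- 5
  e <- fit_peptide_model(pep, fx$pt, pep$map$peptide_id[1])
  expect_false(e$converged)
  expect_identical(e$beta1, 0)
  expect_identical(e$se, 0)
})

test_that("fold change is invariant to constant shifts and row order", {
  fx <- small_study(seed = 4)
  pid <- fx$pep$map$peptide_id[2]
  e1 <- fit_peptide_model(fx$pep, fx$pt, pid)
  shifted <- fx$pep
  shifted$abundance[, pid] <- shifted$abundance[, pid] + 2.5
  e2 <- fit_peptide_model(shifted, fx$pt, pid)
  expect_equal(e1$beta1, e2$beta1, tolerance = 1e-10)
  set.seed(5)
  perm <- sample(nrow(fx$pt))
  e3 <- fit_peptide_model(fx$pep, fx$pt[perm, ], pid)
  expect_equal(e1$beta1, e3$beta1, tolerance = 1e-10)
  expect_equal(e1$se, e3$se, tolerance = 1e-10)
})

test_that("a single-group peptide and a sparse peptide are rejected", {
  fx <- small_study(seed = 4, missing = FALSE)
  pep <- fx$pep
  pid <- pep$map$peptide_id[1]
  pep$abundance[fx$pt$alive90th == 1, pid] <- NA
  expect_error(fit_peptide_model(pep, fx$pt, pid), "single")
  pep2 <- fx$pep
  pep2$abundance[-(1:10), pid] <- NA
  expect_error(fit_peptide_model(pep2, fx$pt, pid), "observed values")
})

test_that("compiled probit matches glm.fit", {
  set.seed(12)
  Z <- cbind(1, matrix(rnorm(500 * 4), 500, 4))
  eta <- drop(Z %*% c(0.6, 0.4, -0.3, 0.2, 0))
  s <- rbinom(500, 1, pnorm(eta))
  f <- serolong:::probit_irls_cpp(Z, s)
  g <- glm(s ~ Z - 1, family = binomial("probit"))
  expect_true(f$converged)
  expect_equal(unname(f$gamma), unname(coef(g)), tolerance = 1e-5)
  expect_equal(unname(sqrt(diag(f$Vg))),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-3)
})

test_that("fully observed peptides bypass the selection correction", {
  fx <- small_study(seed = 4)
  pid <- fx$pep$map$peptide_id[3]
  e1 <- fit_peptide_model(fx$pep, fx$pt, pid)
  e2 <- heckman_correct(fx$pep, fx$pt, pid)
  expect_equal(e1$beta1, e2$beta1)
  expect_equal(e1$se, e2$se)
  expect_true(is.na(e2$heckman_lambda_coef))
})

test_that("under MCAR the corrected and naive fits agree", {
  cfg <- sim_config(n_participants = 600, n_proteins = 4,
                    n_signal_proteins = 1,
                    signal_log10_effects = -0.06, mean_peptides = 5,
                    missingness = c(intercept = 0.8, slope = 0),
                    seed = 77)
  pt <- simulate_cohort(cfg)
  st <- apply_missingness(simulate_peptides(pt, cfg), cfg)
  effH <- fit_all_peptides(st$peptides, pt, heckman = TRUE)
  effN <- fit_all_peptides(st$peptides, pt, heckman = FALSE)
  ok <- effH$converged & effN$converged
  expect_lt(mean(abs(effH$beta1[ok] - effN$beta1[ok])), 0.005)
})

test_that("MCAR null type-I error stays near nominal with the correction", {
  # null peptides, moderate MCAR missingness; reject when |z| > 1.96
  rej <- unlist(lapply(1:4, function(s) {
    cfg <- sim_config(n_participants = 500, n_proteins = 25,
                      n_signal_proteins = 0, mean_peptides = 5,
                      missingness = c(intercept = 0.7, slope = 0),
                      seed = 200 + s)
    pt <- simulate_cohort(cfg)
    st <- apply_missingness(simulate_peptides(pt, cfg), cfg)
    eff <- fit_all_peptides(st$peptides, pt, heckman = TRUE)
    eff <- eff[eff$converged & eff$se > 0, ]
    abs(eff$beta1 / eff$se) > 1.96
  }))
  expect_gte(length(rej), 400)
  expect_lte(mean(rej), 0.08)
})
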