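# Bayesian peptide-to-protein meta-analysis.

test_that("MCMC sample size scales with the base-10 log of peptide count", {
  expect_identical(mcmc_size(5), 10000L)
  expect_identical(mcmc_size(10), 10000L)
  expect_identical(mcmc_size(100), 20000L)
  expect_error(mcmc_size(1))
})

test_that("meta_p is the posterior sign-error probability", {
  expect_identical(meta_p(c(-1, -2, -0.1)), 0)
  expect_equal(meta_p(c(-1, 1, -2, 2)), 0.5)
  set.seed(3)
  expect_lt(abs(meta_p(rnorm(4e5, 1.645, 1)) - pnorm(-1.645)), 0.004)
  expect_equal(meta_p(c(0, 0, 1, -1)), 0.5)
  expect_error(meta_p(numeric(0)))
})

test_that("signed fold changes match the log10 thresholds", {
  expect_equal(round(signed_fold_change(0.041), 2), 1.10)
  expect_identical(signed_fold_change(0), 1)
  expect_equal(round(signed_fold_change(-0.08529), 3), -1.217)
  expect_equal(log10_effect_from_fold(signed_fold_change(-0.063)),
               -0.063)
})

test_that("with tau2 fixed at zero the sampler matches the conjugate posterior", {
  set.seed(21)
  for (k in c(3, 8)) {
    y <- rnorm(k, -0.05, 0.03)
    s2 <- runif(k, 0.0004, 0.002)
    g <- gibbs_meta(data.frame(beta1 = y, se = sqrt(s2)),
                    mcmc = mcmc_config(seed = 31, base_samples = 20000),
                    keep_chain = TRUE, fix_tau2 = 0)
    prec <- sum(1 / s2) + 1
    mu_exact <- sum(y / s2) / prec
    sd_exact <- sqrt(1 / prec)
    mcse <- sd(g$chain) / sqrt(serolong:::ess(g$chain))
    expect_lt(abs(g$meta_effect - mu_exact), 4 * mcse)
    expect_lt(abs(sd(g$chain) - sd_exact) / sd_exact, 0.05)
  }
})

test_that("all-zero peptide effects give a symmetric posterior", {
  g <- gibbs_meta(data.frame(beta1 = rep(0, 5), se = rep(0.02, 5)),
                  mcmc = mcmc_config(seed = 13))
  expect_lt(abs(g$meta_effect), 0.005)
  expect_lt(abs(g$meta_p - 0.5), 0.05)
})

test_that("a strong 19-peptide signal recovers a fold change near -1.22", {
  folds <- sapply(1:5, function(s) {
    set.seed(400 + s)
    y <- rnorm(19, -0.085, 0.01)
    g <- gibbs_meta(data.frame(beta1 = y, se = rep(0.008, 19)),
                    mcmc = mcmc_config(seed = 500 + s))
    g$meta_fold
  })
  expect_lt(abs(mean(folds) + 1.22), 0.02)
})

test_that("chains are reproducible and monotone in uniform shifts", {
  ef <- data.frame(beta1 = c(-0.02, -0.05, -0.04), se = rep(0.01, 3))
  g1 <- gibbs_meta(ef, mcmc = mcmc_config(seed = 77), keep_chain = TRUE)
  g2 <- gibbs_meta(ef, mcmc = mcmc_config(seed = 77), keep_chain = TRUE)
  expect_identical(g1$chain, g2$chain)
  ef2 <- ef; ef2$beta1 <- ef$beta1 + 0.03
  g3 <- gibbs_meta(ef2, mcmc = mcmc_config(seed = 77))
  expect_gt(g3$meta_effect, g1$meta_effect)
})

test_that("proteins with fewer than two usable peptides are skipped", {
  expect_error(gibbs_meta(data.frame(beta1 = -0.1, se = 0.01)), ">= 2")
  eff <- data.frame(peptide_id = c("a", "b", "c"),
                    protein_id = c("P1", "P1", "P2"),
                    beta1 = c(-0.1, -0.2, 0.3), se = rep(0.05, 3),
                    converged = TRUE)
  expect_message(m <- meta_analyze_proteins(eff, seed = 1), "skipped")
  expect_identical(m$protein_id, "P1")
})

test_that("the hierarchical posterior matches dense numerical integration", {
  oracle <- function(y, s2, nm = 2001, nt = 2001) {
    # wide grids: the heavy-tailed variance prior lets the meta-effect
    # revert toward its N(0, 1) prior, so the grid must cover that tail
    mus <- seq(-5, 5, length.out = nm)
    lt2 <- seq(log(1e-12), log(1e4), length.out = nt)
    t2 <- exp(lt2)
    lp_mu <- dnorm(mus, 0, 1, log = TRUE)
    lw <- matrix(0, nm, nt)
    for (j in seq_len(nt)) {
      v <- lp_mu + (-1 / 100 - 1) * log(t2[j]) - (1 / 100) / t2[j] +
        lt2[j]
      sds <- sqrt(s2 + t2[j])
      for (i in seq_along(y)) v <- v + dnorm(y[i], mus, sds[i],
                                             log = TRUE)
      lw[, j] <- v
    }
    w <- exp(lw - max(lw)); w <- w / sum(w)
    pm <- sum(rowSums(w) * mus)
    c(mean = pm, sd = sqrt(sum(rowSums(w) * mus^2) - pm^2))
  }
  set.seed(8)
  for (case in 1:2) {
    y <- rnorm(3, -0.06, 0.05)
    s2 <- runif(3, 0.0005, 0.003)
    g <- gibbs_meta(data.frame(beta1 = y, se = sqrt(s2)),
                    mcmc = mcmc_config(seed = 600 + case,
                                       base_samples = 150000),
                    keep_chain = TRUE)
    o <- oracle(y, s2)
    mcse <- sd(g$chain) / sqrt(serolong:::ess(g$chain))
    expect_lt(abs(g$meta_effect - o["mean"]), 3 * mcse)
    expect_lt(abs(sd(g$chain) - o["sd"]) / o["sd"], 0.02)
  }
})
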