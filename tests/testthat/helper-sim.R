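# Shared fixtures, built in code. The large cohort used by the
# selection-recovery and classifier checks is expensive, so it is
# computed once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# A small complete study (no missingness) for unit tests.
small_study <- function(seed = 7, n = 300, p = 10, signal = 3,
                        mean_pep = 4, missing = FALSE, ...) {
  key <- paste("small", seed, n, p, signal, mean_pep, missing,
               paste(unlist(list(...)), collapse = "_"), sep = "_")
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  cfg <- sim_config(n_participants = n, n_proteins = p,
                    n_signal_proteins = signal, mean_peptides = mean_pep,
                    seed = seed, ...)
  pt <- simulate_cohort(cfg)
  st <- simulate_peptides(pt, cfg)
  if (missing) st <- apply_missingness(st, cfg)
  out <- list(cfg = cfg, pt = pt, st = st, pep = st$peptides)
  .fixtures[[key]] <- out
  out
}

# Paper-scale cohort + full selection pipeline (seed fixed a priori).
# Shared by the tier-recovery and classifier reproduction checks.
big_cohort_run <- function() {
  if (!is.null(.fixtures$big)) return(.fixtures$big)
  cfg <- sim_config(seed = 424242L)
  pt <- simulate_cohort(cfg)
  st <- apply_missingness(simulate_peptides(pt, cfg), cfg)
  pep <- normalize_abundances(st$peptides,
                              groups = setNames(pt$alive90th, pt$id))
  eff <- fit_all_peptides(pep, pt)
  meta <- suppressMessages(
    meta_analyze_proteins(eff, seed = cfg$seed, keep_chains = TRUE))
  boot <- suppressWarnings(jackknife_replicates(
    pep, pt, B = 50, seed = cfg$seed, full = meta,
    mcmc = mcmc_config(burn_in = 500, base_samples = 2000)))
  tier1 <- select_tier1(boot)
  truth <- st$truth$proteins
  .fixtures$big <- list(cfg = cfg, pt = pt, st = st, pep = pep,
                        eff = eff, meta = meta, boot = boot,
                        tier1 = tier1,
                        signal = truth$protein_id[truth$true_effect != 0])
  .fixtures$big
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Two-block protein matrix with the given within-block correlation.
planted_blocks <- function(n, per_block, r, n_blocks = 2, seed = 1) {
  set.seed(seed)
  mat <- do.call(cbind, lapply(seq_len(n_blocks), function(b) {
    f <- rnorm(n)
    sapply(seq_len(per_block), function(j)
      sqrt(r) * f + sqrt(1 - r) * rnorm(n))
  }))
  colnames(mat) <- sprintf("PR%02d", seq_len(ncol(mat)))
  rownames(mat) <- sprintf("S%04d", seq_len(n))
  list(mat = mat, truth = rep(seq_len(n_blocks), each = per_block))
}
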