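# Internal helpers shared across stages.

# Run an expression under a temporary RNG state seeded from `seed`.
# Every stochastic stage goes through this so stages can be re-run
# independently and full runs are reproducible from one integer.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Fixed offsets for per-stage sub-streams; kept well below 2^31.
seed_offset <- function(seed, stage) {
  offs <- c(cohort = 11L, peptides = 23L, missing = 37L, jackknife = 53L,
            gibbs = 71L, cv = 89L, cluster = 97L)
  (as.integer(seed) %% 1000000L) * 1000L + offs[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Effective sample size of a chain from its fitted AR spectrum at
# frequency zero (same idea as the spectral estimator in coda).
ess <- function(x) {
  n <- length(x)
  if (n < 10 || var(x) == 0) return(n)
  v0 <- tryCatch({
    fit <- ar(x, aic = TRUE, order.max = min(50, floor(n / 10)))
    fit$var.pred / (1 - sum(fit$ar))^2
  }, error = function(e) var(x))
  max(1, min(n, n * var(x) / v0))
}

# Geweke convergence diagnostic: z-score comparing the mean of the first
# 10% of the chain to the last 50%, with spectral variance estimates.
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2, floor(frac2 * n)) + 1, n)]
  sv <- function(y) {
    m <- length(y)
    v <- tryCatch({
      fit <- ar(y, aic = TRUE, order.max = min(30, floor(m / 10)))
      fit$var.pred / (1 - sum(fit$ar))^2
    }, error = function(e) var(y))
    v / m
  }
  d <- sv(a) + sv(b)
  if (!is.finite(d) || d <= 0) return(0)
  (mean(a) - mean(b)) / sqrt(d)
}
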