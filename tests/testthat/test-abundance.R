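# Protein abundance estimation, clustering, scores, health links.

test_that("crossed-random-effects estimates track participant means on balanced data", {
  fx <- small_study(seed = 61, n = 150, p = 4, signal = 0, mean_pep = 6)
  amat <- estimate_protein_abundance(fx$pep, fx$pt)
  map <- fx$pep$map
  for (p in colnames(amat)[1:2]) {
    ix <- which(map$protein_id == p)
    ctr <- sweep(fx$pep$abundance[, ix, drop = FALSE], 2,
                 colMeans(fx$pep$abundance[, ix, drop = FALSE]))
    pm <- rowMeans(ctr)
    # shrinkage preserves ordering and nearly all the signal
    expect_gt(cor(amat[, p], pm), 0.99)
    sl <- coef(lm(amat[, p] ~ pm))[2]
    expect_true(sl > 0.7 && sl <= 1.001)
  }
})

test_that("a constant shift of one peptide does not move participants", {
  fx <- small_study(seed = 61, n = 150, p = 4, signal = 0, mean_pep = 6)
  p1 <- unique(fx$pep$map$protein_id)[1]
  j <- which(fx$pep$map$protein_id == p1)[1]
  pep2 <- fx$pep
  pep2$abundance[, j] <- pep2$abundance[, j] + 1.7
  a1 <- estimate_protein_abundance(fx$pep, fx$pt, proteins = p1)
  a2 <- estimate_protein_abundance(pep2, fx$pt, proteins = p1)
  d <- a2[, p1] - a1[, p1]
  expect_lt(diff(range(d)), 1e-6)  # all participants move equally
})

test_that("estimates shift with a protein-wide constant and recover truth", {
  fx <- small_study(seed = 62, n = 250, p = 3, signal = 0, mean_pep = 10,
                    protein_sd = 0.1)
  amat <- estimate_protein_abundance(fx$pep, fx$pt)
  map <- fx$pep$map
  truthp <- sapply(split(seq_len(ncol(fx$st$truth$complete_abundance)),
                         map$protein_id), function(ix)
    rowMeans(fx$st$truth$complete_abundance[, ix, drop = FALSE]))
  for (p in colnames(amat))
    expect_gt(cor(amat[, p], truthp[, p]), 0.9)
  pep2 <- fx$pep
  ix <- which(map$protein_id == colnames(amat)[1])
  pep2$abundance[, ix] <- pep2$abundance[, ix] + 0.5
  a2 <- estimate_protein_abundance(pep2, fx$pt,
                                   proteins = colnames(amat)[1])
  expect_equal(unname(a2[, 1] - amat[, 1]), rep(0.5, nrow(amat)),
               tolerance = 1e-6)
})

test_that("Gower distance on standardized profiles is range-scaled Manhattan", {
  pb <- planted_blocks(60, 4, 0.5, seed = 3)
  X <- t(scale(pb$mat))
  d <- as.matrix(cluster::daisy(as.data.frame(X), metric = "gower"))
  rng <- apply(X, 2, function(v) diff(range(v)))
  manual <- matrix(0, nrow(X), nrow(X))
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(X)))
    manual[i, j] <- mean(abs(X[i, ] - X[j, ]) / rng)
  expect_equal(unname(d), manual, tolerance = 1e-10)
})

test_that("planted two-block structure is recovered exactly", {
  pb <- planted_blocks(300, 8, 0.8, seed = 42)
  cl <- cluster_proteins(pb$mat, seed = 5)
  expect_identical(cl$k, 2)
  expect_equal(adjusted_rand(cl$cluster, pb$truth), 1)
})

test_that("independent proteins are not split into spurious clusters", {
  set.seed(9)
  mat <- matrix(rnorm(300 * 12), 300, 12,
                dimnames = list(NULL, sprintf("P%02d", 1:12)))
  cl <- cluster_proteins(mat, seed = 5)
  expect_lte(cl$k, 2)
  if (cl$k > 1)
    expect_lt(abs(adjusted_rand(cl$cluster, rep(1:2, each = 6))), 0.2)
})

test_that("clustering is invariant to column order and affine rescaling", {
  pb <- planted_blocks(200, 6, 0.7, seed = 11)
  cl1 <- cluster_proteins(pb$mat, seed = 5)
  perm <- c(7:12, 1:6)
  cl2 <- cluster_proteins(pb$mat[, perm], seed = 5)
  expect_equal(adjusted_rand(cl1$cluster[colnames(pb$mat)[perm]],
                             cl2$cluster), 1)
  mat3 <- pb$mat
  mat3[, 2] <- 10 * mat3[, 2] - 4
  cl3 <- cluster_proteins(mat3, seed = 5)
  expect_equal(adjusted_rand(cl1$cluster, cl3$cluster), 1)
  # identical duplicate columns sit at distance zero and merge first
  mat4 <- cbind(pb$mat, dup = pb$mat[, 1])
  hc <- cluster_proteins(mat4, seed = 5)$hclust
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
})

test_that("abundance scores are standardized sums of protein z-scores", {
  pb <- planted_blocks(200, 5, 0.5, seed = 21)
  sc <- abundance_score(pb$mat, colnames(pb$mat))
  expect_equal(mean(sc), 0, tolerance = 1e-12)
  expect_equal(sd(sc), 1, tolerance = 1e-12)
  one <- abundance_score(pb$mat, colnames(pb$mat)[1])
  expect_equal(unname(one), as.numeric(scale(pb$mat[, 1])),
               tolerance = 1e-12)
  # a duplicated protein does not change the participant ranking
  dup <- cbind(pb$mat, dup = pb$mat[, 1])
  sc2 <- abundance_score(dup, c("PR01", "dup"))
  expect_equal(order(sc2), order(abundance_score(pb$mat, "PR01")))
  expect_error(abundance_score(pb$mat, character(0)), "empty")
})

test_that("health correlations are rank-based and handle degenerate indices", {
  fx <- small_study(seed = 71, n = 600, p = 4, signal = 2)
  sc <- setNames(rnorm(600), fx$pt$id)
  h0 <- health_correlations(sc, fx$pt)
  expect_true(all(abs(h0$rho) < 0.12))
  latent <- attr(fx$pt, "latent")
  h1 <- health_correlations(setNames(latent, fx$pt$id), fx$pt)
  h2 <- health_correlations(setNames(exp(latent), fx$pt$id), fx$pt)
  expect_equal(h1$rho, h2$rho, tolerance = 1e-12)
  pt2 <- fx$pt
  pt2$frailty_index <- 1
  h3 <- health_correlations(sc, pt2)
  expect_true(is.na(h3$rho[h3$index == "frailty_index"]))
})

test_that("synthetic health linkage is recovered at the configured magnitude", {
  rs <- sapply(1:3, function(s) {
    fx <- small_study(seed = 300 + s, n = 1200, p = 6, signal = 3,
                      mean_pep = 5)
    sc <- setNames(attr(fx$pt, "latent"), fx$pt$id)
    h <- health_correlations(sc, fx$pt)
    h$rho[h$index == "frailty_index"]
  })
  expect_lt(abs(mean(rs) - 0.192), 0.06)
})
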