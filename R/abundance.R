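# Per-participant protein abundance estimation, protein clustering,
# abundance summary scores, and health-index correlations.

#' Estimate per-participant protein abundances
#'
#' Fits, per protein, a crossed-random-effects model on the observed
#' peptide cells: `abundance ~ intercept + (1 | participant) +
#' (1 | peptide)`. A participant's protein level is the total predicted
#' value minus the peptide BLUP, i.e. the fixed intercept plus the
#' participant random effect; participants with no observed peptides for
#' a protein receive the fixed intercept. When the fit is singular
#' (variance components at the boundary) the estimate falls back to the
#' participant means of peptide-centered values.
#'
#' @param peptides A `serolong_peptides` object.
#' @param participants Participant table (defines row order).
#' @param proteins Optional protein ids to estimate (default: all with
#'   at least `min_peptides` peptides).
#' @param min_peptides Minimum peptides per protein (default 2).
#' @return A participants x proteins matrix of log10 abundance
#'   estimates (no missing entries), with per-protein peptide counts in
#'   attribute `"provenance"`.
#' @export
estimate_protein_abundance <- function(peptides, participants,
                                       proteins = NULL,
                                       min_peptides = 2) {
  map <- peptides$map
  counts <- table(map$protein_id)
  eligible <- names(counts)[counts >= min_peptides]
  if (is.null(proteins)) proteins <- unique(map$protein_id[
    map$protein_id %in% eligible])
  bad <- setdiff(proteins, eligible)
  if (length(bad))
    stopf("protein(s) with < %d peptides: %s", min_peptides,
          paste(head(bad, 5), collapse = ", "))
  ab <- peptides$abundance[participants$id, , drop = FALSE]
  n <- nrow(ab)
  out <- matrix(NA_real_, n, length(proteins),
                dimnames = list(participants$id, proteins))
  prov <- setNames(integer(length(proteins)), proteins)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  for (j in seq_along(proteins)) {
    ix <- which(map$protein_id == proteins[j])
    prov[j] <- length(ix)
    sub <- ab[, ix, drop = FALSE]
    obs <- which(!is.na(sub), arr.ind = TRUE)
    df <- data.frame(value = sub[obs],
                     pid = factor(rownames(sub)[obs[, 1]],
                                  levels = rownames(sub)),
                     pep = factor(obs[, 2]))
    est <- NULL
    if (nlevels(droplevels(df$pep)) >= 2) {
      fit <- tryCatch(suppressMessages(
        lme4::lmer(value ~ 1 + (1 | pid) + (1 | pep), data = df,
                   control = ctrl)), error = function(e) NULL)
      if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
        mu <- unname(lme4::fixef(fit)[1])
        re <- lme4::ranef(fit)$pid
        est <- rep(mu, n)
        est[match(rownames(re), participants$id)] <- mu + re[[1]]
      }
    }
    if (is.null(est)) {
      # boundary / degenerate fit: participant means of peptide-centered
      # values, anchored at the protein's overall mean level
      ctr <- sweep(sub, 2, colMeans(sub, na.rm = TRUE), "-")
      pm <- rowMeans(ctr, na.rm = TRUE)
      pm[is.nan(pm)] <- 0
      est <- mean(sub, na.rm = TRUE) + pm
    }
    out[, j] <- est
  }
  attr(out, "provenance") <- prov
  out
}

# Within-cluster sum of squared deviations from the centroid.
cluster_sse <- function(X) {
  if (nrow(X) <= 1) return(0)
  sum(sweep(X, 2, colMeans(X))^2)
}

# Null distribution of the Ward best-split Je(2)/Je(1) ratio for a
# single spherical Gaussian cluster of m points in p dimensions,
# estimated by Monte Carlo. The classical closed-form critical value
# assumes m >> p; protein-profile clustering has p >> m, where the
# closed form badly over-splits, so the null is simulated instead.
null_split_ratios <- function(m, p, sims) {
  vapply(seq_len(sims), function(i) {
    Z <- matrix(rnorm(m * p), m, p)
    hc <- hclust(dist(Z), method = "ward.D2")
    cl <- cutree(hc, 2)
    (cluster_sse(Z[cl == 1, , drop = FALSE]) +
        cluster_sse(Z[cl == 2, , drop = FALSE])) / cluster_sse(Z)
  }, numeric(1))
}

# Classical Duda-Hart critical ratio (observations >> dimensions).
duda_hart_critical <- function(m, p, z = 3.2) {
  1 - 2 / (pi * p) - z * sqrt(2 * (1 - 8 / (pi^2 * p)) / (m * p))
}

#' Cluster proteins by Gower dissimilarity and Ward linkage
#'
#' Standardizes the abundance matrix per protein, computes Gower
#' dissimilarities between protein profiles (participants as
#' variables), agglomerates with Ward's linkage (squared-distance
#' update), and chooses the number of clusters by a Duda-Hart stopping
#' rule: scanning k upward, the split taking k to k+1 clusters is
#' accepted while its Je(2)/Je(1) ratio is significantly small, and the
#' scan stops at the first non-rejection. By default the null
#' distribution of the ratio is calibrated by Monte Carlo simulation of
#' a single spherical Gaussian cluster of the same shape
#' (`rule = "mc"`); the classical closed-form critical value is
#' available with `rule = "classical"`.
#'
#' @param mat Participants x proteins abundance matrix.
#' @param max_k Largest cluster count scanned.
#' @param rule Null calibration for the stopping rule.
#' @param null_sims Monte-Carlo replicates per split test.
#' @param alpha Test level for the Monte-Carlo rule.
#' @param z Critical z for the classical rule.
#' @param seed Seed for the Monte-Carlo null draws.
#' @return A `serolong_clusters` list: `cluster` (named membership),
#'   `k`, `heights` (Ward merge heights), and the `hclust` tree.
#' @export
cluster_proteins <- function(mat, max_k = NULL,
                             rule = c("mc", "classical"),
                             null_sims = 25, alpha = 0.05, z = 3.2,
                             seed = 1) {
  rule <- match.arg(rule)
  if (ncol(mat) < 3) stopf("need at least 3 proteins to cluster")
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    warnf("removing %d constant protein column(s)", sum(sds == 0))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  X <- t(scale(mat))              # proteins x participants, standardized
  d <- cluster::daisy(as.data.frame(X), metric = "gower")
  hc <- hclust(d, method = "ward.D2")
  m <- nrow(X); p <- ncol(X)
  if (is.null(max_k)) max_k <- min(m - 1, 25)
  k <- 1
  with_seed(seed_offset(seed, "cluster"), {
    while (k < max_k) {
      cl_k <- cutree(hc, k)
      cl_k1 <- cutree(hc, k + 1)
      split_of <- which(tabulate(cl_k[!duplicated(cl_k1)]) == 2)[1]
      members <- which(cl_k == split_of)
      if (length(members) < 3) break
      Xm <- X[members, , drop = FALSE]
      je1 <- cluster_sse(Xm)
      kids <- cl_k1[members]
      je2 <- sum(vapply(unique(kids), function(g)
        cluster_sse(Xm[kids == g, , drop = FALSE]), numeric(1)))
      ratio <- je2 / je1
      crit <- if (rule == "mc")
        quantile(null_split_ratios(length(members), p, null_sims), alpha)
      else duda_hart_critical(length(members), p, z)
      if (ratio >= crit) break   # split not significant: stop at k
      k <- k + 1
    }
  })
  membership <- cutree(hc, k)
  structure(list(cluster = setNames(membership, rownames(X)), k = k,
                 heights = hc$height, hclust = hc),
            class = "serolong_clusters")
}

#' Standardized protein abundance summary score
#'
#' Standardizes the abundance of each protein in the set, sums the
#' z-scores per participant, and standardizes the total; a lower score
#' means generally lower abundance of the set. When a cluster
#' assignment is supplied, per-cluster subscores (means of member
#' z-scores) are attached.
#'
#' @param mat Participants x proteins abundance matrix.
#' @param proteins Protein ids forming the score set.
#' @param clusters Optional `serolong_clusters` or named membership
#'   vector for subscores.
#' @return Named numeric score per participant (mean 0, SD 1), with
#'   attribute `"cluster_scores"` when clusters are given.
#' @export
abundance_score <- function(mat, proteins, clusters = NULL) {
  if (length(proteins) == 0) stopf("empty protein set")
  missing <- setdiff(proteins, colnames(mat))
  if (length(missing))
    stopf("proteins not in the abundance matrix: %s",
          paste(head(missing, 5), collapse = ", "))
  Z <- scale(mat[, proteins, drop = FALSE])
  total <- rowSums(Z)
  score <- as.numeric(scale(total))
  names(score) <- rownames(mat)
  if (!is.null(clusters)) {
    memb <- if (inherits(clusters, "serolong_clusters")) clusters$cluster
            else clusters
    memb <- memb[intersect(names(memb), proteins)]
    cs <- sapply(split(names(memb), memb), function(ids)
      rowMeans(Z[, ids, drop = FALSE]))
    attr(score, "cluster_scores") <- cs
  }
  score
}

#' Spearman correlations of a score with health indices
#'
#' Correlates a per-participant score with self-rated health, the SF-12
#' physical component, the Healthy Aging Index and the frailty index
#' (whichever are present), using Spearman's rank correlation.
#'
#' @param score Named numeric vector (names = participant ids) or plain
#'   vector aligned with `participants`.
#' @param participants Participant table with health-index columns.
#' @return A `data.frame` (index, rho, p_value, n); indices with zero
#'   variance are reported with `NA` correlation.
#' @export
health_correlations <- function(score, participants) {
  idx <- intersect(c("self_rated_health", "sf12_pcs",
                     "healthy_aging_index", "frailty_index"),
                   names(participants))
  if (length(idx) == 0) stopf("no health-index columns present")
  s <- if (!is.null(names(score))) score[participants$id] else score
  rows <- lapply(idx, function(nm) {
    x <- participants[[nm]]
    ok <- is.finite(x) & is.finite(s)
    if (sd(x[ok]) == 0)
      return(data.frame(index = nm, rho = NA_real_, p_value = NA_real_,
                        n = sum(ok)))
    ct <- suppressWarnings(cor.test(s[ok], x[ok], method = "spearman",
                                    exact = FALSE))
    data.frame(index = nm, rho = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok))
  })
  do.call(rbind, rows)
}
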