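# Longevity classification: Mahalanobis subset reduction, all-subsets
# logistic regression with Bayesian model averaging, and ROC summaries.

group_mahalanobis <- function(mat, labels, ridge = 1e-8) {
  g1 <- mat[labels == 1, , drop = FALSE]
  g0 <- mat[labels == 0, , drop = FALSE]
  S <- ((nrow(g1) - 1) * cov(g1) + (nrow(g0) - 1) * cov(g0)) /
    (nrow(g1) + nrow(g0) - 2)
  dm <- colMeans(g1) - colMeans(g0)
  Si <- tryCatch(solve(S), error = function(e) {
    solve(S + diag(ridge * mean(diag(S)), ncol(S)))
  })
  sqrt(drop(t(dm) %*% Si %*% dm))
}

#' Mahalanobis-based reduction of a candidate protein set
#'
#' Backward elimination on the between-group Mahalanobis separation:
#' starting from all candidates, iteratively drops the protein whose
#' removal least reduces the separation of the two longevity groups,
#' and stops when any further removal would push the separation below
#' `(1 - tol)` times the full-set separation.
#'
#' @param mat Participants x proteins abundance matrix.
#' @param labels Binary longevity labels aligned with the rows.
#' @param candidates Candidate protein ids (columns of `mat`).
#' @param tol Allowed fractional loss of separation (default 0.02).
#' @return Character vector of retained protein ids, with the full-set
#'   and retained separations as attributes.
#' @export
mahalanobis_subset <- function(mat, labels, candidates, tol = 0.02) {
  if (length(candidates) < 2) stopf("need at least 2 candidate proteins")
  stopifnot(all(candidates %in% colnames(mat)))
  full_sep <- group_mahalanobis(mat[, candidates, drop = FALSE], labels)
  floor_sep <- (1 - tol) * full_sep
  keep <- candidates
  repeat {
    if (length(keep) <= 2) break
    seps <- vapply(keep, function(drop_id)
      group_mahalanobis(mat[, setdiff(keep, drop_id), drop = FALSE],
                        labels), numeric(1))
    best <- which.max(seps)
    if (seps[best] < floor_sep) break
    keep <- setdiff(keep, keep[best])
  }
  structure(keep, full_separation = full_sep,
            retained_separation =
              group_mahalanobis(mat[, keep, drop = FALSE], labels))
}

# Fast logistic fit returning BIC and fitted probabilities; NULL when
# the fit fails or separates.
logistic_bic <- function(X, y) {
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients))
    return(NULL)
  if (any(fit$fitted.values > 1 - 1e-10 | fit$fitted.values < 1e-10))
    return(NULL)
  list(bic = fit$deviance + log(length(y)) * fit$rank,
       prob = fit$fitted.values, coef = fit$coefficients)
}

#' All-subsets logistic regression with Bayesian model averaging
#'
#' Fits an age-adjusted maximum-likelihood logistic regression of the
#' longevity label on every nonempty subset of the given proteins,
#' weights models by `exp(-BIC/2)` (a unit-information approximation to
#' the posterior model probability under a uniform model prior), and
#' averages the per-participant predicted probabilities across models.
#'
#' @param mat Participants x proteins abundance matrix.
#' @param labels Binary longevity labels.
#' @param subset Protein ids to search over (at most 16).
#' @param age Optional age covariate included in every model.
#' @return A `serolong_bma` list: `models` (subset bitmasks, BICs,
#'   weights), `weights`, `prob` (BMA-averaged probabilities),
#'   `inclusion` (per-protein posterior inclusion probability),
#'   `n_failed`.
#' @export
all_subsets_logistic <- function(mat, labels, subset, age = NULL) {
  if (length(subset) > 16)
    stopf("subset of %d proteins exceeds the 2^16 model cap",
          length(subset))
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  Z <- scale(mat[, subset, drop = FALSE])
  base <- if (is.null(age)) cbind(`(Intercept)` = rep(1, length(labels)))
          else cbind(`(Intercept)` = 1, age = age)
  p <- length(subset)
  n_models <- 2^p - 1
  bics <- rep(NA_real_, n_models)
  probs <- matrix(NA_real_, length(labels), n_models)
  coefs <- vector("list", n_models)
  n_failed <- 0L
  for (m in seq_len(n_models)) {
    cols <- which(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0)
    f <- logistic_bic(cbind(base, Z[, cols, drop = FALSE]), labels)
    if (is.null(f)) { n_failed <- n_failed + 1L; next }
    bics[m] <- f$bic
    probs[, m] <- f$prob
    coefs[[m]] <- f$coef
  }
  ok <- which(is.finite(bics))
  if (!length(ok)) stopf("no candidate model converged")
  w <- exp(-(bics[ok] - min(bics[ok])) / 2)
  w <- w / sum(w)
  avg <- drop(probs[, ok, drop = FALSE] %*% w)
  incl <- vapply(seq_len(p), function(j) {
    has <- bitwAnd(ok, bitwShiftL(1L, j - 1L)) != 0
    sum(w[has])
  }, numeric(1))
  structure(list(models = data.frame(mask = ok, bic = bics[ok],
                                     weight = w),
                 weights = w, prob = avg,
                 inclusion = setNames(incl, subset),
                 subset = subset, n_failed = n_failed,
                 coefs = coefs[ok],
                 center = attr(Z, "scaled:center"),
                 scale = attr(Z, "scaled:scale")),
            class = "serolong_bma")
}

#' ROC area under the curve with a DeLong confidence band
#'
#' AUC computed from midranks (the Wilcoxon statistic, ties handled by
#' midranks) with the DeLong variance estimate for the confidence band.
#'
#' @param probabilities Numeric scores (higher = more likely positive).
#' @param labels Binary labels.
#' @param conf_level Confidence level of the band.
#' @return A list: `auc`, `se`, `ci` (truncated to `[0, 1]`), `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(probabilities, labels, conf_level = 0.95) {
  pos <- probabilities[labels == 1]
  neg <- probabilities[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stopf("both classes must be present")
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  # DeLong placement values
  v10 <- (rank(c(pos, neg))[seq_len(m)] -
            rank(pos)) / n                     # per-positive placements
  v01 <- (rank(c(neg, pos))[seq_len(n)] - rank(neg)) / m
  v01 <- 1 - v01
  s2 <- var(v10) / m + var(v01) / n
  se <- sqrt(max(s2, 0))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  list(auc = auc, se = se,
       ci = pmin(1, pmax(0, c(auc - zq * se, auc + zq * se))),
       n_pos = m, n_neg = n)
}

#' Cross-validated BMA classification AUC
#'
#' K-fold cross-validation of the Bayesian model-averaged classifier:
#' within each training fold the models are refit and reweighted, and
#' held-out participants receive the weight-averaged probability. The
#' protein subset itself is fixed (chosen upstream), mirroring an
#' in-sample subset choice with honest per-fold coefficients.
#'
#' @inheritParams all_subsets_logistic
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @return A list: `auc` (list from [roc_auc()] on the out-of-fold
#'   probabilities), `prob`, `folds`.
#' @export
cv_bma_auc <- function(mat, labels, subset, age = NULL, k = 5, seed = 1) {
  n <- length(labels)
  folds <- with_seed(seed_offset(seed, "cv"), {
    f <- rep(NA_integer_, n)
    for (g in unique(labels))   # stratified folds
      f[labels == g] <- sample(rep(seq_len(k),
                                   length.out = sum(labels == g)))
    f
  })
  prob <- rep(NA_real_, n)
  p <- length(subset)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    fit <- all_subsets_logistic(mat[tr, , drop = FALSE], labels[tr],
                                subset, age = age[tr])
    Zte <- sweep(sweep(mat[!tr, subset, drop = FALSE], 2, fit$center),
                 2, fit$scale, "/")
    base <- if (is.null(age)) cbind(`(Intercept)` = rep(1, sum(!tr)))
            else cbind(`(Intercept)` = 1, age = age[!tr])
    pr <- matrix(NA_real_, sum(!tr), nrow(fit$models))
    for (i in seq_len(nrow(fit$models))) {
      cols <- which(bitwAnd(fit$models$mask[i],
                            bitwShiftL(1L, seq_len(p) - 1L)) != 0)
      Xte <- cbind(base, Zte[, cols, drop = FALSE])
      pr[, i] <- plogis(drop(Xte %*% fit$coefs[[i]]))
    }
    okm <- colSums(is.na(pr)) == 0
    w <- fit$models$weight[okm]; w <- w / sum(w)
    prob[!tr] <- drop(pr[, okm, drop = FALSE] %*% w)
  }
  list(auc = roc_auc(prob, labels), prob = prob, folds = folds)
}
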