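#' Normalize peptide abundances against pooled technical controls
#'
#' Removes per-sample technical offsets estimated from the peptides that
#' were detected in every pooled-QC control run (the "QC-complete" set).
#' For each sample, the offset is the median, over QC-complete peptides
#' observed in that sample, of the deviation from the peptide's median
#' across samples; the offset is subtracted from every observed value of
#' the sample. A per-peptide technical coefficient of variation is
#' estimated from the QC replicate spread on the log10 scale and stored
#' as an attribute.
#'
#' When `groups` is supplied (e.g. the longevity label), the estimated
#' offsets are centered within each group before subtraction. Offsets
#' estimated from sample medians absorb a slice of any real biological
#' group difference (the median shifts when many analytes move
#' together), and subtracting them leaks that difference out of every
#' peptide; group-centering protects the design contrast, in the same
#' spirit as design-aware batch correction.
#'
#' @param peptides A `serolong_peptides` object (see
#'   [simulate_peptides()] or [read_study()]).
#' @param groups Optional vector (named by participant id, or aligned
#'   with the abundance rows) of group labels to protect.
#' @return The object with normalized `abundance` and attributes
#'   `"sample_offsets"` (per-sample log10 offsets) and
#'   `"technical_cv"` (per-peptide CV, as a fraction).
#' @export
normalize_abundances <- function(peptides, groups = NULL) {
  qc <- peptides$qc_pool
  if (is.null(qc) || nrow(qc) == 0) stopf("QC pool is empty")
  qc_complete <- colSums(!is.na(qc)) == nrow(qc)
  if (!any(qc_complete))
    stopf("no peptide is observed in all QC replicates; cannot normalize")
  ab <- peptides$abundance
  ref <- apply(ab[, qc_complete, drop = FALSE], 2, median, na.rm = TRUE)
  dev <- sweep(ab[, qc_complete, drop = FALSE], 2, ref, "-")
  offsets <- apply(dev, 1, median, na.rm = TRUE)
  offsets[is.na(offsets)] <- 0
  if (!is.null(groups)) {
    g <- if (!is.null(names(groups))) groups[rownames(ab)] else groups
    if (length(g) != nrow(ab))
      stopf("groups must cover every abundance row")
    offsets <- offsets - ave(offsets, g)
  }
  peptides$abundance <- ab - offsets
  sd_log10 <- apply(qc, 2, sd, na.rm = TRUE)
  cv <- sqrt(exp((sd_log10 * log(10))^2) - 1)
  attr(peptides, "sample_offsets") <- offsets
  attr(peptides, "technical_cv") <- setNames(cv, peptides$map$peptide_id)
  peptides
}

#' Flag multivariate outlier participants
#'
#' Summarizes each participant by per-protein mean abundances of the
#' observed peptides (column-median completion for wholly missing
#' proteins), projects the standardized summary onto its leading
#' principal components, and computes robust squared Mahalanobis
#' distances (robust location/scatter via [MASS::cov.rob()]).
#' Participants whose squared distance exceeds the chi-square quantile
#' at `level` (df = number of components) are flagged.
#'
#' @param peptides A `serolong_peptides` object.
#' @param n_pcs Number of principal components for the robust distance.
#' @param level Chi-square quantile defining the exclusion threshold.
#' @param seed Seed for the robust-covariance subsampling (the MCD/MVE
#'   search is stochastic; fixing it keeps the pipeline deterministic).
#' @return Character vector of flagged participant ids (may be empty),
#'   with the squared distances as attribute `"distance"`.
#' @export
flag_outliers <- function(peptides, n_pcs = 10, level = 0.999,
                          seed = 1) {
  ab <- peptides$abundance
  if (nrow(ab) < 10) stopf("need at least 10 participants to flag outliers")
  prot <- factor(peptides$map$protein_id,
                 levels = unique(peptides$map$protein_id))
  # per-participant, per-protein means of observed peptides
  summ <- sapply(split(seq_len(ncol(ab)), prot), function(ix)
    rowMeans(ab[, ix, drop = FALSE], na.rm = TRUE))
  for (j in seq_len(ncol(summ))) {
    med <- median(summ[, j], na.rm = TRUE)
    summ[!is.finite(summ[, j]), j] <- med
  }
  sds <- apply(summ, 2, sd)
  keep <- sds > 0
  z <- scale(summ[, keep, drop = FALSE])
  q <- min(n_pcs, ncol(z), nrow(z) - 1)
  sv <- svd(z, nu = q, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(q)], q, q)
  d2 <- tryCatch({
    rob <- with_seed(seed, MASS::cov.rob(scores))
    mahalanobis(scores, rob$center, rob$cov)
  }, error = function(e) {
    warnf("robust covariance failed (%s); falling back to diagonal",
          conditionMessage(e))
    mahalanobis(scores, colMeans(scores), diag(apply(scores, 2, var), q, q))
  })
  flagged <- rownames(ab)[d2 > qchisq(level, df = q)]
  attr(flagged, "distance") <- setNames(d2, rownames(ab))
  flagged
}
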