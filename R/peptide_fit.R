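# Per-peptide longevity association models.
#
# Outcome model per peptide (observed rows only):
#   log10 abundance ~ mu + b1*alive90th + b2*age + b3*cumhazard
#                     + site indicators + imputed indicator + error
# The fold difference long-lived vs not is the antilog of b1.
# Abundance-dependent missingness is handled by a Heckman two-step
# correction: a probit of the observation indicator on the outcome
# covariates plus an exclusion variable (the participant's mean
# abundance over the peptide's protein block), then the outcome model
# augmented with the inverse Mills ratio and a protein-level error
# control, with a covariance corrected for the estimated first step.
#
# Internal fitters return bare numeric rows c(beta1, se, n_obs,
# lambda_coef, converged); the exported functions assemble data.frames.
# Column 2 of the design is always the longevity label.

# Outcome-model design matrix shared by all peptides (no imputed column;
# that one is cell-specific and appended per peptide).
outcome_design <- function(participants) {
  site <- factor(participants$site)
  X <- cbind(`(Intercept)` = 1, alive90th = participants$alive90th,
             age = participants$age, cumhazard = participants$cumhazard)
  if (nlevels(site) > 1) {
    S <- model.matrix(~ site)[, -1, drop = FALSE]
    X <- cbind(X, S)
  }
  X
}

BETA1_COL <- 2L  # position of the longevity label in the design

# Least squares with pivoting. Returns the target coefficient (column
# `target` of X) and its SE, plus pieces for the Heckman covariance.
ols_fit <- function(X, y, target = BETA1_COL, keep_inv = FALSE) {
  fit <- .lm.fit(X, y)
  r <- fit$rank
  n <- length(y)
  pivot_used <- fit$pivot[seq_len(r)]
  # un-pivot coefficients; aliased columns become NA
  coef <- rep(NA_real_, ncol(X))
  coef[pivot_used] <- fit$coefficients[seq_len(r)]
  s2 <- if (n > r) sum(fit$residuals^2) / (n - r) else 0
  pos <- match(target, pivot_used)
  if (is.na(pos))
    return(list(beta = NA_real_, se = NA_real_, coef = coef))
  R <- fit$qr[seq_len(r), seq_len(r), drop = FALSE]
  R[lower.tri(R)] <- 0
  XtXinv <- chol2inv(R)
  out <- list(beta = coef[target], se = sqrt(s2 * XtXinv[pos, pos]),
              s2 = s2, coef = coef, residuals = fit$residuals,
              rank = r, pivot_used = pivot_used)
  if (keep_inv) {
    m <- matrix(NA_real_, ncol(X), ncol(X))
    m[pivot_used, pivot_used] <- XtXinv
    out$XtXinv_full <- m
  }
  out
}

# numeric row: beta1, se, n_obs, lambda_coef, converged
pf_row <- function(beta1, se, n_obs, lam = NA_real_, conv = TRUE)
  c(beta1, se, n_obs, lam, as.numeric(conv))

fit_one_peptide <- function(y, imp, alive, X, min_obs = 20) {
  obs <- !is.na(y)
  no <- sum(obs)
  if (no < min_obs)
    stopf("peptide has %d observed values (< %d)", no, min_obs)
  if (length(unique(alive[obs])) < 2)
    stopf("peptide observed in a single longevity group")
  Xo <- X[obs, , drop = FALSE]
  io <- imp[obs]
  if (any(io) && !all(io)) Xo <- cbind(Xo, imputed = io)
  yv <- y[obs]
  if (var(yv) == 0) return(pf_row(0, 0, no, conv = FALSE))
  f <- ols_fit(Xo, yv)
  if (is.na(f$beta) || !is.finite(f$se))
    return(pf_row(0, 0, no, conv = FALSE))
  pf_row(f$beta, f$se, no)
}

# Probit regression by compiled Fisher scoring, with glm.fit as a
# safety net; returns NULL on failure.
probit_fit <- function(Z, s) {
  f <- tryCatch(probit_irls_cpp(Z, s), error = function(e)
    list(converged = FALSE))
  if (!isTRUE(f$converged)) {
    g <- tryCatch(
      suppressWarnings(glm.fit(Z, s,
                               family = binomial(link = "probit"))),
      error = function(e) NULL)
    if (is.null(g) || !g$converged || g$rank < ncol(Z)) return(NULL)
    XtWX <- crossprod(Z * sqrt(g$weights))
    Vg <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(Vg)) return(NULL)
    f <- list(gamma = g$coefficients, Vg = Vg,
              eta = drop(Z %*% g$coefficients))
  }
  j <- ncol(Z)  # exclusion variable is the last column
  excl_z <- f$gamma[j] / sqrt(f$Vg[j, j])
  list(gamma = f$gamma, Vg = f$Vg, eta = as.numeric(f$eta),
       excl_z = excl_z)
}

heckman_one_peptide <- function(y, imp, alive, X, exclusion,
                                min_obs = 20, min_excl_z = 2,
                                excl_resid = NULL, min_bias = 0.005) {
  obs <- !is.na(y)
  base <- fit_one_peptide(y, imp, alive, X, min_obs)
  if (mean(obs) >= 0.99 || base[5] == 0) return(base)
  Z <- cbind(X, excl = exclusion)
  pr <- probit_fit(Z, as.numeric(obs))
  if (is.null(pr)) {
    base[5] <- 0
    return(base)
  }
  # Instrument-relevance guard: the correction is identified off the
  # exclusion variable; with an irrelevant instrument the inverse Mills
  # ratio is collinear with the covariates and the corrected estimator
  # is pure noise. Fall back to the uncorrected fit in that case.
  if (!is.finite(pr$excl_z) || abs(pr$excl_z) < min_excl_z) return(base)
  eta_o <- pr$eta[obs]
  lam <- dnorm(eta_o) / pnorm(eta_o)
  Xo <- X[obs, , drop = FALSE]
  io <- imp[obs]
  if (any(io) && !all(io)) Xo <- cbind(Xo, imputed = io)
  # Control function: selection acts on the abundance itself, so the
  # outcome error has a protein-level component predicted by the
  # exclusion variable. Conditioning on it (residualized against the
  # covariates, so the longevity estimand is untouched) plus the
  # inverse Mills ratio gives the correctly specified observed-data
  # regression.
  if (is.null(excl_resid)) excl_resid <- .lm.fit(X, exclusion)$residuals
  Xa <- cbind(Xo, block_ctrl = excl_resid[obs], imr = lam)
  imr_col <- ncol(Xa)
  f <- tryCatch(ols_fit(Xa, y[obs], keep_inv = TRUE),
                error = function(e) NULL)
  if (is.null(f) || is.na(f$beta) ||
      is.na(f$coef[imr_col])) {
    base[5] <- 0
    return(base)
  }
  blam <- f$coef[imr_col]
  no <- sum(obs)
  delta <- lam * (lam + eta_o)
  sigma2 <- (sum(f$residuals^2) + blam^2 * sum(delta)) / no
  rho2 <- if (sigma2 > 0) min(1, blam^2 / sigma2) else 0
  used <- f$pivot_used
  Xu <- Xa[, used, drop = FALSE]
  XtXinv <- f$XtXinv_full[used, used, drop = FALSE]
  A <- crossprod(Xu, Xu * (1 - rho2 * delta))
  XdZ <- crossprod(Xu * delta, Z[obs, , drop = FALSE])
  Q <- rho2 * XdZ %*% pr$Vg %*% t(XdZ)
  V <- sigma2 * XtXinv %*% (A + Q) %*% XtXinv
  # Pretest on the implied selection bias: omitting the correction term
  # biases beta1 by about blam times the group difference in the
  # inverse Mills ratio. When that quantity is immaterial relative to
  # the effects of interest, the corrected estimator only adds variance
  # and the uncorrected fit is reported instead.
  ao <- alive[obs]
  bias_est <- blam * (mean(lam[ao == 1]) - mean(lam[ao == 0]))
  if (!is.finite(bias_est) || abs(bias_est) < min_bias) return(base)
  pos <- match(BETA1_COL, used)
  se <- sqrt(max(0, V[pos, pos]))
  pf_row(f$beta, se, no, lam = blam)
}

# Exclusion variable for the selection probit: per participant, the
# mean of peptide-centered observed abundances over the protein's OTHER
# peptides (0, the center, when none are observed). Returned as a
# participants x peptides matrix.
block_mean_exclusion <- function(peptides, participants) {
  ab <- peptides$abundance[participants$id, , drop = FALSE]
  ctr <- sweep(ab, 2, colMeans(ab, na.rm = TRUE), "-")
  obs <- !is.na(ctr)
  ctr[!obs] <- 0
  out <- matrix(0, nrow(ab), ncol(ab), dimnames = dimnames(ab))
  for (ix in split(seq_len(ncol(ab)),
                   factor(peptides$map$protein_id,
                          levels = unique(peptides$map$protein_id)))) {
    tot <- rowSums(ctr[, ix, drop = FALSE])
    cnt <- rowSums(obs[, ix, drop = FALSE])
    num <- tot - ctr[, ix, drop = FALSE]       # leave-one-out sums
    den <- cnt - obs[, ix, drop = FALSE]
    out[, ix] <- (num / pmax(den, 1L)) * (den > 0)
  }
  out
}

as_effect_df <- function(rows, peptide_ids, protein_ids) {
  m <- do.call(rbind, rows)
  data.frame(peptide_id = peptide_ids, protein_id = protein_ids,
             beta1 = m[, 1], se = m[, 2], n_obs = as.integer(m[, 3]),
             heckman_lambda_coef = m[, 4], converged = m[, 5] == 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the longevity association model for one peptide
#'
#' Ordinary least squares of the peptide's observed log10 abundances on
#' the longevity label, age, birth-cohort cumulative hazard, site
#' indicators and the imputed-measurement indicator. The log10 effect
#' of the longevity label (`beta1`) and its standard error are
#' returned; the antilog of `beta1` is the fold difference between
#' long-lived and shorter-lived participants.
#'
#' @param peptides A `serolong_peptides` object.
#' @param participants The participant table (see [simulate_cohort()]).
#' @param peptide_id Column name of the peptide to fit.
#' @param min_obs Minimum observed values required (default 20).
#' @return A one-row `data.frame` (peptide_id, protein_id, beta1, se,
#'   n_obs, heckman_lambda_coef, converged).
#' @export
fit_peptide_model <- function(peptides, participants, peptide_id,
                              min_obs = 20) {
  X <- outcome_design(participants)
  row <- fit_one_peptide(peptides$abundance[participants$id, peptide_id],
                         peptides$imputed[participants$id, peptide_id],
                         participants$alive90th, X, min_obs)
  as_effect_df(list(row), peptide_id,
               peptides$map$protein_id[
                 match(peptide_id, peptides$map$peptide_id)])
}

#' Heckman-corrected longevity association for one peptide
#'
#' Two-step selection correction for abundance-dependent missingness:
#' step 1 fits a probit of the observation indicator on the outcome
#' covariates plus an exclusion variable (by default the participant's
#' mean centered abundance over the other peptides of the same protein,
#' which predicts detection but is excluded from the single peptide's
#' outcome equation); step 2 refits the outcome model augmented with
#' the inverse Mills ratio and with the covariate-residualized
#' exclusion variable as a control for the protein-level error
#' component (since selection acts on the abundance itself), with
#' standard errors corrected for the estimated first step. Peptides at
#' least 99% observed are returned uncorrected; probit failure falls
#' back to the uncorrected fit with `converged = FALSE`.
#'
#' @inheritParams fit_peptide_model
#' @param exclusion Optional numeric vector (length = participants)
#'   used as the selection-equation instrument; defaults to the
#'   protein-block mean described above.
#' @param min_excl_z Minimum absolute probit z-statistic of the
#'   exclusion variable for the correction to engage; below it the
#'   instrument is too weak to identify the correction (the inverse
#'   Mills ratio becomes collinear with the covariates) and the
#'   uncorrected fit is returned.
#' @param min_bias Pretest threshold on the implied selection bias
#'   (log10 units): the correction engages only when the estimated
#'   inverse-Mills coefficient times the group difference in the
#'   inverse Mills ratio exceeds this. Below it, selection bias is
#'   immaterial next to the effect sizes of interest and the corrected
#'   estimator would only add variance, so the uncorrected fit is
#'   returned.
#' @return A one-row `data.frame` as in [fit_peptide_model()], with
#'   `heckman_lambda_coef` holding the inverse-Mills-ratio coefficient.
#' @export
heckman_correct <- function(peptides, participants, peptide_id,
                            exclusion = NULL, min_obs = 20,
                            min_excl_z = 2, min_bias = 0.005) {
  X <- outcome_design(participants)
  if (is.null(exclusion)) {
    excl <- block_mean_exclusion(peptides, participants)
    exclusion <- excl[, peptide_id]
  }
  row <- heckman_one_peptide(
    peptides$abundance[participants$id, peptide_id],
    peptides$imputed[participants$id, peptide_id],
    participants$alive90th, X, exclusion, min_obs, min_excl_z,
    min_bias = min_bias)
  as_effect_df(list(row), peptide_id,
               peptides$map$protein_id[
                 match(peptide_id, peptides$map$peptide_id)])
}

#' Fit longevity associations for all peptides
#'
#' Runs the per-peptide model (with the Heckman correction for
#' incompletely observed peptides when `heckman = TRUE`) over every
#' peptide with at least `min_obs` observed values in both longevity
#' groups. Peptides failing the preconditions are returned with
#' `converged = FALSE`.
#'
#' @inheritParams fit_peptide_model
#' @param heckman Apply the selection correction to incompletely
#'   observed peptides?
#' @param min_excl_z See [heckman_correct()].
#' @return A `data.frame` of peptide effects, one row per peptide.
#' @export
fit_all_peptides <- function(peptides, participants, heckman = TRUE,
                             min_obs = 20, min_excl_z = 2,
                             min_bias = 0.005) {
  X <- outcome_design(participants)
  ab <- peptides$abundance[participants$id, , drop = FALSE]
  impm <- peptides$imputed[participants$id, , drop = FALSE]
  alive <- participants$alive90th
  ids <- peptides$map$peptide_id
  excl <- if (heckman && anyNA(ab))
    block_mean_exclusion(peptides, participants) else NULL
  excl_resid <- if (!is.null(excl)) qr.resid(qr(X), excl) else NULL
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    y <- ab[, k]
    rows[[k]] <- tryCatch({
      if (!is.null(excl) && anyNA(y))
        heckman_one_peptide(y, impm[, k], alive, X, excl[, k], min_obs,
                            min_excl_z, excl_resid[, k], min_bias)
      else fit_one_peptide(y, impm[, k], alive, X, min_obs)
    }, error = function(e)
      pf_row(NA_real_, NA_real_, sum(!is.na(y)), conv = FALSE))
  }
  as_effect_df(rows, ids, peptides$map$protein_id)
}
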