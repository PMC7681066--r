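# Protein-mortality associations: spline-adjusted proportional hazards.

# Natural cubic spline basis in age with 3 knots (10th/50th/90th
# percentiles; outer knots act as boundary knots).
age_spline <- function(age, knots = NULL) {
  if (is.null(knots)) knots <- quantile(age, c(0.1, 0.5, 0.9))
  splines::ns(age, knots = knots[2], Boundary.knots = knots[c(1, 3)])
}

#' Age-adjusted mortality hazard ratio of a protein
#'
#' Cox proportional-hazards fit of time to death on the standardized
#' protein abundance, adjusted for baseline age through a restricted
#' cubic spline (3 knots). Returns the hazard ratio per 1 SD of
#' abundance.
#'
#' @param abundance Numeric protein abundance per participant.
#' @param participants Participant table with `followup_years`, `died`,
#'   `age`.
#' @param min_deaths Minimum observed deaths (default 20).
#' @return A `data.frame`: `hr_per_sd`, `ci_lo`, `ci_hi`, `p_value`,
#'   `n`, `n_deaths`.
#' @export
protein_mortality_hr <- function(abundance, participants,
                                 min_deaths = 20) {
  if (sum(participants$died) < min_deaths)
    stopf("only %d deaths observed (< %d)", sum(participants$died),
          min_deaths)
  if (sd(abundance) == 0) stopf("protein abundance has zero variance")
  z <- as.numeric(scale(abundance))
  B <- age_spline(participants$age)
  fit <- survival::coxph(
    survival::Surv(participants$followup_years, participants$died) ~
      z + B)
  if (any(!is.finite(coef(fit))))
    stopf("proportional-hazards fit did not converge: coef=%s",
          paste(signif(coef(fit), 3), collapse = ","))
  b <- coef(fit)[["z"]]
  se <- sqrt(vcov(fit)["z", "z"])
  data.frame(hr_per_sd = exp(b), ci_lo = exp(b - 1.96 * se),
             ci_hi = exp(b + 1.96 * se),
             p_value = 2 * pnorm(-abs(b / se)),
             n = nrow(participants), n_deaths = sum(participants$died))
}

#' Tertile hazard-ratio curves across baseline age
#'
#' Splits the protein into tertiles, interacts the tertile indicators
#' with a natural spline in baseline age inside a Cox model, and
#' evaluates the hazard ratio of the top and bottom tertiles versus the
#' middle tertile on an age grid, with delta-method 95% bands. Grid
#' ages with an empty tertile stratum nearby are reported missing.
#'
#' @inheritParams protein_mortality_hr
#' @param age_grid Ages at which to evaluate the curves (default: a
#'   grid over the observed range).
#' @param stratum_window Half-width (years) within which each tertile
#'   must have at least one participant for a grid point to be kept.
#' @return A `data.frame` with columns `age`, `hr_high`, `hi_lo`,
#'   `hi_hi`, `hr_low`, `lo_lo`, `lo_hi`.
#' @export
tertile_hr_by_age <- function(abundance, participants, age_grid = NULL,
                              stratum_window = 1.5) {
  qs <- quantile(abundance, c(0, 1/3, 2/3, 1))
  if (anyDuplicated(qs)) stopf("tertile cutpoints are not unique")
  tert <- cut(abundance, qs, include.lowest = TRUE,
              labels = c("low", "mid", "high"))
  tert <- stats::relevel(tert, ref = "mid")
  age <- participants$age
  if (is.null(age_grid))
    age_grid <- seq(quantile(age, 0.02), quantile(age, 0.98),
                    length.out = 25)
  kn <- quantile(age, c(0.1, 0.5, 0.9))
  df <- data.frame(time = participants$followup_years,
                   event = participants$died, tert = tert, age = age)
  fit <- survival::coxph(
    survival::Surv(time, event) ~ tert * splines::ns(
      age, knots = kn[2], Boundary.knots = kn[c(1, 3)]), data = df)
  beta <- coef(fit); V <- vcov(fit)
  tt <- stats::delete.response(stats::terms(fit))
  row_for <- function(level, a) {
    nd <- data.frame(tert = factor(level, levels = levels(tert)),
                     age = a)
    mf <- stats::model.frame(tt, nd, xlev = fit$xlevels)
    stats::model.matrix(tt, mf)[, -1, drop = FALSE]
  }
  est <- function(level, a) {
    d <- row_for(level, a) - row_for("mid", a)
    lp <- drop(d %*% beta)
    se <- sqrt(drop(d %*% V %*% t(d)))
    c(exp(lp), exp(lp - 1.96 * se), exp(lp + 1.96 * se))
  }
  out <- t(vapply(age_grid, function(a) {
    ok <- vapply(levels(tert), function(l)
      any(tert == l & abs(age - a) <= stratum_window), logical(1))
    if (!all(ok)) return(rep(NA_real_, 6))
    c(est("high", a), est("low", a))
  }, numeric(6)))
  data.frame(age = age_grid, hr_high = out[, 1], hi_lo = out[, 2],
             hi_hi = out[, 3], hr_low = out[, 4], lo_lo = out[, 5],
             lo_hi = out[, 6])
}
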