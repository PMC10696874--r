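## mediation: two-step mediation MR.  The indirect effect is the product of
## the exposure->mediator and mediator->outcome MR estimates (product
## method); its SE is first-order delta (Sobel-type) with zero covariance
## between the two independently fitted steps.

#' Indirect effect by the product method with a delta-method SE
#'
#' `indirect = beta_EM * beta_MO`;
#' `se = sqrt(beta_EM^2 * se_MO^2 + beta_MO^2 * se_EM^2)` (first-order delta,
#' zero covariance across the two independent MR fits); the 95% CI is
#' `indirect +/- 1.959964 * se`.
#'
#' @param beta_EM,se_EM Exposure-on-mediator estimate and SE.
#' @param beta_MO,se_MO Mediator-on-outcome estimate and SE.
#' @return List with `indirect`, `se`, `ci_low`, `ci_high`, `pval`
#'   (two-sided normal).
#' @examples
#' indirect_effect(0.5, 0.1, 0.2, 0.05)
#' @export
indirect_effect <- function(beta_EM, se_EM, beta_MO, se_MO) {
  if (!is_number(se_EM) || se_EM <= 0 || !is_number(se_MO) || se_MO <= 0)
    stop_protmr("standard errors must be positive")
  ind <- beta_EM * beta_MO
  se <- sqrt(beta_EM^2 * se_MO^2 + beta_MO^2 * se_EM^2)
  list(indirect = ind, se = se,
       ci_low = ind - Z95 * se, ci_high = ind + Z95 * se,
       pval = if (se > 0) 2 * stats::pnorm(-abs(ind / se)) else NA_real_)
}

#' Proportion of the total effect that is mediated
#'
#' @param indirect Indirect effect (product of the two step estimates).
#' @param beta_EO Total exposure-on-outcome effect from the primary MR.
#' @param floor Minimum `|beta_EO|` below which the proportion is flagged not
#'   estimable rather than divided (default 1e-6).
#' @return List with `proportion` (signed fraction; `NA` when not
#'   estimable), `percent`, and `estimable`.  Proportions outside \[0, 1\]
#'   are reported as computed, never truncated.
#' @export
proportion_mediated <- function(indirect, beta_EO, floor = 1e-6) {
  if (!is_number(indirect) || !is_number(beta_EO))
    stop_protmr("indirect and beta_EO must be finite")
  if (abs(beta_EO) < floor)
    return(list(proportion = NA_real_, percent = NA_real_, estimable = FALSE))
  p <- indirect / beta_EO
  list(proportion = p, percent = 100 * p, estimable = TRUE)
}

#' Two-step mediation Mendelian randomization
#'
#' Step 1 estimates the exposure-on-mediator effect using the exposure's
#' instruments; step 2 estimates the mediator-on-outcome effect using the
#' mediator's own instruments (univariable, no adjustment for the exposure);
#' the total effect is the standard univariable exposure-on-outcome MR.  The
#' indirect effect is then `beta_EM * beta_MO` with a delta-method SE, and
#' the proportion mediated is `indirect / beta_EO`.
#'
#' Instruments shared between the exposure and the mediator break the
#' exclusion restriction of step 2 (their outcome effect travels through the
#' exposure's direct path, so their Wald ratio estimates
#' `theta_EO / theta_EM`, not the mediator effect); by default, SNPs that are
#' genome-wide significant for the exposure are therefore excluded from the
#' mediator's instrument set before step 2.
#'
#' @param exposure,mediator,outcome Canonical summary-statistics tables.
#' @param ld An [ld_matrix()] covering the instrument SNPs, or `NULL`.
#' @param config An [instrument_config()].
#' @param proportion_floor Passed to [proportion_mediated()].
#' @param exclude_exposure_instruments Drop exposure-significant SNPs from
#'   the step-2 instrument set (default `TRUE`).
#' @return Object of class `mr_mediation`: the three step fits
#'   (`fit_EM`, `fit_MO`, `fit_EO`, each an `mr_estimate`), the six
#'   betas/SEs, `indirect`, `indirect_se`, `indirect_ci_low`,
#'   `indirect_ci_high`, `proportion`, `percent`, `estimable`.
#' @export
mr_mediate <- function(exposure, mediator, outcome, ld = NULL,
                       config = instrument_config(), proportion_floor = 1e-6,
                       exclude_exposure_instruments = TRUE) {
  step_fit <- function(from, to, label) {
    h <- prepare_instruments(from, to, ld, config)
    if (is.null(h) || nrow(retained(h)) == 0L)
      stop_protmr("mediation step '", label, "' has zero usable instruments")
    mr_ivw(h)
  }
  mediator_step2 <- mediator
  if (exclude_exposure_instruments) {
    expo_sig <- select_significant(exposure, config)$SNP
    mediator_step2 <- mediator[!mediator$SNP %in% expo_sig, , drop = FALSE]
  }
  fit_EM <- step_fit(exposure, mediator, "exposure->mediator")
  fit_MO <- step_fit(mediator_step2, outcome, "mediator->outcome")
  fit_EO <- step_fit(exposure, outcome, "exposure->outcome (total)")
  ind <- indirect_effect(fit_EM$beta, fit_EM$se, fit_MO$beta, fit_MO$se)
  prop <- proportion_mediated(ind$indirect, fit_EO$beta, proportion_floor)
  structure(list(fit_EM = fit_EM, fit_MO = fit_MO, fit_EO = fit_EO,
                 beta_EM = fit_EM$beta, se_EM = fit_EM$se,
                 beta_MO = fit_MO$beta, se_MO = fit_MO$se,
                 beta_EO = fit_EO$beta, se_EO = fit_EO$se,
                 indirect = ind$indirect, indirect_se = ind$se,
                 indirect_ci_low = ind$ci_low, indirect_ci_high = ind$ci_high,
                 indirect_pval = ind$pval,
                 proportion = prop$proportion, percent = prop$percent,
                 estimable = prop$estimable), class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, digits = 4, ...) {
  cat("Two-step mediation MR\n")
  cat("  beta_EM = ", signif(x$beta_EM, digits), " (SE ", signif(x$se_EM, digits),
      ");  beta_MO = ", signif(x$beta_MO, digits), " (SE ", signif(x$se_MO, digits),
      ");  beta_EO = ", signif(x$beta_EO, digits), " (SE ", signif(x$se_EO, digits),
      ")\n", sep = "")
  cat("  indirect = ", signif(x$indirect, digits), " (SE ",
      signif(x$indirect_se, digits), "), 95% CI [",
      signif(x$indirect_ci_low, digits), ", ",
      signif(x$indirect_ci_high, digits), "]\n", sep = "")
  if (x$estimable)
    cat("  proportion mediated = ", signif(x$proportion, digits), " (",
        signif(x$percent, digits), "%)\n", sep = "")
  else
    cat("  proportion mediated: not estimable (|beta_EO| below floor)\n")
  invisible(x)
}

#' @export
as.data.frame.mr_mediation <- function(x, ...) {
  data.frame(beta_EM = x$beta_EM, se_EM = x$se_EM,
             beta_MO = x$beta_MO, se_MO = x$se_MO,
             beta_EO = x$beta_EO, se_EO = x$se_EO,
             indirect = x$indirect, indirect_se = x$indirect_se,
             indirect_ci_low = x$indirect_ci_low,
             indirect_ci_high = x$indirect_ci_high,
             proportion = x$proportion, percent = x$percent,
             estimable = x$estimable, stringsAsFactors = FALSE)
}
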