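## mr_estimators: Wald ratios, IVW, MR-Egger, Cochran's Q, leave-one-out.
##
## IVW is weighted regression of the outcome betas on the exposure betas
## through the origin with weights 1/se_outcome^2; algebraically identical to
## the inverse-variance-weighted mean of per-SNP Wald ratios with first-order
## SEs.  The default standard error uses multiplicative random effects with
## the residual scale floored at 1, so it is never narrower than the
## fixed-effect SE.

#' Per-SNP Wald ratio
#'
#' The causal estimate contributed by one instrument: outcome effect divided
#' by exposure effect.  The default standard error is first-order
#' (`se_outcome / |beta_exposure|`); instruments passing genome-wide
#' significance make the exposure-noise contribution second-order.  The
#' second-order delta form, which adds the exposure-noise term, is available
#' via `second_order = TRUE` (requires `se_exposure`).
#'
#' @param beta_exposure,beta_outcome Effect estimates on a shared effect
#'   allele.
#' @param se_outcome Outcome standard error.
#' @param se_exposure Exposure standard error (only used when
#'   `second_order = TRUE`).
#' @param second_order Use the second-order delta-method SE.
#' @return List with `ratio` and `se`.
#' @examples
#' wald_ratio(0.2, 0.05, 0.01)   # ratio 0.25, se 0.05
#' @export
wald_ratio <- function(beta_exposure, beta_outcome, se_outcome,
                       se_exposure = NULL, second_order = FALSE) {
  if (any(beta_exposure == 0))
    stop_protmr("zero exposure beta: Wald ratio undefined ",
                "(such rows should not survive the significance filter)")
  ratio <- beta_outcome / beta_exposure
  se <- se_outcome / abs(beta_exposure)
  if (second_order) {
    if (is.null(se_exposure))
      stop_protmr("second-order Wald SE requires se_exposure")
    se <- sqrt(se_outcome^2 / beta_exposure^2 +
                 beta_outcome^2 * se_exposure^2 / beta_exposure^4)
  }
  list(ratio = ratio, se = se)
}

new_mr_estimate <- function(method, n_snp, beta, se, pval = NULL,
                            q_stat = NA_real_, q_df = NA_integer_,
                            egger = NULL, data = NULL, se_type = "random") {
  # floor at the smallest positive double: extreme z underflows to 0, which
  # would violate the (0,1] domain of downstream multiplicity adjustment
  pval <- pval %||% max(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
  structure(list(
    method = method, n_snp = as.integer(n_snp),
    beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    pval = pval,
    q_stat = q_stat, q_df = q_df,
    q_pval = if (!is.na(q_stat) && !is.na(q_df) && q_df > 0)
      stats::pchisq(q_stat, q_df, lower.tail = FALSE) else NA_real_,
    egger_intercept = egger$intercept %||% NA_real_,
    egger_intercept_se = egger$se %||% NA_real_,
    egger_intercept_pval = egger$pval %||% NA_real_,
    se_type = se_type, data = data), class = "mr_estimate")
}

harmonized_columns <- function(set) {
  if (inherits(set, "harmonized_set")) set <- retained(set)
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing <- setdiff(need, names(set))
  if (length(missing))
    stop_protmr("harmonized set missing column(s): ",
                paste(missing, collapse = ", "))
  set
}

#' Fit a two-sample Mendelian randomization model
#'
#' The central fitting function.  `method = "ivw"` (the default, and the
#' primary analysis) combines per-SNP Wald estimates by inverse-variance
#' weighting, reporting Cochran's Q for heterogeneity; with a single SNP it
#' reduces to the Wald ratio.  `method = "egger"` fits the weighted
#' regression with intercept (MR-Egger); a non-zero intercept indicates
#' directional horizontal pleiotropy, and the slope is the pleiotropy-robust
#' effect.
#'
#' @param set A `harmonized_set` from [harmonize()] (dropped rows are
#'   ignored), or any data frame with columns `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome` (and ideally `SNP`).
#' @param method `"ivw"` or `"egger"`.
#' @param se_type `"random"` (default): multiplicative random-effects SE,
#'   residual scale floored at 1 so the interval is never narrower than the
#'   fixed-effect one; `"fixed"`: fixed-effect SE.
#' @return An object of class `mr_estimate` with components `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval` (two-sided normal; the Egger intercept test
#'   uses t with n-2 df), `q_stat`, `q_df`, `q_pval`, and for Egger the
#'   intercept triple.  `coef()`, `confint()`, `print()`, `summary()` and
#'   `plot()` methods are provided; see also [odds_ratio()].
#' @examples
#' sim <- simulate_two_sample(truth_config(n_snps = 30, theta = 0.1, seed = 3))
#' h <- harmonize(select_significant(sim$exposure), sim$outcome)
#' mr(h)
#' @export
mr <- function(set, method = c("ivw", "egger"), se_type = c("random", "fixed")) {
  method <- match.arg(method)
  se_type <- match.arg(se_type)
  set <- harmonized_columns(set)
  if (nrow(set) == 0L) stop_protmr("no usable SNPs in harmonized set")
  switch(method,
         ivw = mr_ivw_fit(set, se_type),
         egger = mr_egger_fit(set, se_type))
}

mr_ivw_fit <- function(set, se_type = "random") {
  n <- nrow(set)
  bx <- set$beta_exposure; by <- set$beta_outcome; sy <- set$se_outcome
  if (n == 1L) {
    wr <- wald_ratio(bx, by, sy)
    return(new_mr_estimate("Wald ratio", 1L, wr$ratio, wr$se,
                           q_stat = 0, q_df = 0L, data = set,
                           se_type = se_type))
  }
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  se_fixed <- sqrt(1 / sxx)
  q <- sum(w * (by - beta * bx)^2)
  sigma <- sqrt(q / (n - 1))
  se <- if (se_type == "random") se_fixed * max(1, sigma) else se_fixed
  new_mr_estimate("IVW", n, beta, se, q_stat = q, q_df = n - 1L,
                  data = set, se_type = se_type)
}

mr_egger_fit <- function(set, se_type = "random") {
  n <- nrow(set)
  if (n < 3L) stop_protmr("MR-Egger requires at least 3 SNPs (got ", n, ")")
  bx <- set$beta_exposure; by <- set$beta_outcome; sy <- set$se_outcome
  w <- 1 / sy^2
  # closed-form weighted least squares with intercept
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  denom <- sw * sxx - swx^2
  slope <- (sw * sxy - swx * swy) / denom
  intercept <- (swy - slope * swx) / sw
  rss <- sum(w * (by - intercept - slope * bx)^2)
  sigma <- sqrt(rss / (n - 2))
  scale <- if (se_type == "random") max(1, sigma) else 1
  se_slope <- sqrt(sw / denom) * scale
  se_int <- sqrt(sxx / denom) * scale
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = n - 2)
  new_mr_estimate("MR-Egger", n, slope, se_slope,
                  q_stat = rss, q_df = n - 2L,
                  egger = list(intercept = intercept, se = se_int, pval = p_int),
                  data = set, se_type = se_type)
}

#' Inverse-variance-weighted MR (primary analysis)
#'
#' Shorthand for `mr(set, method = "ivw")`.
#' @inheritParams mr
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(set, se_type = c("random", "fixed"))
  mr(set, "ivw", match.arg(se_type))

#' MR-Egger regression
#'
#' Shorthand for `mr(set, method = "egger")`.
#' @inheritParams mr
#' @return An `mr_estimate` with the intercept triple filled in.
#' @export
mr_egger <- function(set, se_type = c("random", "fixed"))
  mr(set, "egger", match.arg(se_type))

#' Leave-one-out sensitivity analysis
#'
#' Refits the IVW model excluding each SNP in turn, in the same estimator
#' dialect as [mr_ivw()].
#'
#' @inheritParams mr
#' @return Data frame of class `mr_loo` with one row per excluded SNP:
#'   `excluded_snp`, `beta`, `se`, `pval`.
#' @export
leave_one_out <- function(set, se_type = c("random", "fixed")) {
  se_type <- match.arg(se_type)
  set <- harmonized_columns(set)
  n <- nrow(set)
  if (n < 2L) stop_protmr("leave-one-out requires at least 2 SNPs")
  snp <- if ("SNP" %in% names(set)) set$SNP else sprintf("snp_%d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    fit <- mr_ivw_fit(set[-i, , drop = FALSE], se_type)
    data.frame(excluded_snp = snp[i], beta = fit$beta, se = fit$se,
               pval = fit$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mr_loo", "data.frame")
  out
}

#' Odds-ratio view of an MR estimate
#'
#' @param x An `mr_estimate`.
#' @return Named numeric vector `c(or, ci_low, ci_high)` — the elementwise
#'   exponential of the estimate and its confidence limits.
#' @export
odds_ratio <- function(x) {
  stopifnot(inherits(x, "mr_estimate"))
  c(or = exp(x$beta), ci_low = exp(x$ci_low), ci_high = exp(x$ci_high))
}

#' @export
print.mr_estimate <- function(x, digits = 5, ...) {
  cat(x$method, " estimate (", x$n_snp, " SNP",
      if (x$n_snp != 1) "s", ", ", x$se_type, "-effect SE)\n", sep = "")
  cat("  beta = ", signif(x$beta, digits), " (SE ", signif(x$se, digits),
      "), 95% CI [", signif(x$ci_low, digits), ", ",
      signif(x$ci_high, digits), "], p = ", signif(x$pval, 3), "\n", sep = "")
  cat("  OR [95% CI] = ", format_or_ci(x$beta, x$ci_low, x$ci_high), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.mr_estimate <- function(object, ...) {
  print(object)
  if (!is.na(object$q_stat) && !is.na(object$q_df) && object$q_df > 0)
    cat("  Cochran's Q = ", signif(object$q_stat, 4), " on ", object$q_df,
        " df, p = ", signif(object$q_pval, 3),
        if (object$q_pval > 0.05) "  (no detectable heterogeneity)" else
          "  (heterogeneity present)", "\n", sep = "")
  if (!is.na(object$egger_intercept))
    cat("  Egger intercept = ", signif(object$egger_intercept, 4),
        " (SE ", signif(object$egger_intercept_se, 4), "), p = ",
        signif(object$egger_intercept_pval, 3), "\n", sep = "")
  invisible(object)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  if (is.na(object$egger_intercept)) c(beta = object$beta)
  else c(intercept = object$egger_intercept, beta = object$beta)
}

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  matrix(c(object$beta - z * object$se, object$beta + z * object$se),
         nrow = 1, dimnames = list("beta",
                                   paste0(100 * c((1 - level) / 2,
                                                  1 - (1 - level) / 2), " %")))
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             q_stat = x$q_stat, q_df = x$q_df, q_pval = x$q_pval,
             egger_intercept = x$egger_intercept,
             egger_intercept_se = x$egger_intercept_se,
             egger_intercept_pval = x$egger_intercept_pval,
             stringsAsFactors = FALSE)
}

#' Scatter plot of outcome vs exposure effects with the fitted MR line
#'
#' @param x An `mr_estimate` fitted from a harmonized set.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_estimate <- function(x, ...) {
  d <- x$data
  if (is.null(d)) stop_protmr("estimate carries no per-SNP data to plot")
  graphics::plot(d$beta_exposure, d$beta_outcome,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome",
                 main = paste0(x$method, ": beta = ", signif(x$beta, 4)), ...)
  graphics::arrows(d$beta_exposure, d$beta_outcome - Z95 * d$se_outcome,
                   d$beta_exposure, d$beta_outcome + Z95 * d$se_outcome,
                   angle = 90, code = 3, length = 0.02, col = "grey60")
  intercept <- if (is.na(x$egger_intercept)) 0 else x$egger_intercept
  graphics::abline(a = intercept, b = x$beta, col = "firebrick")
  invisible(x)
}
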