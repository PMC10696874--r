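# Independent reference implementations used as oracles.  These deliberately
# take different routes than the package code: lm() for the weighted
# regressions, p.adjust() for BH, and an explicit greedy recomputation over
# the r2 matrix for clumping.

oracle_ivw <- function(bx, by, sy) {
  fit <- stats::lm(by ~ 0 + bx, weights = 1 / sy^2)
  s <- summary(fit)
  beta <- unname(stats::coef(fit)[1])
  se_fixed <- unname(s$coefficients[1, 2]) / s$sigma
  list(beta = beta,
       se_random = se_fixed * max(1, s$sigma),
       se_fixed = se_fixed,
       q = sum((1 / sy^2) * stats::resid(fit)^2))
}

oracle_egger <- function(bx, by, sy) {
  fit <- stats::lm(by ~ bx, weights = 1 / sy^2)
  s <- summary(fit)
  se_f <- s$coefficients[, 2] / s$sigma
  scale <- max(1, s$sigma)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       se_intercept = unname(se_f[1]) * scale,
       se_slope = unname(se_f[2]) * scale)
}

oracle_bh <- function(p) stats::p.adjust(p, method = "BH")

# greedy clump recomputed independently over indices
oracle_clump <- function(snp, pval, r2, cutoff) {
  ord <- order(pval, snp)
  left <- ord
  kept <- integer(0)
  while (length(left)) {
    top <- left[1]
    kept <- c(kept, top)
    left <- left[-1]
    if (length(left))
      left <- left[r2[snp[top], snp[left]] <= cutoff]
  }
  sort(snp[kept])
}

# second-order delta SE for the Wald ratio
oracle_wald_se2 <- function(bx, by, sx, sy)
  sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)

# convenience: aligned harmonized set straight from a two-sample simulation
sim_harmonized <- function(sim, config = instrument_config()) {
  retained(harmonize(select_significant(sim$exposure, config), sim$outcome,
                     config))
}
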