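hset <- function(bx, by, sy, sx = 0.01, snp = NULL) {
  data.frame(SNP = snp %||% sprintf("rs%02d", seq_along(bx)),
             beta_exposure = bx, se_exposure = sx, beta_outcome = by,
             se_outcome = sy, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Wald ratio arithmetic and degenerate cases", {
  expect_equal(wald_ratio(0.2, 0.05, 0.01), list(ratio = 0.25, se = 0.05))
  expect_equal(wald_ratio(0.2, 0, 0.01)$ratio, 0)
  expect_equal(wald_ratio(-0.2, 0.05, 0.01)$se, 0.05)  # |beta_exposure|
  expect_error(wald_ratio(0, 0.05, 0.01), "zero exposure beta")
})

test_that("first-order Wald SE agrees with second-order for strong instruments", {
  # regime of a modest causal effect measured with strong instruments:
  # exposure z-score >= 10, outcome effect a tenth of the exposure effect,
  # comparable per-SNP precision in the two GWAS.  There the exposure-noise
  # term the first-order SE ignores is second-order small.
  set.seed(42)
  for (i in 1:20) {
    bx <- runif(1, 0.1, 0.5)
    sx <- abs(bx) / runif(1, 10, 50)
    by <- 0.1 * bx
    sy <- sx * runif(1, 0.8, 1.5)
    first <- wald_ratio(bx, by, sy)$se
    second <- oracle_wald_se2(bx, by, sx, sy)
    expect_lt(abs(first - second) / second, 0.02)
  }
  expect_equal(wald_ratio(0.2, 0.05, 0.01, 0.01, second_order = TRUE)$se,
               oracle_wald_se2(0.2, 0.05, 0.01, 0.01))
})

test_that("IVW matches an independent weighted-least-squares fit", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(3:100, 1)
    bx <- rnorm(n, 0.2, 0.1); bx[bx == 0] <- 0.1
    by <- 0.1 * bx + rnorm(n, 0, 0.01)
    sy <- runif(n, 0.005, 0.05)
    fit <- mr_ivw(hset(bx, by, sy))
    orc <- oracle_ivw(bx, by, sy)
    expect_equal(fit$beta, orc$beta, tolerance = 1e-10)
    expect_equal(fit$se, orc$se_random, tolerance = 1e-10)
    expect_equal(fit$q_stat, orc$q, tolerance = 1e-10)
    expect_equal(mr_ivw(hset(bx, by, sy), se_type = "fixed")$se,
                 orc$se_fixed, tolerance = 1e-10)
  }
})

test_that("IVW equals the inverse-variance-weighted mean of Wald ratios", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(2:50, 1)
    bx <- rnorm(n, 0.3, 0.1); bx[abs(bx) < 0.01] <- 0.05
    by <- rnorm(n, 0.05, 0.02); sy <- runif(n, 0.005, 0.05)
    wr <- wald_ratio(bx, by, sy)
    w <- 1 / wr$se^2
    expect_equal(mr_ivw(hset(bx, by, sy))$beta,
                 sum(w * wr$ratio) / sum(w), tolerance = 1e-10)
  }
})

test_that("single-SNP IVW reduces to the Wald ratio", {
  fit <- mr_ivw(hset(0.2, 0.05, 0.01))
  expect_equal(fit$method, "Wald ratio")
  expect_equal(fit$beta, 0.25)
  expect_equal(fit$se, 0.05)
  expect_equal(fit$ci_low, 0.25 - 1.959964 * 0.05, tolerance = 1e-10)
})

test_that("noiseless homogeneous ratios give Q = 0 and beta equal to the ratio", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  fit <- mr_ivw(hset(bx, 0.3 * bx, 0.01))
  expect_equal(fit$beta, 0.3, tolerance = 1e-12)
  expect_lt(fit$q_stat, 1e-10)
  expect_equal(fit$q_df, 3L)
  expect_equal(fit$se_type, "random")
  # underdispersion floor: SE never shrinks below the fixed-effect SE
  expect_equal(fit$se, mr_ivw(hset(bx, 0.3 * bx, 0.01), "fixed")$se)
})

test_that("MR-Egger recovers an exact affine relationship", {
  bx <- c(0.1, 0.2, 0.3)
  fit <- mr_egger(hset(bx, 0.02 + 0.3 * bx, 0.01))
  expect_equal(fit$egger_intercept, 0.02, tolerance = 1e-10)
  expect_equal(fit$beta, 0.3, tolerance = 1e-10)
  expect_error(mr_egger(hset(c(0.1, 0.2), c(0.01, 0.02), 0.01)),
               "at least 3")
})

test_that("MR-Egger matches an independent weighted regression with intercept", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(3:80, 1)
    bx <- rnorm(n, 0.25, 0.1)
    by <- 0.01 + 0.2 * bx + rnorm(n, 0, 0.01)
    sy <- runif(n, 0.005, 0.05)
    fit <- mr_egger(hset(bx, by, sy))
    orc <- oracle_egger(bx, by, sy)
    expect_equal(fit$beta, orc$slope, tolerance = 1e-10)
    expect_equal(fit$egger_intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(fit$se, orc$se_slope, tolerance = 1e-10)
    expect_equal(fit$egger_intercept_se, orc$se_intercept, tolerance = 1e-10)
    # intercept test uses t with n - 2 df
    expect_equal(fit$egger_intercept_pval,
                 2 * pt(-abs(orc$intercept / orc$se_intercept), n - 2),
                 tolerance = 1e-10)
  }
})

test_that("estimates are sign- and scale-equivariant in the exposure", {
  set.seed(5)
  bx <- rnorm(20, 0.3, 0.1); by <- 0.2 * bx + rnorm(20, 0, 0.01)
  sy <- runif(20, 0.005, 0.02)
  base <- mr_ivw(hset(bx, by, sy))
  neg <- mr_ivw(hset(-bx, by, sy))
  expect_equal(neg$beta, -base$beta, tolerance = 1e-12)
  expect_equal(neg$se, base$se, tolerance = 1e-12)
  scaled <- mr_ivw(hset(3 * bx, by, sy))
  expect_equal(scaled$beta, base$beta / 3, tolerance = 1e-12)
})

test_that("Q is invariant to SNP ordering", {
  set.seed(6)
  d <- hset(rnorm(30, 0.3, 0.1), rnorm(30, 0.05, 0.02), runif(30, 0.005, 0.05))
  perm <- d[sample(nrow(d)), ]
  expect_equal(mr_ivw(perm)$q_stat, mr_ivw(d)$q_stat, tolerance = 1e-10)
  expect_equal(mr_ivw(perm)$beta, mr_ivw(d)$beta, tolerance = 1e-12)
})

test_that("leave-one-out reduces correctly and isolates a planted outlier", {
  bx <- rep(0.2, 6)
  by <- 0.3 * bx
  by[4] <- 0.3 * bx[4] + 0.05  # planted outlier
  loo <- leave_one_out(hset(bx, by, 0.01))
  expect_equal(nrow(loo), 6L)
  full <- mr_ivw(hset(bx, by, 0.01))$beta
  deltas <- abs(loo$beta - full)
  expect_equal(which.max(deltas), 4L)
  # homogeneous noiseless set: every row equals the full-set beta
  loo0 <- leave_one_out(hset(bx, 0.3 * bx, 0.01))
  expect_true(all(abs(loo0$beta - 0.3) < 1e-12))
  # n = 2 reduces to two single-SNP Wald ratios
  loo2 <- leave_one_out(hset(c(0.2, 0.4), c(0.05, 0.08), 0.01))
  expect_equal(loo2$beta, c(0.08 / 0.4, 0.05 / 0.2))
  expect_error(leave_one_out(hset(0.2, 0.05, 0.01)), "at least 2")
})

test_that("mr_estimate invariants: CI construction and OR view", {
  fit <- mr_ivw(hset(c(0.2, 0.3, 0.25), c(0.02, 0.031, 0.024), 0.01))
  expect_equal(fit$ci_low, fit$beta - 1.959964 * fit$se, tolerance = 1e-10)
  expect_equal(fit$ci_high, fit$beta + 1.959964 * fit$se, tolerance = 1e-10)
  expect_equal(unname(odds_ratio(fit)),
               exp(c(fit$beta, fit$ci_low, fit$ci_high)))
  expect_gte(fit$q_stat, 0)
  expect_equal(fit$q_df, 2L)
  expect_equal(fit$q_pval, pchisq(fit$q_stat, 2, lower.tail = FALSE))
  df <- as.data.frame(fit)
  expect_equal(df$beta, fit$beta)
  expect_output(print(fit), "IVW estimate")
  expect_output(summary(mr_egger(hset(c(0.1, 0.2, 0.3, 0.4),
                                      c(0.03, 0.05, 0.08, 0.13), 0.01))),
                "Egger intercept")
})

test_that("egger recovers injected directional pleiotropy and null intercepts", {
  ests <- t(vapply(1:200, function(s) {
    sim <- simulate_two_sample(truth_config(n_snps = 30, theta = 0.1,
                                            pleiotropy_mean = 0.01,
                                            pleiotropy_sd = 0.002, seed = s))
    fit <- mr_egger(sim_harmonized(sim))
    c(fit$egger_intercept, fit$egger_intercept_se)
  }, numeric(2)))
  mc_se <- sd(ests[, 1]) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests[, 1]) - 0.01), 3 * mc_se)

  null_int <- vapply(1:100, function(s) {
    sim <- simulate_two_sample(truth_config(n_snps = 30, theta = 0.1, seed = 300 + s))
    mr_egger(sim_harmonized(sim))$egger_intercept
  }, numeric(1))
  expect_lt(abs(mean(null_int)), 3 * sd(null_int) / sqrt(100))
})
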