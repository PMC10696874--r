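test_that("identical seed and config reproduce byte-identical tables", {
  cfg <- truth_config(n_snps = 40, theta = 0.05, seed = 11,
                      ld_block_sizes = c(5, 5), ld_rho = 0.8)
  a <- simulate_two_sample(cfg)
  b <- simulate_two_sample(cfg)
  expect_identical(a$exposure, b$exposure)
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$ld$r2, b$ld$r2)
})

test_that("generator p-values follow the normal approximation exactly", {
  sim <- simulate_two_sample(truth_config(n_snps = 200, seed = 2))
  for (tab in list(sim$exposure, sim$outcome)) {
    expect_true(all(abs(tab$pval - 2 * (1 - pnorm(abs(tab$beta / tab$se)))) <= 1e-12))
    expect_true(all(tab$se > 0))
    expect_false(any(duplicated(tab$SNP)))
    expect_true(all(tab$effect_allele != tab$other_allele))
  }
})

test_that("SEs follow the 1/sqrt(2 n maf (1-maf)) scaling", {
  sim <- simulate_two_sample(truth_config(n_snps = 50, seed = 4))
  expect_equal(sim$exposure$se,
               1 / sqrt(2 * sim$exposure$n * sim$exposure$eaf *
                          (1 - sim$exposure$eaf)), tolerance = 1e-12)
})

test_that("null model: downstream IVW is consistent with theta = 0", {
  sim <- simulate_two_sample(truth_config(n_snps = 50, theta = 0, seed = 21))
  fit <- mr_ivw(sim_harmonized(sim))
  expect_lt(abs(fit$beta), 4 * fit$se)
})

test_that("noiseless limit: every Wald ratio and the IVW equal theta", {
  cfg <- truth_config(n_snps = 30, theta = 0.1, seed = 8,
                      n_exposure_cohort = 1e18, n_outcome_cohort = 1e18)
  sim <- simulate_two_sample(cfg)
  h <- sim_harmonized(sim)
  ratios <- h$beta_outcome / h$beta_exposure
  expect_true(all(abs(ratios - 0.1) <= 1e-6))
  expect_equal(mr_ivw(h)$beta, 0.1, tolerance = 1e-6)
})

test_that("LD blocks share the causal signal and the emitted matrix matches", {
  cfg <- truth_config(n_snps = 20, seed = 13, ld_block_sizes = c(4, 3),
                      ld_rho = 0.9)
  sim <- simulate_two_sample(cfg)
  expect_equal(length(unique(sim$truth$b[1:4])), 1L)
  expect_equal(length(unique(sim$truth$b[5:7])), 1L)
  expect_equal(unname(sim$ld$r2[1, 2]), 0.81)
  expect_equal(unname(sim$ld$r2[1, 5]), 0)
  expect_equal(unname(diag(sim$ld$r2)), rep(1, 20))
})

test_that("chain config derives the total effect and true proportion", {
  ch <- chain_config(0.5, 0.2, 0.2)
  expect_equal(ch$theta_EO, 0.3)
  expect_equal(ch$proportion_mediated, 1 / 3)
  expect_equal(chain_config(0.4, 0.5, 0)$proportion_mediated, 1)
  expect_true(is.na(chain_config(0.5, -0.2, 0.1)$proportion_mediated))
})

test_that("chain truth: mediator-specific instruments do not touch the exposure", {
  sim <- simulate_chain(truth_config(n_snps = 25, seed = 31),
                        chain_config(0.5, 0.2, 0.2))
  mi <- sim$truth$mediator_instruments
  expect_length(intersect(mi, sim$truth$exposure_instruments), 0)
  # exposure association of mediator instruments is pure noise
  rows <- sim$exposure[sim$exposure$SNP %in% mi, ]
  expect_true(all(rows$pval > 5e-8))
})

test_that("scramble with zero fractions is the identity", {
  sim <- simulate_two_sample(truth_config(n_snps = 30, seed = 5))
  out <- scramble_alleles(sim$outcome, 0, 0, 0, seed = 9)
  expect_equal(out, sim$outcome, ignore_attr = TRUE)
  expect_true(all(attr(out, "scramble_log")$action == "none"))
})

test_that("scramble fractions must be valid and sum to at most one", {
  sim <- simulate_two_sample(truth_config(n_snps = 10, seed = 5))
  expect_error(scramble_alleles(sim$outcome, 0.6, 0.6, 0, seed = 1),
               "sum to at most 1")
  expect_error(scramble_alleles(sim$outcome, -0.1, 0, 0, seed = 1), "\\[0, 1\\]")
})

test_that("swapped rows are an involution under harmonization", {
  sim <- simulate_two_sample(truth_config(n_snps = 40, theta = 0.1, seed = 6))
  scr <- scramble_alleles(sim$outcome, swap_fraction = 1, seed = 3)
  h <- harmonize(sim$exposure, scr)
  expect_true(all(h$action == "sign-flipped"))
  expect_equal(h$beta_outcome, sim$outcome$beta)
  expect_equal(h$eaf_outcome, sim$outcome$eaf)
})

test_that("panel truth labels exactly the requested causal exposures", {
  p <- simulate_panel(30, 7, effect = 0.2,
                      config = truth_config(n_snps = 10), seed = 17)
  expect_equal(sum(p$truth$causal), 7L)
  expect_equal(length(p$exposures), 30L)
  expect_equal(nrow(p$outcome), 300L)
  expect_false(any(duplicated(p$outcome$SNP)))
  expect_identical(names(p$exposures), p$truth$exposure_id)
})

test_that("config validation rejects out-of-range values", {
  expect_error(truth_config(instrument_effect_sd = 0), "instrument_effect_sd")
  expect_error(truth_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(truth_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(truth_config(ld_rho = 1), "ld_rho")
  expect_error(truth_config(n_snps = 10, ld_block_sizes = c(6, 6)),
               "ld_block_sizes")
  expect_error(chain_config(NA, 1, 0), "finite")
})
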