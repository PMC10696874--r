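make_stats <- function(snp, pval, beta = 0.1, se = 0.01, eaf = 0.3,
                       ea = "A", oa = "C") {
  n <- length(snp)
  data.frame(SNP = snp, effect_allele = rep_len(ea, n),
             other_allele = rep_len(oa, n), eaf = rep_len(eaf, n),
             beta = rep_len(beta, n), se = rep_len(se, n),
             pval = pval, n = 1e5, stringsAsFactors = FALSE)
}

test_that("significance filter applies a strict threshold, preserving order", {
  tab <- make_stats(c("a", "b", "c"), c(1e-9, 1e-7, 1e-8))
  kept <- select_significant(tab, instrument_config(p_threshold = 5e-8))
  expect_identical(kept$SNP, c("a", "c"))
  all_null <- make_stats(c("a", "b"), c(0.5, 0.5))
  expect_equal(nrow(select_significant(all_null)), 0L)
})

test_that("clumping with identity LD keeps everything; dominated SNPs drop", {
  tab <- make_stats(paste0("rs", 1:5), c(1e-10, 1e-9, 1e-12, 1e-8, 1e-11))
  id <- ld_matrix(diag(5), tab$SNP)
  expect_identical(clump(tab, id)$SNP, tab$SNP)

  two <- make_stats(c("rs1", "rs2"), c(1e-10, 1e-9))
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = NULL)
  expect_identical(clump(two, ld_matrix(r2, two$SNP))$SNP, "rs1")
})

test_that("clumping a block-structured matrix equals the brute-force oracle", {
  cfg <- truth_config(n_snps = 50, theta = 0.1, seed = 19,
                      ld_block_sizes = c(10, 8, 5), ld_rho = 0.9)
  sim <- simulate_two_sample(cfg)
  cfg_i <- instrument_config(clump_r2 = 0.5)
  kept <- clump(sim$exposure, sim$ld, cfg_i)$SNP
  expect_identical(sort(kept),
                   oracle_clump(sim$exposure$SNP, sim$exposure$pval,
                                sim$ld$r2, 0.5))
  # one representative per block at the default stringent cutoff
  kept2 <- clump(sim$exposure, sim$ld, instrument_config())$SNP
  expect_equal(length(kept2), 50 - 10 - 8 - 5 + 3)
})

test_that("clumped output is maximal: every discard conflicts with a keep", {
  for (seed in 1:5) {
    cfg <- truth_config(n_snps = 40, seed = seed,
                        ld_block_sizes = c(12, 10), ld_rho = 0.8)
    sim <- simulate_two_sample(cfg)
    cfg_i <- instrument_config(clump_r2 = 0.3)
    kept <- clump(sim$exposure, sim$ld, cfg_i)$SNP
    dropped <- setdiff(sim$exposure$SNP, kept)
    for (d in dropped)
      expect_true(any(sim$ld$r2[d, kept] > 0.3))
    for (k in kept)
      expect_true(all(sim$ld$r2[k, setdiff(kept, k)] <= 0.3))
  }
})

test_that("clumping demands LD coverage of every SNP", {
  tab <- make_stats(c("rs1", "rs2"), c(1e-10, 1e-9))
  expect_error(clump(tab, ld_matrix(diag(1), "rs1")), "rs2")
})

test_that("harmonizing identical tables keeps every row unchanged", {
  sim <- simulate_two_sample(truth_config(n_snps = 20, seed = 7))
  h <- harmonize(sim$exposure, sim$outcome)
  expect_true(all(h$action == "kept"))
  expect_equal(h$beta_outcome, sim$outcome$beta)
  expect_equal(h$eaf_outcome, sim$outcome$eaf)
})

test_that("an all-swapped outcome yields the identical IVW estimate", {
  sim <- simulate_two_sample(truth_config(n_snps = 30, theta = 0.1, seed = 9))
  swapped <- scramble_alleles(sim$outcome, swap_fraction = 1, seed = 2)
  fit_plain <- mr_ivw(retained(harmonize(sim$exposure, sim$outcome)))
  fit_swap <- mr_ivw(retained(harmonize(sim$exposure, swapped)))
  expect_equal(fit_swap$beta, fit_plain$beta, tolerance = 1e-12)
  expect_equal(fit_swap$se, fit_plain$se, tolerance = 1e-12)
})

test_that("strand-flipped rows are recognized and left numerically intact", {
  sim <- simulate_two_sample(truth_config(n_snps = 30, seed = 10))
  flipped <- scramble_alleles(sim$outcome, flip_fraction = 1, seed = 2)
  h <- harmonize(sim$exposure, flipped)
  expect_true(all(h$action == "strand-flipped"))
  expect_equal(h$beta_outcome, sim$outcome$beta)
})

test_that("harmonization is idempotent on its own output", {
  sim <- simulate_two_sample(truth_config(n_snps = 40, theta = 0.1, seed = 14))
  scr <- scramble_alleles(sim$outcome, flip_fraction = 0.3, swap_fraction = 0.3,
                          seed = 4)
  h1 <- retained(harmonize(sim$exposure, scr))
  # rebuild the two tables from the harmonized rows and harmonize again
  expo2 <- data.frame(SNP = h1$SNP, effect_allele = h1$effect_allele,
                      other_allele = h1$other_allele, eaf = h1$eaf_exposure,
                      beta = h1$beta_exposure, se = h1$se_exposure,
                      pval = h1$pval_exposure, n = 1e5,
                      stringsAsFactors = FALSE)
  outc2 <- transform(expo2, eaf = h1$eaf_outcome, beta = h1$beta_outcome,
                     se = h1$se_outcome)
  h2 <- harmonize(expo2, outc2)
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$beta_exposure, h1$beta_exposure)
})

test_that("palindromic SNPs without usable frequency are dropped", {
  tab <- make_stats(c("rs1", "rs2"), c(1e-9, 1e-9), ea = "A", oa = "T")
  tab$eaf <- c(NA, 0.2)
  out <- tab
  out$eaf <- c(0.3, NA)
  h <- harmonize(tab, out)
  expect_identical(h$action, rep("dropped(palindromic_missing_eaf)", 2))

  tab$eaf <- c(0.45, 0.2); out$eaf <- c(0.45, 0.55)
  h2 <- harmonize(tab, out)
  expect_identical(h2$action, rep("dropped(palindromic_ambiguous)", 2))
})

test_that("unambiguous palindromic SNPs are frequency-aligned", {
  tab <- make_stats(c("rs1", "rs2"), c(1e-9, 1e-9), ea = "G", oa = "C")
  tab$eaf <- c(0.2, 0.2)
  out <- tab
  out$beta <- c(0.05, -0.05)
  out$eaf <- c(0.21, 0.79)  # rs2 reported on the opposite strand orientation
  h <- harmonize(tab, out)
  expect_identical(h$action, c("kept", "sign-flipped"))
  expect_equal(h$beta_outcome, c(0.05, 0.05))
  expect_equal(h$eaf_outcome, c(0.21, 0.21))
})

test_that("irreconcilable alleles and missing outcome SNPs are audited drops", {
  expo <- make_stats(c("rs1", "rs2"), c(1e-9, 1e-9), ea = "A", oa = "C")
  outc <- make_stats("rs1", 1e-9, ea = "A", oa = "G")
  h <- harmonize(expo, outc)
  expect_identical(h$action, c("dropped(allele_mismatch)",
                               "dropped(missing_in_outcome)"))
  expect_error(harmonize(expo, make_stats("zz", 0.5)), "no SNPs shared")
})

test_that("select -> clump -> harmonize preserves untouched numeric fields", {
  cfg <- truth_config(n_snps = 30, theta = 0.1, seed = 23,
                      ld_block_sizes = c(6, 6), ld_rho = 0.9)
  sim <- simulate_two_sample(cfg)
  sig <- select_significant(sim$exposure)
  cl <- clump(sig, sim$ld)
  h <- retained(harmonize(cl, sim$outcome))
  src <- sim$exposure[match(h$SNP, sim$exposure$SNP), ]
  expect_equal(h$beta_exposure, src$beta)
  expect_equal(h$se_exposure, src$se)
  expect_equal(h$eaf_exposure, src$eaf)
})
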