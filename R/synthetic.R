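## synthetic_gwas: two-sample GWAS summary statistics with known causal
## structure.  Simulation is at the summary level: per-SNP effect estimates
## are drawn directly from their sampling distributions (the pipeline only
## ever sees summary statistics), with SE = 1/sqrt(2 * n * maf * (1 - maf))
## for a unit-variance trait.

#' Configuration for the synthetic two-sample generator
#'
#' Describes the generative model: per-SNP instrument effects
#' `b_j ~ N(0, instrument_effect_sd^2)` on the exposure, a causal effect
#' `theta` transmitting them to the outcome, optional direct (pleiotropic)
#' SNP-outcome effects `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)`
#' violating the exclusion restriction, and optional LD blocks within which
#' SNPs share their true effect and have noise correlated at `ld_rho`
#' (emitted LD r-squared is `ld_rho^2` within a block).
#'
#' @param n_snps Number of candidate instrument SNPs.
#' @param n_exposure_cohort,n_outcome_cohort Sample sizes of the two
#'   non-overlapping GWAS cohorts.
#' @param theta True causal effect of the exposure on the outcome (log-odds
#'   per unit exposure for a binary outcome).
#' @param instrument_effect_sd SD of the true per-SNP instrument effects
#'   (must be > 0).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of direct SNP-outcome
#'   effects; both 0 gives a valid instrument set.
#' @param maf_range Interval within (0, 0.5] from which minor allele
#'   frequencies are drawn uniformly.
#' @param seed RNG seed (integer); mandatory for reproducibility.
#' @param ld_block_sizes Integer vector of LD block sizes (blocks are filled
#'   from the first SNP onward; remaining SNPs are independent), or `NULL`.
#' @param ld_rho Within-block correlation of the underlying genotypes, in
#'   `[0, 1)`.
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(n_snps = 50L,
                         n_exposure_cohort = 1e5,
                         n_outcome_cohort = 3e5,
                         theta = 0,
                         instrument_effect_sd = 0.15,
                         pleiotropy_mean = 0,
                         pleiotropy_sd = 0,
                         maf_range = c(0.05, 0.5),
                         seed = 1L,
                         ld_block_sizes = NULL,
                         ld_rho = 0) {
  if (!is_count(n_snps) || n_snps < 1) stop_protmr("n_snps must be a positive count")
  if (!is_count(n_exposure_cohort) || !is_count(n_outcome_cohort) ||
      n_exposure_cohort < 2 || n_outcome_cohort < 2)
    stop_protmr("cohort sizes must be counts >= 2")
  if (!is_number(theta)) stop_protmr("theta must be finite")
  if (!is_number(instrument_effect_sd) || instrument_effect_sd <= 0)
    stop_protmr("instrument_effect_sd must be > 0")
  if (!is_number(pleiotropy_mean) || !is_number(pleiotropy_sd) || pleiotropy_sd < 0)
    stop_protmr("pleiotropy parameters must be finite (sd >= 0)")
  if (length(maf_range) != 2L || !all(is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_protmr("maf_range must lie within (0, 0.5]")
  if (!is_count(seed)) stop_protmr("seed must be a non-negative integer")
  if (!is.null(ld_block_sizes)) {
    if (!all(vapply(ld_block_sizes, is_count, logical(1))) ||
        sum(ld_block_sizes) > n_snps)
      stop_protmr("ld_block_sizes must be counts summing to <= n_snps")
  }
  if (!is_number(ld_rho) || ld_rho < 0 || ld_rho >= 1)
    stop_protmr("ld_rho must be in [0, 1)")
  structure(list(n_snps = as.integer(n_snps),
                 n_exposure_cohort = n_exposure_cohort,
                 n_outcome_cohort = n_outcome_cohort,
                 theta = theta,
                 instrument_effect_sd = instrument_effect_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 maf_range = maf_range,
                 seed = as.integer(seed),
                 ld_block_sizes = ld_block_sizes,
                 ld_rho = ld_rho),
            class = "truth_config")
}

#' Configuration of a true exposure -> mediator -> outcome causal chain
#'
#' The total exposure effect decomposes as
#' `theta_EO = theta_direct + theta_EM * theta_MO`, and when `theta_EO != 0`
#' the true proportion mediated is `theta_EM * theta_MO / theta_EO`.
#'
#' @param theta_EM True exposure-on-mediator effect.
#' @param theta_MO True mediator-on-outcome effect.
#' @param theta_direct Direct exposure-on-outcome effect not through the
#'   mediator.
#' @return An object of class `chain_config` carrying the derived `theta_EO`
#'   and `proportion_mediated` (NA when `theta_EO == 0`).
#' @export
chain_config <- function(theta_EM, theta_MO, theta_direct = 0) {
  for (v in c(theta_EM, theta_MO, theta_direct))
    if (!is_number(v)) stop_protmr("chain effects must be finite numbers")
  theta_EO <- theta_direct + theta_EM * theta_MO
  structure(list(theta_EM = theta_EM, theta_MO = theta_MO,
                 theta_direct = theta_direct, theta_EO = theta_EO,
                 proportion_mediated = if (theta_EO != 0)
                   theta_EM * theta_MO / theta_EO else NA_real_),
            class = "chain_config")
}

## Non-palindromic allele pairs used for simulated SNPs; harmonization tests
## inject palindromic pairs explicitly via scramble_alleles().
NONPALINDROMIC_PAIRS <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"),
                               ncol = 2, byrow = TRUE)

# block id per SNP (0 = independent); blocks fill from the first SNP
ld_block_ids <- function(config) {
  ids <- integer(config$n_snps)
  if (!is.null(config$ld_block_sizes) && length(config$ld_block_sizes)) {
    ends <- cumsum(config$ld_block_sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (k in seq_along(ends)) ids[starts[k]:ends[k]] <- k
  }
  ids
}

# noise vector of length n with within-block correlation rho (unit variance)
correlated_noise <- function(blocks, rho) {
  z <- stats::rnorm(length(blocks))
  if (rho > 0 && any(blocks > 0)) {
    shared <- stats::rnorm(max(blocks))
    inb <- blocks > 0
    z[inb] <- rho * shared[blocks[inb]] + sqrt(1 - rho^2) * z[inb]
  }
  z
}

make_summary_stats <- function(snp, ea, oa, eaf, beta, se, n) {
  data.frame(SNP = snp, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se,
             pval = pmax(2 * stats::pnorm(-abs(beta / se)),
                         .Machine$double.xmin), n = n,
             stringsAsFactors = FALSE)
}

# shared scaffold: SNP ids, alleles, MAFs, per-cohort SEs, true effects
draw_scaffold <- function(config) {
  n <- config$n_snps
  snp <- sprintf("rs%05d", seq_len(n))
  pair <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS), n, replace = TRUE), ,
                               drop = FALSE]
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  blocks <- ld_block_ids(config)
  b <- stats::rnorm(n, 0, config$instrument_effect_sd)
  if (any(blocks > 0)) {  # SNPs in a block tag the same causal signal
    for (k in unique(blocks[blocks > 0])) b[blocks == k] <- b[which(blocks == k)[1]]
  }
  alpha <- if (config$pleiotropy_sd > 0 || config$pleiotropy_mean != 0)
    stats::rnorm(n, config$pleiotropy_mean, config$pleiotropy_sd) else numeric(n)
  list(snp = snp, ea = pair[, 1], oa = pair[, 2], maf = maf,
       blocks = blocks, b = b, alpha = alpha,
       se_x = 1 / sqrt(2 * config$n_exposure_cohort * maf * (1 - maf)),
       se_y = 1 / sqrt(2 * config$n_outcome_cohort * maf * (1 - maf)))
}

scaffold_ld <- function(sc) {
  n <- length(sc$snp)
  r2 <- diag(n)
  rho2 <- attr(sc, "ld_rho")^2
  if (any(sc$blocks > 0) && rho2 > 0) {
    for (k in unique(sc$blocks[sc$blocks > 0])) {
      idx <- which(sc$blocks == k)
      r2[idx, idx] <- rho2
      diag(r2)[idx] <- 1
    }
  }
  ld_matrix(r2, sc$snp)
}

#' Simulate two-sample GWAS summary statistics
#'
#' Draws true instrument effects once, then generates exposure and outcome
#' association tables in two independent cohorts:
#' `beta_X = b_j + e_X`, `beta_Y = theta * b_j + alpha_j + e_Y`, with noise
#' SDs given by the standard `1/sqrt(2 n maf (1 - maf))` scaling.  Within LD
#' blocks the noise draws are correlated at `ld_rho` and the matching LD
#' matrix (r-squared `ld_rho^2` within blocks) is returned.
#'
#' @param config A [truth_config()].
#' @return A list with elements `exposure`, `outcome` (canonical
#'   summary-statistics data frames), `ld` (an [ld_matrix()]), and `truth`
#'   (the config echoed back, plus the realized `b`, `alpha` and block ids).
#' @examples
#' sim <- simulate_two_sample(truth_config(n_snps = 20, theta = 0.1, seed = 7))
#' head(sim$exposure)
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  set.seed(config$seed)
  sc <- draw_scaffold(config)
  ex <- make_summary_stats(sc$snp, sc$ea, sc$oa, sc$maf,
                           sc$b + sc$se_x * correlated_noise(sc$blocks, config$ld_rho),
                           sc$se_x, config$n_exposure_cohort)
  out <- make_summary_stats(sc$snp, sc$ea, sc$oa, sc$maf,
                            config$theta * sc$b + sc$alpha +
                              sc$se_y * correlated_noise(sc$blocks, config$ld_rho),
                            sc$se_y, config$n_outcome_cohort)
  attr(sc, "ld_rho") <- config$ld_rho
  truth <- c(unclass(config), list(b = sc$b, alpha = sc$alpha, blocks = sc$blocks))
  list(exposure = ex, outcome = out, ld = scaffold_ld(sc), truth = truth)
}

#' Simulate an exposure -> mediator -> outcome summary-statistics chain
#'
#' Two disjoint instrument sets are generated, `n_snps` each.  Exposure
#' instruments (ids `rs...`) have true effects `b_j` on the exposure,
#' `theta_EM * b_j` on the mediator and
#' `theta_EO * b_j = (theta_direct + theta_EM * theta_MO) * b_j` on the
#' outcome.  Mediator-specific instruments (ids `rsM...`) have effects `m_k`
#' on the mediator, `theta_MO * m_k` on the outcome and zero on the exposure
#' — without them `theta_MO` is not identifiable: a mediator-on-outcome MR
#' run on exposure-driven instruments alone estimates `theta_EO / theta_EM`,
#' not `theta_MO`.  All three cohorts draw independent noise (the mediator
#' cohort uses `n_outcome_cohort`); pleiotropy `alpha_j` applies to the
#' outcome.
#'
#' @param config A [truth_config()]; `config$theta` is ignored (the chain
#'   defines the outcome effect); `n_snps` counts each instrument set.
#' @param chain A [chain_config()].
#' @return List with `exposure`, `mediator`, `outcome` (each covering both
#'   instrument sets), `ld`, and `truth` (config echo plus the chain,
#'   including the implied proportion mediated and the instrument sets).
#' @export
simulate_chain <- function(config, chain) {
  stopifnot(inherits(config, "truth_config"), inherits(chain, "chain_config"))
  set.seed(config$seed)
  sc <- draw_scaffold(config)
  rho <- config$ld_rho
  n <- config$n_snps
  # mediator-specific instruments: own ids, alleles, MAFs and true effects
  msnp <- sprintf("rsM%04d", seq_len(n))
  mpair <- NONPALINDROMIC_PAIRS[sample.int(4, n, replace = TRUE), , drop = FALSE]
  mmaf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  m <- stats::rnorm(n, 0, config$instrument_effect_sd)
  mse_x <- 1 / sqrt(2 * config$n_exposure_cohort * mmaf * (1 - mmaf))
  mse_y <- 1 / sqrt(2 * config$n_outcome_cohort * mmaf * (1 - mmaf))

  snp <- c(sc$snp, msnp)
  ea <- c(sc$ea, mpair[, 1]); oa <- c(sc$oa, mpair[, 2])
  maf <- c(sc$maf, mmaf)
  se_x <- c(sc$se_x, mse_x); se_y <- c(sc$se_y, mse_y)
  blocks <- c(sc$blocks, integer(n))   # mediator instruments are LD-free
  true_x <- c(sc$b, numeric(n))
  true_m <- c(chain$theta_EM * sc$b, m)
  true_y <- c(chain$theta_EO * sc$b + sc$alpha, chain$theta_MO * m)

  noise <- function(se) se * correlated_noise(blocks, rho)
  ex <- make_summary_stats(snp, ea, oa, maf, true_x + noise(se_x), se_x,
                           config$n_exposure_cohort)
  med <- make_summary_stats(snp, ea, oa, maf, true_m + noise(se_y), se_y,
                            config$n_outcome_cohort)
  out <- make_summary_stats(snp, ea, oa, maf, true_y + noise(se_y), se_y,
                            config$n_outcome_cohort)
  sc2 <- list(snp = snp, blocks = blocks)
  attr(sc2, "ld_rho") <- rho
  truth <- c(unclass(config), unclass(chain),
             list(b = sc$b, m = m, alpha = sc$alpha, blocks = blocks,
                  exposure_instruments = sc$snp,
                  mediator_instruments = msnp))
  list(exposure = ex, mediator = med, outcome = out,
       ld = scaffold_ld(sc2), truth = truth)
}

#' Inject allele-coding noise into a summary-statistics table
#'
#' Creates the misalignments that harmonization must undo.  Rows are
#' partitioned (disjointly, under the seed's permutation) into:
#' *palindromic* rows, whose allele pair is replaced by A/T or G/C (betas and
#' frequencies untouched); *swapped* rows, whose alleles are exchanged with
#' `beta` negated and `eaf` reflected to `1 - eaf`; and *flipped* rows, whose
#' alleles are both strand-complemented with `beta`/`eaf` unchanged.
#'
#' Because the permutation and the palindromic pair choices are drawn first,
#' calling this on two tables with the same SNP order and the same `seed` and
#' `palindromic_fraction` makes the *same* rows palindromic with the *same*
#' pairs in both — use that to plant palindromic SNPs consistently in an
#' exposure/outcome pair while scrambling only the outcome.
#'
#' @param stats Canonical summary-statistics data frame.
#' @param flip_fraction,swap_fraction,palindromic_fraction Fractions of rows
#'   (in `[0, 1]`, summing to at most 1) receiving each edit.
#' @param seed RNG seed.
#' @return The edited table, with attribute `scramble_log`: a data frame of
#'   `{SNP, action}` where action is one of `none`, `palindromic`, `swapped`,
#'   `flipped`.
#' @export
scramble_alleles <- function(stats, flip_fraction = 0, swap_fraction = 0,
                             palindromic_fraction = 0, seed = 1L) {
  check_fraction(flip_fraction, "flip_fraction")
  check_fraction(swap_fraction, "swap_fraction")
  check_fraction(palindromic_fraction, "palindromic_fraction")
  if (flip_fraction + swap_fraction + palindromic_fraction > 1 + 1e-12)
    stop_protmr("scramble fractions must sum to at most 1")
  n <- nrow(stats)
  set.seed(seed)
  perm <- sample.int(n)
  n_pal <- round(palindromic_fraction * n)
  n_swap <- round(swap_fraction * n)
  n_flip <- round(flip_fraction * n)
  pal_idx <- perm[seq_len(n_pal)]
  swap_idx <- perm[n_pal + seq_len(n_swap)]
  flip_idx <- perm[n_pal + n_swap + seq_len(n_flip)]
  # pair choices drawn immediately after the permutation so that two calls
  # with the same seed agree on them
  pal_pairs <- matrix(c("A", "T", "G", "C"), ncol = 2, byrow = TRUE)[
    sample.int(2, n_pal, replace = TRUE), , drop = FALSE]

  out <- stats
  if (n_pal) {
    out$effect_allele[pal_idx] <- pal_pairs[, 1]
    out$other_allele[pal_idx] <- pal_pairs[, 2]
  }
  if (length(swap_idx)) {
    ea <- out$effect_allele[swap_idx]
    out$effect_allele[swap_idx] <- out$other_allele[swap_idx]
    out$other_allele[swap_idx] <- ea
    out$beta[swap_idx] <- -out$beta[swap_idx]
    out$eaf[swap_idx] <- 1 - out$eaf[swap_idx]
  }
  if (length(flip_idx)) {
    out$effect_allele[flip_idx] <- complement_allele(out$effect_allele[flip_idx])
    out$other_allele[flip_idx] <- complement_allele(out$other_allele[flip_idx])
  }
  action <- rep("none", n)
  action[pal_idx] <- "palindromic"
  action[swap_idx] <- "swapped"
  action[flip_idx] <- "flipped"
  attr(out, "scramble_log") <- data.frame(SNP = stats$SNP, action = action,
                                          stringsAsFactors = FALSE)
  out
}

#' Simulate a multi-exposure panel sharing one outcome cohort
#'
#' Emulates a proteome-wide screen at reduced scale: each exposure gets its
#' own independent instrument scaffold (distinct SNP ids); `n_causal`
#' exposures act on the outcome with effect `effect`, the rest with 0.  All
#' outcome rows come from one shared outcome cohort.
#'
#' @param n_exposures Number of exposures (proteins) in the panel.
#' @param n_causal Number with a true causal effect (must be `<=`
#'   `n_exposures`); the first `n_causal` exposures are causal and the truth
#'   table records the labels.
#' @param effect True causal effect for the causal exposures.
#' @param config Template [truth_config()]; `n_snps`, cohort sizes, MAF range
#'   and instrument strength apply per exposure (LD blocks are not used here;
#'   panel instruments are independent).
#' @param seed RNG seed for the whole panel.
#' @return List with `exposures` (named list of summary-stat tables),
#'   `outcome` (one table over all panel SNPs), and `truth`
#'   (data frame `{exposure_id, theta, causal}`).
#' @export
simulate_panel <- function(n_exposures, n_causal, effect = 0.1,
                           config = truth_config(), seed = 1L) {
  if (!is_count(n_exposures) || n_exposures < 1)
    stop_protmr("n_exposures must be a positive count")
  if (!is_count(n_causal) || n_causal > n_exposures)
    stop_protmr("n_causal must be a count <= n_exposures")
  stopifnot(inherits(config, "truth_config"))
  set.seed(seed)
  ids <- sprintf("EXP%04d", seq_len(n_exposures))
  theta <- c(rep(effect, n_causal), rep(0, n_exposures - n_causal))
  exposures <- vector("list", n_exposures)
  outcome_parts <- vector("list", n_exposures)
  n <- config$n_snps
  for (i in seq_len(n_exposures)) {
    snp <- sprintf("%s_rs%03d", ids[i], seq_len(n))
    pair <- NONPALINDROMIC_PAIRS[sample.int(4, n, replace = TRUE), , drop = FALSE]
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    b <- stats::rnorm(n, 0, config$instrument_effect_sd)
    se_x <- 1 / sqrt(2 * config$n_exposure_cohort * maf * (1 - maf))
    se_y <- 1 / sqrt(2 * config$n_outcome_cohort * maf * (1 - maf))
    exposures[[i]] <- make_summary_stats(snp, pair[, 1], pair[, 2], maf,
                                         b + stats::rnorm(n, 0, se_x), se_x,
                                         config$n_exposure_cohort)
    outcome_parts[[i]] <- make_summary_stats(snp, pair[, 1], pair[, 2], maf,
                                             theta[i] * b + stats::rnorm(n, 0, se_y),
                                             se_y, config$n_outcome_cohort)
  }
  names(exposures) <- ids
  list(exposures = exposures,
       outcome = do.call(rbind, outcome_parts),
       truth = data.frame(exposure_id = ids, theta = theta,
                          causal = theta != 0, stringsAsFactors = FALSE))
}

#' Simulate a phenotype catalogue for an MR-PheWAS scan
#'
#' One exposure instrument scaffold is scanned against `n_phenotypes`
#' synthetic phenotype GWAS tables; the first `n_affected` phenotypes are
#' truly affected by the exposure with effect `effect`, the rest are null.
#'
#' @param n_phenotypes Catalogue size.
#' @param n_affected Number of truly affected phenotypes.
#' @param effect True causal effect on affected phenotypes.
#' @param config Template [truth_config()] for the exposure scaffold.
#' @param seed RNG seed.
#' @return List with `exposure`, `phenotypes` (named list keyed by phecode),
#'   `catalog` (phecode, label, category, n_cases, n_controls), and `truth`
#'   (`{phecode, theta, affected}`).
#' @export
simulate_phewas <- function(n_phenotypes, n_affected, effect = 0.1,
                            config = truth_config(), seed = 1L) {
  if (!is_count(n_phenotypes) || n_phenotypes < 1)
    stop_protmr("n_phenotypes must be a positive count")
  if (!is_count(n_affected) || n_affected > n_phenotypes)
    stop_protmr("n_affected must be a count <= n_phenotypes")
  set.seed(seed)
  sc <- draw_scaffold(config)
  exposure <- make_summary_stats(sc$snp, sc$ea, sc$oa, sc$maf,
                                 sc$b + stats::rnorm(config$n_snps, 0, sc$se_x),
                                 sc$se_x, config$n_exposure_cohort)
  phecodes <- sprintf("P%03d.0", seq_len(n_phenotypes))
  theta <- c(rep(effect, n_affected), rep(0, n_phenotypes - n_affected))
  cats <- c("circulatory", "endocrine", "neoplasms", "digestive", "respiratory")
  phenos <- lapply(seq_len(n_phenotypes), function(k) {
    make_summary_stats(sc$snp, sc$ea, sc$oa, sc$maf,
                       theta[k] * sc$b + stats::rnorm(config$n_snps, 0, sc$se_y),
                       sc$se_y, config$n_outcome_cohort)
  })
  names(phenos) <- phecodes
  n_cases <- round(config$n_outcome_cohort * stats::runif(n_phenotypes, 0.01, 0.2))
  list(exposure = exposure, phenotypes = phenos,
       catalog = data.frame(phecode = phecodes,
                            label = sprintf("phenotype %d", seq_len(n_phenotypes)),
                            category = rep_len(cats, n_phenotypes),
                            n_cases = n_cases,
                            n_controls = config$n_outcome_cohort - n_cases,
                            stringsAsFactors = FALSE),
       truth = data.frame(phecode = phecodes, theta = theta,
                          affected = theta != 0, stringsAsFactors = FALSE))
}
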