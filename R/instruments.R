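## instruments: genome-wide-significance filtering, greedy LD clumping and
## effect-allele harmonization.

#' Instrument-selection configuration
#'
#' @param p_threshold Genome-wide significance cutoff; instruments must have
#'   `pval < p_threshold` (default `5e-8`).
#' @param clump_r2 LD r-squared cutoff for clumping (default `0.001`).
#' @param clump_window_kb Clumping window in kb (default 10000).  Positions
#'   are optional in this package's canonical tables; when absent the window
#'   constraint is vacuous and only the r-squared rule applies.
#' @param palindromic_ambiguity Half-width of the allele-frequency ambiguity
#'   zone around 0.5 within which palindromic SNPs are dropped at
#'   harmonization (default 0.08, i.e. eaf in \[0.42, 0.58\]).
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                              clump_window_kb = 10000,
                              palindromic_ambiguity = 0.08) {
  if (!is_number(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    stop_protmr("p_threshold must be in (0, 1)")
  if (!is_number(clump_r2) || clump_r2 < 0 || clump_r2 > 1)
    stop_protmr("clump_r2 must be in [0, 1]")
  if (!is_number(palindromic_ambiguity) || palindromic_ambiguity < 0 ||
      palindromic_ambiguity >= 0.5)
    stop_protmr("palindromic_ambiguity must be in [0, 0.5)")
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 palindromic_ambiguity = palindromic_ambiguity),
            class = "instrument_config")
}

#' Keep genome-wide-significant SNPs
#'
#' @param stats Canonical summary-statistics data frame.
#' @param config An [instrument_config()].
#' @return The rows with `pval < p_threshold`, input order preserved.  An
#'   empty result is returned, not an error: exposures with no significant
#'   SNP are flagged ineligible downstream.
#' @export
select_significant <- function(stats, config = instrument_config()) {
  out <- stats[stats$pval < config$p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Sorts SNPs by p-value ascending (ties broken lexicographically by SNP id),
#' then repeatedly keeps the most significant remaining SNP and discards all
#' remaining SNPs with r-squared greater than `clump_r2` against it.  The
#' procedure is fully deterministic.
#'
#' @param stats Canonical summary-statistics data frame.
#' @param ld An [ld_matrix()] covering every SNP in `stats`, or `NULL` to
#'   treat all SNPs as independent (no clumping).
#' @param config An [instrument_config()].
#' @return The retained rows, in input order.
#' @export
clump <- function(stats, ld, config = instrument_config()) {
  if (is.null(ld) || nrow(stats) <= 1L) return(stats)
  stopifnot(inherits(ld, "ld_matrix"))
  missing <- setdiff(stats$SNP, ld$snps)
  if (length(missing))
    stop_protmr("SNP(s) absent from LD matrix: ", paste(missing, collapse = ", "))
  ord <- order(stats$pval, stats$SNP)
  remaining <- stats$SNP[ord]
  kept <- character(0)
  while (length(remaining)) {
    top <- remaining[1]
    kept <- c(kept, top)
    r2 <- ld$r2[top, remaining[-1]]
    remaining <- remaining[-1][r2 <= config$clump_r2]
  }
  out <- stats[stats$SNP %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harmonize exposure and outcome effect alleles
#'
#' For every SNP shared by the two tables, aligns the outcome effect to the
#' exposure's effect allele: matching alleles are kept; swapped alleles have
#' the outcome beta negated and eaf reflected; strand-complement mismatches
#' are strand-flipped and re-evaluated; palindromic (A/T or G/C) SNPs are
#' dropped when either allele frequency is missing or inside the ambiguity
#' zone around 0.5, and are otherwise frequency-aligned; irreconcilable
#' allele pairs are dropped.  Exposure SNPs absent from the outcome are
#' dropped with a reason code (no proxy search is attempted).
#'
#' @param exposure,outcome Canonical summary-statistics data frames.
#' @param config An [instrument_config()] (supplies the palindromic
#'   ambiguity half-width).
#' @return A data frame of class `harmonized_set`, one row per exposure SNP
#'   attempted, with columns `SNP`, `effect_allele`, `other_allele`,
#'   `beta_exposure`, `se_exposure`, `eaf_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_outcome` and `action` (one of `kept`, `sign-flipped`,
#'   `strand-flipped`, `strand-sign-flipped`, or `dropped(<reason>)`).
#'   Use [retained()] to extract the usable rows.
#' @export
harmonize <- function(exposure, outcome, config = instrument_config()) {
  shared <- intersect(exposure$SNP, outcome$SNP)
  if (!length(shared))
    stop_protmr("no SNPs shared between exposure and outcome tables")
  amb <- config$palindromic_ambiguity
  oidx <- match(exposure$SNP, outcome$SNP)

  n <- nrow(exposure)
  res <- data.frame(SNP = exposure$SNP,
                    effect_allele = exposure$effect_allele,
                    other_allele = exposure$other_allele,
                    beta_exposure = exposure$beta,
                    se_exposure = exposure$se,
                    eaf_exposure = exposure$eaf,
                    pval_exposure = exposure$pval,
                    beta_outcome = NA_real_, se_outcome = NA_real_,
                    eaf_outcome = NA_real_,
                    action = NA_character_, stringsAsFactors = FALSE)

  # fast path: non-palindromic rows whose alleles already match exactly
  easy <- !is.na(oidx) &
    exposure$effect_allele == outcome$effect_allele[oidx] &
    exposure$other_allele == outcome$other_allele[oidx] &
    !is_palindromic(exposure$effect_allele, exposure$other_allele)
  easy[is.na(easy)] <- FALSE
  if (any(easy)) {
    j <- oidx[easy]
    res$beta_outcome[easy] <- outcome$beta[j]
    res$se_outcome[easy] <- outcome$se[j]
    res$eaf_outcome[easy] <- outcome$eaf[j]
    res$action[easy] <- "kept"
  }

  for (i in which(!easy)) {
    j <- oidx[i]
    if (is.na(j)) {
      res$action[i] <- "dropped(missing_in_outcome)"
      next
    }
    ea_x <- exposure$effect_allele[i]; oa_x <- exposure$other_allele[i]
    ea_y <- outcome$effect_allele[j]; oa_y <- outcome$other_allele[j]
    by <- outcome$beta[j]; sy <- outcome$se[j]; fy <- outcome$eaf[j]
    fx <- exposure$eaf[i]
    pal <- is_palindromic(ea_x, oa_x)

    if (pal) {
      # outcome alleles must form the same palindromic pair (a strand flip
      # maps the pair onto itself, so letters cannot resolve orientation)
      if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
        res$action[i] <- "dropped(allele_mismatch)"
        next
      }
      if (is.na(fx) || is.na(fy)) {
        res$action[i] <- "dropped(palindromic_missing_eaf)"
        next
      }
      if (abs(fx - 0.5) <= amb || abs(fy - 0.5) <= amb) {
        res$action[i] <- "dropped(palindromic_ambiguous)"
        next
      }
      # align by letters first, then let frequency decide the strand
      nflip <- 0L
      if (ea_y == oa_x) { by <- -by; fy <- 1 - fy; nflip <- nflip + 1L }
      if ((fx - 0.5) * (fy - 0.5) < 0) { by <- -by; fy <- 1 - fy; nflip <- nflip + 1L }
      res$beta_outcome[i] <- by; res$se_outcome[i] <- sy; res$eaf_outcome[i] <- fy
      res$action[i] <- if (nflip %% 2L == 1L) "sign-flipped" else "kept"
      next
    }

    strand <- FALSE
    if (!(ea_y %in% c(ea_x, oa_x)) || !(oa_y %in% c(ea_x, oa_x))) {
      # try the complementary strand
      ea_y <- complement_allele(ea_y); oa_y <- complement_allele(oa_y)
      strand <- TRUE
    }
    if (ea_y == ea_x && oa_y == oa_x) {
      res$action[i] <- if (strand) "strand-flipped" else "kept"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      by <- -by
      if (!is.na(fy)) fy <- 1 - fy
      res$action[i] <- if (strand) "strand-sign-flipped" else "sign-flipped"
    } else {
      res$action[i] <- "dropped(allele_mismatch)"
      next
    }
    res$beta_outcome[i] <- by; res$se_outcome[i] <- sy; res$eaf_outcome[i] <- fy
  }
  class(res) <- c("harmonized_set", "data.frame")
  res
}

#' Extract the retained rows of a harmonized set
#'
#' @param h A `harmonized_set` from [harmonize()].
#' @return The rows whose action is not a drop, as a plain `harmonized_set`.
#' @export
retained <- function(h) {
  out <- h[!startsWith(h$action, "dropped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  kept <- sum(!startsWith(x$action, "dropped"))
  cat("Harmonized exposure/outcome set: ", kept, " of ", nrow(x),
      " SNPs retained\n", sep = "")
  tab <- table(x$action)
  for (nm in names(tab)) cat(sprintf("  %-32s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Select, clump and harmonize instruments in one call
#'
#' Convenience wrapper running the assumption-1 pipeline: genome-wide
#' significance filter on the exposure, greedy LD clumping, then
#' harmonization against the outcome.
#'
#' @inheritParams harmonize
#' @param ld An [ld_matrix()] or `NULL` (instruments treated as independent).
#' @return A `harmonized_set` (possibly with zero retained rows); `NULL` if
#'   the exposure has no genome-wide-significant SNP (ineligible).
#' @export
prepare_instruments <- function(exposure, outcome, ld = NULL,
                                config = instrument_config()) {
  sig <- select_significant(exposure, config)
  if (nrow(sig) == 0L) return(NULL)
  harmonize(clump(sig, ld, config), outcome, config)
}
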