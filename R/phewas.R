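## phewas_scan: scan one exposure's instruments across a phenotype catalogue
## (MR-PheWAS).  Each phenotype's summary statistics are harmonized against
## the exposure instruments and IVW-estimated; BH FDR is applied across
## phenotypes within the exposure.

#' MR-PheWAS: scan exposure instruments across a phenotype catalogue
#'
#' Instruments are selected once from the exposure (significance filter +
#' clumping), then harmonized against each phenotype's summary statistics and
#' combined by IVW.  Phenotypes with no overlapping instrument yield a
#' reason-coded row, never a silent omission: the result always has one row
#' per catalogue entry.  BH adjustment runs across the phenotypes that
#' produced an estimate.
#'
#' @param exposure Canonical summary-statistics table for the exposure.
#' @param phenotypes Named list of canonical summary-statistics tables keyed
#'   by phecode, or a directory containing `<phecode>.tsv` files.
#' @param catalog Phenotype catalogue data frame (phecode, label, category,
#'   n_cases, n_controls), e.g. from [read_phenotype_catalog()].
#' @param ld An [ld_matrix()] or `NULL`.
#' @param config An [instrument_config()].
#' @param fdr_threshold Threshold recorded for downstream summaries.
#' @param exposure_id Label carried into the result rows.
#' @return Data frame of class `mr_phewas`, one row per catalogue phenotype,
#'   sorted by `fdr` then `pval`: `exposure_id`, `phecode`, `label`,
#'   `category`, `n_snps_used`, `beta`, `se`, `ci_low`, `ci_high`, `pval`,
#'   `q_stat`, `q_df`, `q_pval`, `fdr`, `reason`.
#' @export
run_phewas <- function(exposure, phenotypes, catalog, ld = NULL,
                       config = instrument_config(), fdr_threshold = 0.05,
                       exposure_id = "exposure") {
  instr <- clump(select_significant(exposure, config), ld, config)
  if (nrow(instr) == 0L)
    stop_protmr("exposure has no genome-wide-significant instrument")
  get_pheno <- function(code) {
    if (is.list(phenotypes)) return(phenotypes[[code]])
    path <- file.path(phenotypes, paste0(code, ".tsv"))
    if (!file.exists(path)) return(NULL)
    read_summary_stats(path)
  }
  rows <- lapply(seq_len(nrow(catalog)), function(k) {
    code <- catalog$phecode[k]
    row <- data.frame(exposure_id = exposure_id, phecode = code,
                      label = catalog$label[k], category = catalog$category[k],
                      n_snps_used = 0L, beta = NA_real_, se = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
                      q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
                      fdr = NA_real_, reason = "", stringsAsFactors = FALSE)
    pheno <- get_pheno(code)
    if (is.null(pheno)) {
      row$reason <- "phenotype_table_missing"
      return(row)
    }
    tryCatch({
      r <- retained(harmonize(instr, pheno, config))
      if (nrow(r) == 0L) {
        row$reason <- "no_harmonizable_snp"
        return(row)
      }
      fit <- mr_ivw(r)
      row$n_snps_used <- fit$n_snp
      row$beta <- fit$beta; row$se <- fit$se
      row$ci_low <- fit$ci_low; row$ci_high <- fit$ci_high
      row$pval <- fit$pval
      row$q_stat <- fit$q_stat; row$q_df <- fit$q_df; row$q_pval <- fit$q_pval
      row
    }, protmr_error = function(e) {
      row$reason <- "no_overlapping_snp"
      row
    })
  })
  out <- do.call(rbind, rows)
  est <- !is.na(out$pval)
  out$fdr[est] <- bh_fdr(out$pval[est])
  out <- out[order(out$fdr, out$pval, out$phecode, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("mr_phewas", "data.frame")
  out
}

#' Per-category summary of an MR-PheWAS result
#'
#' @param result An `mr_phewas` from [run_phewas()].
#' @param fdr_threshold Threshold for the significance counts; defaults to
#'   the one recorded on the result.
#' @return Data frame with one row per phenotype category: `category`,
#'   `n_tested` (rows with an estimate), `n_significant` (FDR below
#'   threshold), `n_positive`, `n_negative` (direction tallies among the
#'   significant rows).
#' @export
category_summary <- function(result, fdr_threshold = NULL) {
  stopifnot(inherits(result, "mr_phewas"))
  if (nrow(result) == 0L) stop_protmr("empty PheWAS result")
  thr <- fdr_threshold %||% attr(result, "fdr_threshold") %||% 0.05
  cats <- unique(result$category)
  rows <- lapply(cats, function(cc) {
    r <- result[result$category == cc, , drop = FALSE]
    sig <- !is.na(r$fdr) & r$fdr < thr
    data.frame(category = cc, n_tested = sum(!is.na(r$pval)),
               n_significant = sum(sig),
               n_positive = sum(sig & r$beta > 0),
               n_negative = sum(sig & r$beta < 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
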