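## screen: proteome-style multi-exposure scan with BH FDR control.

#' Benjamini-Hochberg adjusted p-values
#'
#' The step-up procedure: sort ascending, take
#' `adjusted_i = min over j >= i of (p_(j) * m / j)`, cap at 1, and return in
#' input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted values, same length and order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stop_protmr("p-values must lie in (0, 1]")
  m <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * pvals[o]))[ro]
}

#' Run a multi-exposure MR screen against one outcome
#'
#' For every exposure in the panel: genome-wide-significance filter, greedy
#' LD clumping, harmonization against the shared outcome, and IVW
#' estimation.  Exposures with no genome-wide-significant SNP are ineligible:
#' they carry no estimate and are excluded from the FDR denominator
#' (mirroring a screen that retains only proteins with at least one
#' significant pQTL).  BH adjustment is applied across the eligible,
#' successfully estimated exposures.
#'
#' @param exposures Named list of canonical summary-statistics tables (names
#'   are the exposure ids).
#' @param outcome Canonical summary-statistics table for the shared outcome.
#' @param ld An [ld_matrix()] covering all exposure SNPs, or `NULL` to treat
#'   instruments as independent.
#' @param config An [instrument_config()].
#' @param fdr_threshold Significance threshold on the adjusted values used
#'   by downstream tables (default 0.05).
#' @return Data frame of class `mr_screen`, one row per exposure, sorted by
#'   `fdr`, then `pval`, then `exposure_id` (ineligible/failed rows last):
#'   columns `exposure_id`, `eligible`, `n_snps_used`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `q_stat`, `q_df`, `q_pval`, `fdr`,
#'   `reason`.
#' @export
run_screen <- function(exposures, outcome, ld = NULL,
                       config = instrument_config(), fdr_threshold = 0.05) {
  if (!length(exposures)) stop_protmr("empty exposure panel")
  ids <- names(exposures) %||% sprintf("EXP%04d", seq_along(exposures))
  if (is.null(names(exposures))) names(exposures) <- ids
  rows <- lapply(ids, function(id) {
    row <- data.frame(exposure_id = id, eligible = FALSE,
                      n_snps_used = 0L, beta = NA_real_, se = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
                      q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
                      fdr = NA_real_, reason = "", stringsAsFactors = FALSE)
    tryCatch({
      h <- prepare_instruments(exposures[[id]], outcome, ld, config)
      if (is.null(h)) {
        row$reason <- "no_significant_snp"
        return(row)
      }
      r <- retained(h)
      if (nrow(r) == 0L) {
        row$eligible <- TRUE
        row$reason <- "no_harmonizable_snp"
        return(row)
      }
      fit <- mr_ivw(r)
      row$eligible <- TRUE
      row$n_snps_used <- fit$n_snp
      row$beta <- fit$beta; row$se <- fit$se
      row$ci_low <- fit$ci_low; row$ci_high <- fit$ci_high
      row$pval <- fit$pval
      row$q_stat <- fit$q_stat; row$q_df <- fit$q_df; row$q_pval <- fit$q_pval
      row
    }, protmr_error = function(e) {
      row$reason <- conditionMessage(e)
      row
    })
  })
  out <- do.call(rbind, rows)
  est <- !is.na(out$pval)
  out$fdr[est] <- bh_fdr(out$pval[est])
  out <- out[order(out$fdr, out$pval, out$exposure_id, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("mr_screen", "data.frame")
  out
}

#' Volcano-plot coordinates for a screen result
#'
#' @param result An `mr_screen` from [run_screen()].
#' @param fdr_threshold Threshold for the significance flag; defaults to the
#'   one recorded on the screen result.
#' @return Data frame with `exposure_id`, `beta` (x), `neg_log10_p` (y) and
#'   `significant` (adjusted value below the threshold), estimated rows only.
#' @export
volcano_table <- function(result, fdr_threshold = NULL) {
  stopifnot(inherits(result, "mr_screen"))
  thr <- fdr_threshold %||% attr(result, "fdr_threshold") %||% 0.05
  est <- result[!is.na(result$pval), , drop = FALSE]
  if (nrow(est) == 0L) stop_protmr("screen result carries no estimates")
  data.frame(exposure_id = est$exposure_id, beta = est$beta,
             neg_log10_p = -log10(est$pval),
             significant = !is.na(est$fdr) & est$fdr < thr,
             stringsAsFactors = FALSE)
}

#' @export
print.mr_screen <- function(x, ...) {
  thr <- attr(x, "fdr_threshold") %||% 0.05
  cat("MR screen: ", nrow(x), " exposures, ", sum(x$eligible),
      " eligible, ", sum(!is.na(x$fdr) & x$fdr < thr),
      " with FDR < ", thr, "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}
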