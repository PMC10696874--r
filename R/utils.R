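## Internal helpers shared across modules.

# 95% normal quantile, fixed so CIs are bit-reproducible across platforms
Z95 <- 1.959964

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_protmr <- function(..., class = "protmr_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == floor(x)

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

check_fraction <- function(x, name) {
  if (!is_number(x) || x < 0 || x > 1)
    stop_protmr(name, " must be a single value in [0, 1]")
  invisible(x)
}

#' Format an odds ratio with its confidence interval for display
#'
#' Renders `exp(beta)` and its 95% confidence limits in the fixed-precision
#' style used in MR result tables, e.g. `"1.00142 [1.00068, 1.00216]"`.
#' Machine-precision values are kept in the numeric columns of result tables;
#' this string is a display copy only.
#'
#' @param beta Causal effect on the log-odds (or linear) scale.
#' @param ci_low,ci_high Confidence limits on the same scale as `beta`.
#' @param digits Number of decimals in the display copy (default 5).
#' @return A character string `"OR [low, high]"`.
#' @examples
#' format_or_ci(0, -0.01, 0.01)
#' @export
format_or_ci <- function(beta, ci_low, ci_high, digits = 5L) {
  fmt <- paste0("%.", digits, "f")
  sprintf(paste0(fmt, " [", fmt, ", ", fmt, "]"),
          exp(beta), exp(ci_low), exp(ci_high))
}

## Complement map for strand flips
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) unname(DNA_COMPLEMENT[a])

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}
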