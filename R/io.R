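## gwas_io: reading/writing summary statistics, LD matrices, phenotype
## catalogues and result tables.  The canonical on-disk dialect is TSV with
## the eight headers SNP, effect_allele, other_allele, eaf, beta, se, pval, n.

CANONICAL_COLS <- c("SNP", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n")
REQUIRED_COLS <- c("SNP", "effect_allele", "other_allele", "beta", "se", "pval")

#' Map foreign summary-statistic column names onto the canonical dialect
#'
#' GWAS summary statistics come in many dialects.  A column map translates the
#' source file's headers to the canonical names used throughout the package.
#' `SNP`, `effect_allele`, `other_allele`, `beta`, `se` and `pval` must be
#' mapped; `eaf` and `n` may be `NA` and are then carried as missing, which in
#' turn forces palindromic SNPs to be dropped at harmonization (no frequency
#' to align on).
#'
#' @param SNP,effect_allele,other_allele,eaf,beta,se,pval,n Source column
#'   names (character), or `NA` for the optional `eaf`/`n`.
#' @return An object of class `column_map`.
#' @examples
#' column_map(SNP = "rsid", beta = "b", se = "stderr", pval = "p",
#'            effect_allele = "A1", other_allele = "A2")
#' @export
column_map <- function(SNP = "SNP", effect_allele = "effect_allele",
                       other_allele = "other_allele", eaf = "eaf",
                       beta = "beta", se = "se", pval = "pval", n = "n") {
  m <- list(SNP = SNP, effect_allele = effect_allele,
            other_allele = other_allele, eaf = eaf, beta = beta,
            se = se, pval = pval, n = n)
  for (nm in REQUIRED_COLS)
    if (!is.character(m[[nm]]) || is.na(m[[nm]]))
      stop_protmr("column_map: required field '", nm, "' must name a source column")
  structure(m, class = "column_map")
}

infer_delim <- function(path) {
  p <- sub("\\.gz$", "", path)
  if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
}

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Validate a summary-statistics table
#'
#' Checks each row against the invariants of the canonical table: positive SE,
#' p-value in (0, 1], distinct alleles drawn from A/C/G/T, allele frequency in
#' (0, 1) when present, and unique SNP identifiers.  Offending rows are
#' removed, each with a machine-readable reason code.
#'
#' @param stats A data frame with the canonical columns.
#' @return The cleaned table, with a `rejected` attribute holding a data frame
#'   of `{row, SNP, reason}` for every removed row (zero rows when clean).
#' @export
validate_summary_stats <- function(stats) {
  missing <- setdiff(CANONICAL_COLS, names(stats))
  if (length(missing))
    stop_protmr("summary statistics missing canonical column(s): ",
                paste(missing, collapse = ", "))
  stats$effect_allele <- toupper(stats$effect_allele)
  stats$other_allele <- toupper(stats$other_allele)

  reason <- rep(NA_character_, nrow(stats))
  bad <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- code
  }
  bad(!is.finite(stats$se) | stats$se <= 0, "non-positive SE")
  bad(!is.finite(stats$pval) | stats$pval <= 0 | stats$pval > 1,
      "p-value outside (0,1]")
  bad(!stats$effect_allele %in% names(DNA_COMPLEMENT) |
        !stats$other_allele %in% names(DNA_COMPLEMENT), "invalid allele")
  bad(stats$effect_allele == stats$other_allele, "identical alleles")
  bad(!is.finite(stats$beta), "non-finite beta")
  bad(!is.na(stats$eaf) & (stats$eaf <= 0 | stats$eaf >= 1),
      "eaf outside (0,1)")
  bad(duplicated(stats$SNP), "duplicate SNP id")

  rejected <- data.frame(row = which(!is.na(reason)),
                         SNP = stats$SNP[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  out <- stats[is.na(reason), CANONICAL_COLS, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited file (delimiter inferred from the extension: `.csv` is
#' comma, anything else tab; plain `gzip` is accepted), renames columns via a
#' [column_map()], uppercases alleles and validates every row.  Rows failing
#' validation are dropped and reported in the `rejected` attribute.
#'
#' @param path Path to the file.
#' @param map A [column_map()]; the default assumes canonical headers.
#' @return A canonical summary-statistics data frame with attribute
#'   `rejected` (see [validate_summary_stats()]).
#' @export
read_summary_stats <- function(path, map = column_map()) {
  if (!file.exists(path)) stop_protmr("file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  raw <- utils::read.table(con, header = TRUE, sep = infer_delim(path),
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L)
    stop_protmr("empty summary-statistics table: ", path,
                class = "protmr_empty_table")
  out <- data.frame(SNP = NA_character_, stringsAsFactors = FALSE)[rep(1, nrow(raw)), , drop = FALSE]
  for (nm in CANONICAL_COLS) {
    src <- map[[nm]]
    if (is.na(src) || is.null(src)) {
      out[[nm]] <- NA
      next
    }
    if (!src %in% names(raw)) {
      if (nm %in% REQUIRED_COLS)
        stop_protmr("mapped column '", src, "' (for ", nm, ") absent from ", path,
                    class = "protmr_config_error")
      out[[nm]] <- NA
      next
    }
    out[[nm]] <- raw[[src]]
  }
  out$SNP <- as.character(out$SNP)
  for (nm in c("eaf", "beta", "se", "pval", "n"))
    out[[nm]] <- as.numeric(out[[nm]])
  rownames(out) <- NULL
  validate_summary_stats(out)
}

#' Write a summary-statistics table in the canonical TSV dialect
#'
#' @param stats Canonical summary-statistics data frame.
#' @param path Output path (plain TSV; use a `.gz` suffix for gzip).
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  df <- stats[, CANONICAL_COLS, drop = FALSE]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated LD matrix object
#'
#' @param r2 Square numeric matrix of pairwise r-squared values.
#' @param snps Character vector of SNP identifiers, one per row/column.
#' @param tol Symmetry tolerance (default 1e-8).  Asymmetry beyond it is an
#'   error, never silently symmetrized.
#' @return An object of class `ld_matrix`: list with elements `snps` and `r2`
#'   (dimnames set to the SNP ids).
#' @export
ld_matrix <- function(r2, snps, tol = 1e-8) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2))
    stop_protmr("LD matrix is not square: ", nrow(r2), " x ", ncol(r2))
  if (length(snps) != nrow(r2))
    stop_protmr("LD matrix dimension (", nrow(r2),
                ") does not match SNP list length (", length(snps), ")")
  bad <- which(!is.finite(r2) | r2 < 0 | r2 > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop_protmr("LD r-squared outside [0,1] at cell [", bad[1, 1], ",",
                bad[1, 2], "]: ", r2[bad[1, 1], bad[1, 2]])
  if (any(diag(r2) != 1))
    stop_protmr("LD matrix diagonal must be exactly 1")
  asym <- max(abs(r2 - t(r2)))
  if (asym > tol)
    stop_protmr("LD matrix asymmetric beyond tolerance (max |r2 - t(r2)| = ",
                signif(asym, 3), ")")
  dimnames(r2) <- list(snps, snps)
  structure(list(snps = as.character(snps), r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix and its SNP list
#'
#' The matrix file is a plain whitespace-delimited square numeric table with
#' no header; the SNP list is one identifier per line, in matrix order.
#'
#' @param matrix_path Path to the square r-squared table.
#' @param snplist_path Path to the one-column SNP list.
#' @return An [ld_matrix()] object.
#' @export
read_ld_matrix <- function(matrix_path, snplist_path) {
  for (p in c(matrix_path, snplist_path))
    if (!file.exists(p)) stop_protmr("file not found: ", p)
  m <- as.matrix(utils::read.table(matrix_path, header = FALSE))
  snps <- readLines(snplist_path)
  snps <- snps[nzchar(snps)]
  ld_matrix(unname(m), snps)
}

#' Write an LD matrix and its SNP list
#'
#' @param ld An [ld_matrix()] object.
#' @param matrix_path,snplist_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_ld_matrix <- function(ld, matrix_path, snplist_path) {
  utils::write.table(format(unname(ld$r2), digits = 17, trim = TRUE),
                     matrix_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(ld$snps, snplist_path)
  invisible(matrix_path)
}

#' Read a phenotype catalogue
#'
#' A catalogue row links a PheCode to its label, clinical category and
#' case/control counts; the phenotype summary statistics live in separate
#' canonical TSV files keyed by PheCode.
#'
#' @param path TSV with columns phecode, label, category, n_cases, n_controls.
#' @return Data frame with those columns; duplicate phecodes are an error.
#' @export
read_phenotype_catalog <- function(path) {
  if (!file.exists(path)) stop_protmr("file not found: ", path)
  cat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("phecode", "label", "category", "n_cases", "n_controls")
  missing <- setdiff(need, names(cat))
  if (length(missing))
    stop_protmr("phenotype catalogue missing column(s): ",
                paste(missing, collapse = ", "))
  cat$phecode <- as.character(cat$phecode)
  if (anyDuplicated(cat$phecode))
    stop_protmr("duplicate phecode in catalogue: ",
                cat$phecode[duplicated(cat$phecode)][1])
  cat[, need]
}

#' Write a result table with display-precision OR/CI strings
#'
#' Writes a TSV in a deterministic column order with full-precision numeric
#' columns.  When the table carries `beta`, `ci_low` and `ci_high` columns, a
#' display copy `or_ci` in the style `"1.00142 [1.00068, 1.00216]"` is
#' appended (the numeric columns remain authoritative).
#'
#' @param table A data frame of results (e.g. from [as.data.frame.mr_estimate()]
#'   or [run_screen()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  df <- as.data.frame(table)
  if (all(c("beta", "ci_low", "ci_high") %in% names(df)) &&
      !"or_ci" %in% names(df))
    df$or_ci <- format_or_ci(df$beta, df$ci_low, df$ci_high)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return Data frame with numeric columns restored.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
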