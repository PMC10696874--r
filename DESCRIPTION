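Package: protmr
Title: Proteome-Wide Two-Sample Mendelian Randomization with Synthetic
    GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: genome-wide-significance instrument selection, greedy
    LD clumping against an explicit LD matrix, effect-allele harmonization
    with palindromic-SNP handling, Wald-ratio and inverse-variance-weighted
    (IVW) causal estimation with Cochran's Q, MR-Egger and leave-one-out
    sensitivity analyses, two-step mediation MR with delta-method standard
    errors, proteome-style multi-exposure screening under Benjamini-Hochberg
    false discovery rate control, and an MR-PheWAS scan across phenotype
    catalogues.  A synthetic summary-statistics generator with known causal
    structure (mediation chains, pleiotropy, LD blocks, allele-coding noise)
    makes every stage verifiable by parameter recovery at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
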