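---
title: "Methods: two-sample MR, mediation and screening in protmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, mediation and screening in protmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protmr)
```

## The model

protmr implements two-sample Mendelian randomization (MR) from GWAS summary
statistics.  Genetic variants serve as instrumental variables for a
modifiable exposure (here, typically a circulating protein level
instrumented by its pQTLs); the variant–exposure and variant–outcome
associations come from two non-overlapping cohorts.  Under the three
instrumental-variable assumptions — the variant is associated with the
exposure (relevance), shares no confounder with the outcome (independence),
and affects the outcome only through the exposure (exclusion restriction) —
the per-SNP Wald ratio $\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal
effect $\theta$, and the inverse-variance-weighted (IVW) combination of
Wald ratios is the primary estimator:

$$\hat\theta_{IVW} = \frac{\sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj}}
                          {\sum_j w_j \hat\beta_{Xj}^2},
  \qquad w_j = 1/\mathrm{se}(\hat\beta_{Yj})^2 .$$

This is algebraically identical to weighted regression of the outcome betas
on the exposure betas through the origin, and to the inverse-variance mean
of Wald ratios with first-order SEs; the package exploits the first form and
the test suite checks the identity against an independent weighted
least-squares fit.

For a binary outcome all effects live on the log-odds scale and results are
reported both as `beta` and as an odds-ratio view `exp(beta)` with its 95%
confidence interval; no liability-scale conversion is attempted.

## Estimator dialect

* **Random-effects scaling with an underdispersion floor.**  The IVW SE is
  the fixed-effect SE multiplied by $\max(1, \hat\sigma)$ where
  $\hat\sigma^2 = Q/(n-1)$ is the multiplicative overdispersion estimated
  from Cochran's $Q$.  The interval is therefore never narrower than the
  fixed-effect interval; `se_type = "fixed"` exposes the unscaled version
  for comparison.  This mirrors the default of the widely used two-sample
  MR toolchains.
* **Wald-ratio SE.**  First-order (`se_outcome / |beta_exposure|`): the
  instruments must pass $P < 5\times10^{-8}$, so the exposure-noise term is
  second-order.  The second-order delta form is available
  (`second_order = TRUE`) and serves as the test oracle; the two agree to
  within ~2% precisely when the per-SNP outcome z-score is small relative
  to instrument strength, the regime MR operates in.
* **MR-Egger.**  Weighted regression of the outcome betas on the exposure
  betas *with* an intercept, the same weights, and the same multiplicative
  random-effects floor.  A non-zero intercept indicates directional
  horizontal pleiotropy.  The intercept test uses a t distribution with
  $n-2$ df (it is a regression coefficient); the causal-effect p-values
  elsewhere use the normal, matching summary-data MR convention.  No
  reorientation of exposure betas is performed: the regression is run on
  effects as harmonized, so a pleiotropy distribution that is independent
  of instrument sign is estimated without attenuation.
* **Confidence intervals** use the fixed multiplier
  $\Phi^{-1}(0.975) = 1.959964$ everywhere, so output is bit-reproducible
  across platforms.
* **P-value floor.**  Computed p-values are floored at the smallest positive
  double rather than underflowing to 0, keeping them inside the (0, 1]
  domain that the BH adjustment requires.

## Instrument selection and harmonization

Instruments are SNPs with $P < 5\times10^{-8}$ in the exposure GWAS
(strictly less than), pruned by greedy LD clumping against an explicit
r² matrix: sort by p-value (ties broken lexicographically by SNP id), keep
the best remaining SNP, discard everything with $r^2 > 0.001$ (default)
against it, repeat.  Positions are optional in the canonical table, so the
conventional 10 Mb window is vacuous unless positions are supplied; with an
explicit LD matrix only the r² rule matters.  Every tie-break in the
pipeline is deterministic, so identical inputs give identical results
regardless of execution order.

Harmonization aligns the outcome effect to the exposure's effect allele:
matching alleles are kept, swapped alleles negate the outcome beta and
reflect its frequency, strand-complement mismatches are flipped and
re-evaluated.  Palindromic (A/T, G/C) SNPs cannot be resolved from letters;
they are dropped when either allele frequency is missing or within 0.08 of
0.5 (eaf in [0.42, 0.58], a common conservative default, configurable), and
otherwise frequency-aligned.  Exposure instruments absent from the outcome
are dropped with an audit code — no proxy search is attempted.  Every
dropped row carries a machine-readable reason, and the test suite verifies
actions row-for-row against the generator's truth log.

## Mediation

Two-step mediation MR: step 1 estimates $\beta_{EM}$ (exposure on mediator)
with the exposure's instruments, step 2 estimates $\beta_{MO}$ (mediator on
outcome) with the mediator's instruments, and the total effect $\beta_{EO}$
comes from the standard univariable exposure-on-outcome MR.  The indirect
effect is the product $\beta_{EM}\beta_{MO}$, its SE the first-order
(Sobel-type) delta form
$\sqrt{\beta_{EM}^2\,\mathrm{se}_{MO}^2 + \beta_{MO}^2\,\mathrm{se}_{EM}^2}$
with zero covariance across the two independently fitted steps (a
documented approximation when cohorts overlap), and the proportion mediated
is indirect / total, reported as computed — proportions outside [0, 1] are
flagged, never truncated.  The division is refused when
$|\beta_{EO}| < 10^{-6}$ (configurable floor).

One design point deserves emphasis: **instruments shared between the
exposure and the mediator are excluded from step 2** (default
`exclude_exposure_instruments = TRUE`).  A SNP that acts on the mediator
*through the exposure* violates the exclusion restriction for the
mediator→outcome model — its Wald ratio estimates
$\beta_{EO}/\beta_{EM}$, not $\beta_{MO}$ — so retaining such SNPs biases
step 2 toward the total-over-first-step ratio.  Dropping
exposure-significant SNPs keeps step 2 specific to the mediator's own
genetic signal.  Correspondingly, the chain generator gives the mediator
its own instrument set; without one, $\beta_{MO}$ is not identifiable from
summary statistics at all.

## The screen and multiplicity

`run_screen()` applies select→clump→harmonize→IVW to every exposure in a
panel against one outcome.  Exposures with no genome-wide-significant SNP
are *ineligible*: they are reported with a reason code but carry no
estimate and are excluded from the FDR denominator, mirroring a
proteome-wide screen that retains only proteins with at least one
significant pQTL.  Benjamini–Hochberg step-up adjustment (implemented
directly; checked against `p.adjust` in tests) runs across the eligible
exposures; Bonferroni-style alternatives can be applied to the returned
p-values by the user.  Per-exposure failures are recorded and skipped,
never fatal, and results are identical under any panel ordering.

The MR-PheWAS stage (`run_phewas()`) is the same machinery turned sideways:
one exposure's instruments scanned across a catalogue of phenotype summary
statistics keyed by PheCode, BH-adjusted across phenotypes within the
exposure, with one output row per catalogue entry (reason-coded when a
phenotype cannot be tested).  This implements the MR-per-phenotype reading
of a PheWAS; a per-SNP association lookup is deliberately not the default
because the protein's instrument set is the declared unit of analysis.

## The synthetic generator

Simulation is at the summary level: per-SNP estimates are drawn directly
from their sampling distributions, because the pipeline only ever sees
summary statistics and this keeps generation O(n_snps).  For SNP $j$ with
minor allele frequency $m_j$ drawn uniformly from `maf_range` and a cohort
of size $n$, the SE is the standard unit-variance-trait form
$1/\sqrt{2\,n\,m_j(1-m_j)}$.  True instrument effects are
$b_j \sim N(0, \texttt{instrument\_effect\_sd}^2)$; exposure betas are
$b_j$ plus noise, outcome betas $\theta b_j + \alpha_j$ plus independent
noise (two-sample design), with $\alpha_j$ the pleiotropic direct effects
violating the exclusion restriction when requested.  LD is emulated by
blocks that share $b_j$ and have noise correlated at `ld_rho`, with the
matching r² matrix (`ld_rho`² within blocks) emitted for clumping — no
genotype-level simulation, case/control sampling or population structure.
Allele-coding noise (swaps, strand flips, palindromic pairs) is injected by
`scramble_alleles()`, which returns a truth log for verification.

Defaults are chosen to resemble pQTL-instrumented analyses: exposure cohort
$10^5$, outcome cohort $3\times10^5$, `instrument_effect_sd = 0.15` (per-SNP
instrument F-statistics in the hundreds-to-thousands, as is typical for
cis-pQTLs), MAF in [0.05, 0.5].  Protein GWAS sample sizes are a package
choice, documented here, not a claim about any particular study.

What passing tests on this generator show — and do not show: they verify
the estimators, harmonization and multiplicity machinery against known
truth under an idealized sampling model with normal errors, exact SE
scaling and exchangeable SNPs.  They do not probe winner's-curse bias from
instrument selection in finite samples, sample overlap, allele-frequency
mismatch between cohorts, population stratification, or misspecified LD —
all real-data hazards outside this generator's scope.

## Reproducibility and numerics

Randomness flows through R's default Mersenne-Twister seeded once per
generator call from the config's mandatory `seed`; identical config + seed
gives byte-identical tables, and the pipeline writes an artifact manifest
of MD5 digests (manifest last) so end-to-end determinism is checkable with
`diff`.  Result tables are written at full double precision with a
fixed 5-decimal display copy of the OR/CI string (e.g.
`1.00142 [1.00068, 1.00216]`); the numeric columns remain authoritative.

The simulation studies shipped with the package use desk-scale problem
sizes chosen to make Monte-Carlo error small relative to the bands they
check: 1000 replicates of 30-instrument designs for IVW calibration and
coverage, 500 replicates for mediation recovery (30 + 30 instruments), and
500 replicates of a 200-exposure null panel (10 SNPs per exposure) for FDR
control.  `scripts/acceptance.R` recomputes all of these from scratch at
any seed.

## Known limitations

* No weighted-median, mode-based, MR-PRESSO or multivariable MR; MR-Egger
  and leave-one-out are the shipped sensitivity analyses.
* No Steiger direction filtering by default (extension point only).
* No proxy-SNP search; instruments missing from the outcome are dropped.
* LD must be supplied (or absent, treating SNPs as independent); the
  package never computes it from genotypes.
* The delta-method CI for the indirect effect is first-order; its coverage
  at moderate effect sizes is verified by simulation, but very weak steps
  (product of near-zero normals) are outside its comfort zone.
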