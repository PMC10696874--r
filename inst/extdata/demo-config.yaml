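# Demonstration pipeline config: synthetic panel screen + mediation chain +
# MR-PheWAS, all at desk scale.  A seed is mandatory.
seed: 42
fdr_threshold: 0.05
instruments:
  p_threshold: 5.0e-8
  clump_r2: 0.001
  palindromic_ambiguity: 0.08
panel:
  n_exposures: 60
  n_causal: 5
  effect: 0.1
  n_snps: 20
  n_exposure_cohort: 100000
  n_outcome_cohort: 300000
chain:
  theta_EM: 0.5
  theta_MO: 0.2
  theta_direct: 0.2
  n_snps: 30
phewas:
  n_phenotypes: 20
  n_affected: 3
  effect: 0.1
  n_snps: 25
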