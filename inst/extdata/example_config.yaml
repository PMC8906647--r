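# Example pipeline configuration for `targetmr run --config <this file>`.
# One LDL-like drug target instrumented from a single 10-variant locus,
# a two-trait metabolite panel and a CAD-like disease outcome.
n_individuals: 6000
seed: 5
fdr: 0.05
fractions:
  discovery: 0.5
  outcome: 0.45
  reference: 0.05
loci:
  - locus_id: L1
    chromosome: "5"
    start_bp: 900000
    end_bp: 1150000
    n_variants: 10
    maf_range: [0.1, 0.4]
    ld_decay_rho: 0.5
    causal_indices: [2, 6]
    causal_effects: [0.35, 0.3]
    exposure: LDL
model:
  exposure_names: [LDL]
  metabolite_loadings:
    - [0.6]
    - [0.0]
  metabolite_names: [m1, m2]
  metabolite_noise_sd: 0.7
  disease_log_odds:
    - [-0.3]
  disease_names: [CAD]
  disease_intercepts: [-2.0]
targets:
  - target_name: T1
    chromosome: "5"
    gene_start: 1000000
    gene_end: 1050000
    exposure_trait: LDL
    therapeutic_direction: -1
    window_kb: 100
    p_threshold: 1.0e-6
    r2_threshold: 0.1
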