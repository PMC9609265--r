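seed: 3
cohort:
  n_patients: 30
  n_taxa: {phylum: 3, class: 4, order: 5, family: 6, genus: 10, species: 3, asv: 30}
  n_genes: 10
min_reads: 3000
rarefaction: {depth: 1500, iterations: 10}
ranks: [genus]
community: {n_perm: 49}
selection: {R: 3, K: 5, alpha: 0.5, min_fraction: 0.25, q_threshold: 0.2, lambda_rule: min}
tdroc: {t_grid: [24], n_boot: 10, n_perm: 10, endpoint: RFS, max_block: 2}
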