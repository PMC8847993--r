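# Small end-to-end preset: simulated 100-gene screen with 5 designated
# synthetic-lethal genes, two knockout and two control replicates.
seed: 7
simulate:
  n_genes: 100
  clones_per_gene: [4, 10]
  n_nontargeting: 50
  depth: 2.0e5
  dispersion: 0.05
  n_sl_genes: 5
  fold_depletion: 10
  penetrance: 0.8
hitcall:
  pseudocount: 1
  normalization: cpm
  fold_threshold: 5
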