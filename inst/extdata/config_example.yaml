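# Example pipeline configuration: synthetic benchmark run.
# For real data replace `simulate:` with an `inputs:` block:
#   inputs:
#     fasta: transcripts.fa
#     regions: regions.tsv
#     expression: expression.tsv
#     gene_sets: rbp_targets.gmt
#     terms: go_slim.gmt
simulate:
  n_genes: 3000
  regulon_size: 400
  delta: -2
  sigma: 0.25
  plant_rate: 0.9
  background_rate: 0.05
tau: 1.0
alpha: 0.01
forest:
  ntree_grid: [250, 500, 1000]
  n_folds: 10
seed: 1
outdir: run1
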