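# Fixed validation scenario: 5,000 cells x 2,000 genes, 5 planted modules of
# 60 genes, 3 cell types (60/30/10), 3 batches, NB counts, seed 0.
n_cells: 5000
n_genes: 2000
module_sizes: [60, 60, 60, 60, 60]
type_props:
  A: 0.6
  B: 0.3
  C: 0.1
n_batches: 3
loading: 3.0
activity_sd: 1.5
batch_sd: 0.1
libsize_sd: 0.3
nb_dispersion: 5.0
sparsity_range: [0.02, 0.95]
module_sparsity_range: [0.10, 0.95]
seed: 0
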