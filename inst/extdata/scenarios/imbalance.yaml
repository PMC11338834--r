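# Imbalance stress scenario: a rare cell type (5% of cells) carries one
# exclusive module; the remaining modules are shared or common-type
# programs. Used to compare the decorrelated pipeline against the raw
# correlation baseline.
n_cells: 2500
n_genes: 800
module_sizes: [40, 40, 40, 40]
type_props:
  A: 0.80
  B: 0.15
  C: 0.05
activity:
  A: [1, 1, 0, 0]
  B: [1, 0, 1, 0]
  C: [1, 0, 0, 1]
n_batches: 4
loading: 3.0
activity_sd: 1.5
batch_sd: 0.1
libsize_sd: 0.3
nb_dispersion: 5.0
sparsity_range: [0.02, 0.95]
module_sparsity_range: [0.10, 0.95]
seed: 0
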