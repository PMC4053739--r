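# Example discovery configuration. Any subset of keys may be given;
# omitted keys take the documented defaults (see ?load_config).
q: 7              # seed word length
k: 200            # expression-space neighborhood size
n_shuffles: 10    # shuffle rounds for the empirical FDR
seed_fdr: 0.001   # seed selection threshold (FDR strictly below)
alpha: 0.75       # density-profile correlation gate for generalization
gamma: 0.75       # density-profile correlation gate for redundancy
max_len: 9        # maximum motif length after elongation (<= 15)
min_overlap: 4    # ungapped overlap gate for redundancy
criterion: mutual_information   # or hypergeometric
metric: euclidean               # or pearson
strands: both                   # or forward (e.g. 3'UTR analyses)
heatmap_bins: 25
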