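# Small labeled dataset with no planted effects, for plan/structure tests.
null_sim <- function(n_cells = 3, n_genes = 10, seed = 1)
  generate_counts(synth_config(n_cells_per_group = n_cells,
                               n_genes = n_genes, seed = seed,
                               planted = default_planted()[0, ]))
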