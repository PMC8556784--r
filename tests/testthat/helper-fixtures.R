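# Fixture builders shared across test files.

rand_binary <- function(n, m, density = 0.3, seed = 1, prefix = c("r", "c")) {
  set.seed(seed)
  labeled_matrix(matrix(as.double(runif(n * m) < density), n, m),
                 row_labels = paste0(prefix[1], seq_len(n)),
                 col_labels = paste0(prefix[2], seq_len(m)))
}

# A tiny end-to-end triple: 40 drugs in 4 groups, quick to push through the
# whole pipeline.
tiny_triple <- function(seed = 1, ...) {
  synth_generate(synth_config(
    n_drugs = 40, n_diseases = 30, n_features = 24, n_side_effects = 20,
    n_drug_groups = 4, n_disease_groups = 4, p_assoc_in_group = 0.5,
    p_assoc_background = 0.02, p_feature_in_group = 0.35,
    p_side_in_group = 0.3, feature_flip_noise = 0.02,
    overlap_fraction = 0.3, seed = seed, ...))
}

fast_encoder <- function(input_dim, seed = 1, ...) {
  encoder_config(input_dim, hidden_dims = 16L, code_dim = 8L,
                 dropout_rate = 0.2, batch_size = 8L, max_epochs = 30L,
                 patience = 10L, seed = seed, ...)
}
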