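# Shared micro-scale fixtures: everything is generated in code at test time.

# Tiny schema/model pair used by mechanism tests (not by the acceptance
# criteria, which run the published-scale configuration).
micro_schema <- function() pair_schema(12L, 20L)

micro_spec <- function(...) {
  model_spec(input_len = 32L, n_kernels = 8L, kernel_size = 4L,
             rnn_units = 4L, dense_hidden_units = 4L, ...)
}

micro_dataset <- function(n = 60L, seed = 1L, negative_mode = "shuffle_mirna") {
  generate_dataset(synth_config(n_pos = n, n_neg = n, site_len = 20L,
                                mirna_len_range = c(12L, 12L), n_mirnas = 6L,
                                negative_mode = negative_mode,
                                rng_seed = seed))
}

# Independent reversal oracle: character-by-character from the end.
reverse_oracle <- function(s) {
  out <- character(nchar(s))
  for (k in seq_len(nchar(s))) out[k] <- substr(s, nchar(s) - k + 1L, nchar(s) - k + 1L)
  paste(out, collapse = "")
}

random_rna <- function(len) {
  paste(sample(c("A", "U", "G", "C"), len, replace = TRUE), collapse = "")
}
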