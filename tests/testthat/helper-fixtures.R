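# Shared fixtures: everything is generated in code at test time.

random_dna_string <- function(n, gc = 0.5) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# A deterministic toy genome with two chromosomes.
toy_genome <- function(sizes = c(chrA = 10000L, chrB = 3000L), seed = 99L) {
  set.seed(seed)
  dna <- Biostrings::DNAStringSet(vapply(sizes, random_dna_string, ""))
  names(dna) <- names(sizes)
  dna
}

# Write an activity-matrix TSV from a plain value matrix.
write_toy_matrix <- function(values, path,
                             ids = sprintf("chr1:%d-%d",
                                           1000L * seq_len(nrow(values)),
                                           1000L * seq_len(nrow(values)) + 400L),
                             samples = sprintf("s%d", seq_len(ncol(values)))) {
  header <- paste(c("region", samples), collapse = "\t")
  rows <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(ids[i], format(values[i, ], trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  path
}

# Small labeled set with a single strong planted consensus separating the
# classes; linearly separable by construction.
toy_motif_set <- function(n_pos = 40L, n_neg = 40L, length = 60L,
                          motif = "TGACGTCATT", seed = 1L) {
  set.seed(seed)
  pos <- vapply(seq_len(n_pos), function(i) {
    s <- random_dna_string(length)
    at <- sample.int(length - nchar(motif) + 1L, 1L)
    paste0(substr(s, 1L, at - 1L), motif,
           substr(s, at + nchar(motif), length))
  }, "")
  neg <- vapply(seq_len(n_neg), function(i) random_dna_string(length), "")
  sequence_set(id = c(sprintf("p%03d", seq_len(n_pos)),
                      sprintf("n%03d", seq_len(n_neg))),
               seq = c(pos, neg),
               label = c(rep(1L, n_pos), rep(0L, n_neg)))
}

tiny_net_cfg <- function(input_length = 60L) {
  network_config(filter_number = 4L, filter_length = 7L, pool_size = 3L,
                 gru_units = 4L, dense_units = 8L, dropout_rate = 0.1,
                 input_length = input_length)
}

fast_obj_cfg <- function(epochs = 5L, seed = 1L) {
  objective_config(max_epochs = epochs, seed = seed, batch_size = 32L)
}
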