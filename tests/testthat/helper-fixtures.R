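# Shared fixture builders; everything is generated in code at test time.

random_residues <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

random_records <- function(n, len_range = c(50L, 80L), seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    protein_record(sprintf("r%03d", i),
                   random_residues(sample(len_range[1]:len_range[2], 1L)))
  })
}

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(records, function(r) {
    c(paste0(">", r$id), r$residues)
  })), path)
  path
}

write_tmp_pairs <- function(pairs, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(pairs[, c("id1", "id2", "score")], path, sep = "\t",
                     col.names = FALSE)
  path
}

small_encoder <- function(in_dim = 7L, seed = 1L, merge = "concatenate",
                          num_units = 2L, hidden = 6L, d = 3L, n = 3L) {
  cfg <- rcnn_config(num_units = num_units, d = d, hidden = hidden, n = n,
                     merge = merge)
  init_encoder_state(cfg, in_dim = in_dim, seed = seed)
}

# scalar-loop R oracle for the GRU gate equations (independent of the
# compiled implementation)
gru_oracle <- function(V, p, h0 = numeric(p$hidden)) {
  sig <- function(x) 1 / (1 + exp(-x))
  L <- nrow(V)
  H <- matrix(0, L, p$hidden)
  h <- h0
  for (t in seq_len(L)) {
    v <- V[t, ]
    z <- sig(as.numeric(v %*% p$Mz + h %*% p$Nz) + p$bz)
    r <- sig(as.numeric(v %*% p$Mr + h %*% p$Nr) + p$br)
    cand <- tanh(as.numeric(v %*% p$Ms) + r * as.numeric(h %*% p$Ns) + p$bs)
    h <- z * cand + (1 - z) * h
    H[t, ] <- h
  }
  H
}
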