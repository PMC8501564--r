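#' Embedding tables for amino acids
#'
#' An embedding table maps every symbol of the 20-letter alphabet to a fixed
#' length numeric vector. Three kinds exist: `onehot` (20 orthogonal basis
#' vectors), `eh` (the 7-dimensional physicochemical class indicator, from
#' the conjoint-triad grouping of residues by dipole and side-chain volume)
#' and `skipgram` (vectors learned from co-occurrence within protein
#' sequences).
#'
#' @name embedding_tables
NULL

new_embedding_table <- function(kind, vectors) {
  stopifnot(is.matrix(vectors), nrow(vectors) == 20L)
  rownames(vectors) <- AA_ALPHABET
  structure(list(kind = kind, dim = ncol(vectors), vectors = vectors),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> kind=%s dim=%d (20 symbols)\n", x$kind, x$dim))
  invisible(x)
}

#' @describeIn embedding_tables one-hot table: each residue is a distinct
#'   20-dimensional standard basis vector, in alphabetical order.
#' @export
onehot_table <- function() {
  new_embedding_table("onehot", diag(20))
}

#' @describeIn embedding_tables 7-class physicochemical indicator table:
#'   residues in the same conjoint-triad class share the same 7-dimensional
#'   indicator vector.
#' @export
eh_table <- function() {
  cl <- .residue_classes(paste(AA_ALPHABET, collapse = ""))
  v <- matrix(0, 20L, 7L)
  v[cbind(seq_len(20L), cl)] <- 1
  new_embedding_table("eh", v)
}

#' Skip-gram training configuration
#'
#' @param embed_dim dimension of the learned vectors (default 20, matching
#'   the one-hot dimension so downstream convolutions are comparable).
#' @param context_half_len half window length C; the context window covers
#'   positions t-C..t+C, skipping the center (default 3).
#' @param negatives number of negative samples m per positive (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param learning_rate initial SGD learning rate, decayed linearly
#'   (default 0.025).
#' @param seed integer seed governing initialization and negative sampling.
#' @return a list of class `skipgram_config`.
#' @export
skipgram_config <- function(embed_dim = 20L, context_half_len = 3L,
                            negatives = 5L, epochs = 5L,
                            learning_rate = 0.025, seed = 1L) {
  stopifnot(embed_dim >= 1, context_half_len >= 1, negatives >= 1,
            epochs >= 0, learning_rate > 0)
  structure(list(embed_dim = as.integer(embed_dim),
                 context_half_len = as.integer(context_half_len),
                 negatives = as.integer(negatives),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "skipgram_config")
}

# corpus records -> list of 0-based integer token vectors (non-standard
# residues dropped: they have no vocabulary slot)
.tokenize_corpus <- function(corpus) {
  lapply(corpus, function(r) {
    idx <- .residue_indices(r$residues)
    as.integer(idx[!is.na(idx)] - 1L)
  })
}

#' Train skip-gram embeddings on a protein corpus
#'
#' Each protein sequence is one sentence; for every residue the surrounding
#' window of half length C provides positive center-context pairs, contrasted
#' against m negatives sampled uniformly from the alphabet. The negative
#' sampling objective is minimized by plain SGD with a linearly decaying
#' learning rate. Deterministic given `config$seed`.
#'
#' @param corpus non-empty list of [protein_record()] objects.
#' @param config a [skipgram_config()].
#' @return an `embedding_table` of kind `skipgram` (the input vectors).
#' @export
train_skipgram <- function(corpus, config = skipgram_config()) {
  if (length(corpus) == 0L) stop("skip-gram corpus is empty")
  tokens <- .tokenize_corpus(corpus)
  win <- 2L * config$context_half_len + 1L
  if (any(lengths(tokens) < win)) {
    stop("all corpus sequences must be at least one context window (",
         win, " residues) long")
  }
  n_positions <- sum(vapply(tokens, function(tk) {
    L <- length(tk)
    sum(pmin(seq_len(L) - 1L + config$context_half_len, L - 1L) -
        pmax(seq_len(L) - 1L - config$context_half_len, 0L))
  }, numeric(1)))
  res <- withr_seed(config$seed, {
    d <- config$embed_dim
    Win <- matrix(runif(20L * d, -0.5 / d, 0.5 / d), 20L, d)
    Wout <- matrix(0, 20L, d)
    if (config$epochs == 0L) {
      list(Win = Win, Wout = Wout)
    } else {
      negs <- sample.int(20L, config$epochs * n_positions * config$negatives,
                         replace = TRUE) - 1L
      skipgram_train_cpp(tokens, Win, Wout, config$context_half_len,
                         config$negatives, config$epochs,
                         config$learning_rate, negs)
    }
  })
  new_embedding_table("skipgram", res$Win)
}

#' Embed a padded protein sequence
#'
#' Row t of the result is the embedding vector of residue t; rows beyond the
#' true sequence length (right padding) and rows of non-standard residues
#' are exactly zero.
#'
#' @param record a [protein_record()].
#' @param table an `embedding_table`.
#' @param max_len padded length (the full-scale setting pads to 2000).
#' @return an `embedded_sequence`: list with `matrix` (`max_len` x `dim`)
#'   and `true_length`.
#' @export
embed_sequence <- function(record, table, max_len) {
  if (record$length > max_len) {
    stop("sequence '", record$id, "' is longer (", record$length,
         ") than max_len (", max_len, "); length-filter the records first")
  }
  m <- matrix(0, max_len, table$dim)
  idx <- .residue_indices(record$residues)
  known <- which(!is.na(idx))
  m[known, ] <- table$vectors[idx[known], , drop = FALSE]
  structure(list(matrix = m, true_length = record$length),
            class = "embedded_sequence")
}

#' Serialize an embedding table to a plain-text file
#'
#' Two-column format: symbol, then whitespace-separated vector entries at 9
#' significant digits (round-trip exact at that precision).
#'
#' @param table an `embedding_table`.
#' @param path output path.
#' @export
write_embedding_table <- function(table, path) {
  lines <- c(paste0("#kind ", table$kind),
             vapply(seq_len(20L), function(i) {
               paste(AA_ALPHABET[i],
                     paste(formatC(table$vectors[i, ], format = "g", digits = 9),
                           collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Load an embedding table written by [write_embedding_table()]
#' @param path path to the text file.
#' @return an `embedding_table`.
#' @export
read_embedding_table <- function(path) {
  if (!file.exists(path)) stop("embedding table not found: ", path)
  lines <- readLines(path)
  kind <- sub("^#kind ", "", lines[[1L]])
  body <- lines[-1L]
  parts <- strsplit(trimws(body), "\\s+")
  syms <- vapply(parts, `[[`, character(1), 1L)
  if (!setequal(syms, AA_ALPHABET)) {
    stop("embedding table must cover exactly the 20 standard residues")
  }
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                   numeric(length(parts[[1L]]) - 1L)))
  rownames(vecs) <- syms
  new_embedding_table(kind, vecs[AA_ALPHABET, , drop = FALSE])
}
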