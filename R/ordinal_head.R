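#' Uniform interval partition of the confidence-score range
#'
#' The range `(cs_min, cs_max)` is split into K equal sub-intervals. The
#' first sub-interval is open at `cs_min`; every sub-interval k >= 2 is
#' `[cs_min + (k-1) w, cs_min + k w)` with width `w = (cs_max - cs_min) / K`.
#' With the default `(0, 1)` and K = 20 this reproduces the sub-intervals
#' (0, 0.05), [0.05, 0.1), ..., [0.95, 1).
#'
#' @param cs_min,cs_max open range bounds of the confidence score.
#' @param K number of sub-intervals (>= 2).
#' @return a list of class `interval_partition` with a `width` field.
#' @export
interval_partition <- function(cs_min = 0, cs_max = 1, K = 20L) {
  stopifnot(cs_min < cs_max, K >= 2)
  structure(list(cs_min = cs_min, cs_max = cs_max, K = as.integer(K),
                 width = (cs_max - cs_min) / K),
            class = "interval_partition")
}

#' Ordinal label of a confidence score
#'
#' Returns the 1-based sub-interval index containing each score. Scores on a
#' boundary belong to the right (higher) sub-interval. Scores outside the
#' open range are an error.
#'
#' @param score numeric vector of scores, all in `(cs_min, cs_max)`.
#' @param p an [interval_partition()].
#' @return integer labels in `1..K`.
#' @export
label_of_score <- function(score, p) {
  if (any(score <= p$cs_min | score >= p$cs_max)) {
    stop("score outside the open interval (", p$cs_min, ", ", p$cs_max, ")")
  }
  # multiply-then-floor is robust to the float boundaries of width = range/K
  k <- floor((score - p$cs_min) / (p$cs_max - p$cs_min) * p$K) + 1L
  as.integer(pmin(k, p$K))
}

#' Attach ordinal labels to a scored-pair table
#'
#' @param pairs pair table from [read_pair_table()] or [gen_scored_pairs()].
#' @param p an [interval_partition()].
#' @param drop_outside drop (with a message) pairs whose score falls outside
#'   the open partition range instead of erroring.
#' @return the table with an integer `label` column.
#' @export
label_pairs <- function(pairs, p, drop_outside = FALSE) {
  if (drop_outside) {
    keep <- pairs$score > p$cs_min & pairs$score < p$cs_max
    if (any(!keep)) {
      message(sum(!keep), " pair(s) dropped: score outside the partition range (",
              p$cs_min, ", ", p$cs_max, ")")
    }
    pairs <- pairs[keep, , drop = FALSE]
  }
  pairs$label <- label_of_score(pairs$score, p)
  pairs
}

#' Relabel the training set for the k-th sub-problem
#'
#' The k-th binary sub-problem asks whether the ordinal label exceeds k:
#' positives are the pairs with `label > k` (relabelled +1), negatives those
#' with `label <= k` (relabelled -1). Together they partition the input.
#'
#' @param pairs labeled pair table.
#' @param k sub-problem index in `1..K-1`.
#' @return list with elements `positives` and `negatives`, each carrying a
#'   `y` column of +1 / -1.
#' @export
relabel_for_k <- function(pairs, k) {
  if (is.null(pairs$label) || anyNA(pairs$label)) {
    stop("pairs must carry ordinal labels; run label_pairs() first")
  }
  pos <- pairs[pairs$label > k, , drop = FALSE]
  neg <- pairs[pairs$label <= k, , drop = FALSE]
  if (nrow(pos)) pos$y <- 1L
  else pos$y <- integer(0)
  if (nrow(neg)) neg$y <- -1L
  else neg$y <- integer(0)
  list(positives = pos, negatives = neg)
}

# ---- MLP sub-classifier ----------------------------------------------------

new_mlp_head <- function(in_dim, hidden, out_dim, slope) {
  rnd <- function(nr, nc) matrix(runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
  list(W1 = rnd(in_dim, hidden), b1 = numeric(hidden),
       W2 = rnd(hidden, out_dim), b2 = numeric(out_dim), slope = slope)
}

# batched forward through a leaky-ReLU MLP; returns raw output + cache
mlp_forward <- function(X, head) {
  Z1 <- X %*% head$W1 + matrix(head$b1, nrow(X), length(head$b1), byrow = TRUE)
  A <- ifelse(Z1 > 0, Z1, head$slope * Z1)
  S <- A %*% head$W2 + matrix(head$b2, nrow(X), length(head$b2), byrow = TRUE)
  list(S = S, A = A, Z1 = Z1, X = X)
}

mlp_backward <- function(cache, head, dS) {
  dA <- dS %*% t(head$W2)
  dZ1 <- dA * ifelse(cache$Z1 > 0, 1, head$slope)
  list(grads = list(W1 = crossprod(cache$X, dZ1), b1 = colSums(dZ1),
                    W2 = crossprod(cache$A, dS), b2 = colSums(dS)),
       dX = tcrossprod(dZ1, head$W1))
}

softmax2 <- function(S) {
  m <- pmax(S[, 1L], S[, 2L])
  e1 <- exp(S[, 1L] - m); e2 <- exp(S[, 2L] - m)
  cbind(e1, e2) / (e1 + e2)
}

#' Forward pass of one binary sub-classifier
#'
#' The sub-classifier is a multi-layer perceptron with Leaky ReLU activation
#' and a 2-unit output normalized by a two-term softmax; `s1` is the
#' confidence for the positive class (`label > k`), `s2` for the negative.
#'
#' @param x fused pair vector (or a matrix of rows).
#' @param head one sub-classifier parameter block (from [ordinal_model()]).
#' @return a vector `c(s1, s2)` (or a 2-column matrix), rows summing to 1.
#' @export
subclassifier_forward <- function(x, head) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != nrow(head$W1)) {
    stop("input dimension ", ncol(X), " does not match sub-classifier (",
         nrow(head$W1), ")")
  }
  P <- softmax2(mlp_forward(X, head)$S)
  colnames(P) <- c("s1", "s2")
  if (is.matrix(x)) P else P[1L, ]
}

#' Binary decision of a sub-classifier
#'
#' +1 iff `s1 > s2`, otherwise -1 (ties fall to the negative class).
#'
#' @param s1,s2 softmax outputs (vectors allowed).
#' @return +1 / -1 integer vector.
#' @export
decide_fk <- function(s1, s2) {
  ifelse(s1 > s2, 1L, -1L)
}

#' Aggregate K-1 binary decisions into a rank
#'
#' `rank = 1 + #positive decisions`. The sum form tolerates inconsistent
#' sub-classifier patterns; no monotonicity is required or repaired.
#'
#' @param decisions vector (or matrix with one row per item) of +1 / -1.
#' @param K number of sub-intervals; decisions must have length `K - 1`.
#' @return integer rank(s) in `1..K`.
#' @export
aggregate_rank <- function(decisions, K = NULL) {
  if (is.matrix(decisions)) {
    if (!is.null(K) && ncol(decisions) != K - 1L) {
      stop("expected ", K - 1L, " decisions per item, got ", ncol(decisions))
    }
    return(as.integer(1L + rowSums(decisions > 0)))
  }
  if (!is.null(K) && length(decisions) != K - 1L) {
    stop("expected ", K - 1L, " decisions, got ", length(decisions))
  }
  as.integer(1L + sum(decisions > 0))
}

#' Decode a rank into a confidence score
#'
#' `mode = "mid"` takes the middle value of the rank's sub-interval
#' (`cs_min + (r - 1) w + w/2`); `"left"` and `"right"` take the endpoints
#' (`cs_min + (r - 1) w` and `cs_min + r w`), which for the `(0, 1)`, K = 20
#' partition are `0.05 (r - 1)` and `0.05 r`.
#'
#' @param r integer rank(s) in `1..K`.
#' @param p an [interval_partition()].
#' @param mode `"mid"`, `"left"` or `"right"`.
#' @return numeric score(s).
#' @export
score_from_rank <- function(r, p, mode = c("mid", "left", "right")) {
  mode <- match.arg(mode)
  if (any(r < 1L | r > p$K)) stop("rank outside 1..", p$K)
  base <- p$cs_min + p$width * (r - 1)
  switch(mode,
         mid = base + p$width / 2,
         left = base,
         right = base + p$width)
}

#' Threshold a confidence score into a PPI call
#'
#' @param score predicted confidence score(s).
#' @param theta threshold; the call is positive iff `score > theta`
#'   (strictly).
#' @return logical vector.
#' @export
call_ppi <- function(score, theta) {
  score > theta
}

#' Cross-entropy loss of a sub-classifier on a relabelled batch
#'
#' Mean negative log-probability assigned to the true class, where the true
#' class indicator puts +1 items on `s1` and -1 items on `s2`.
#'
#' @param X matrix of fused pair vectors (rows).
#' @param y vector of +1 / -1 labels.
#' @param head one sub-classifier parameter block.
#' @return a single numeric loss.
#' @export
cross_entropy_loss <- function(X, y, head) {
  stopifnot(nrow(X) == length(y), nrow(X) > 0)
  S <- mlp_forward(X, head)$S
  # log-probabilities straight from the logits (log-sum-exp), stable when a
  # softmax output underflows to zero
  m <- pmax(S[, 1L], S[, 2L])
  lse <- m + log(exp(S[, 1L] - m) + exp(S[, 2L] - m))
  s_true <- ifelse(y > 0, S[, 1L], S[, 2L])
  -mean(s_true - lse)
}

# ---- models ---------------------------------------------------------------

#' Construct an untrained ordinal PPI model
#'
#' Bundles the interval partition, the shared siamese encoder and the K-1
#' MLP sub-classifiers. Both encoder arms reference the same parameter
#' bundle by construction.
#'
#' @param partition an [interval_partition()].
#' @param encoder_config an [rcnn_config()].
#' @param table the residue [embedding_tables] used to embed sequences.
#' @param max_len padded sequence length fed to the encoder (2000 at full
#'   scale).
#' @param head_hidden hidden units of each sub-classifier MLP.
#' @param leaky_slope Leaky ReLU negative-side slope.
#' @param seed integer seed for all weight initialization.
#' @return a list of class `ordinal_model`.
#' @export
ordinal_model <- function(partition, encoder_config, table, max_len,
                          head_hidden = 32L, leaky_slope = 0.01, seed = 1L) {
  encoder <- init_encoder_state(encoder_config, in_dim = table$dim, seed = seed)
  heads <- withr_seed(seed + 1L, {
    lapply(seq_len(partition$K - 1L), function(k) {
      new_mlp_head(encoder_config$hidden, head_hidden, 2L, leaky_slope)
    })
  })
  structure(list(partition = partition, config = encoder_config,
                 encoder = encoder, heads = heads, table = table,
                 max_len = as.integer(max_len),
                 head_hidden = as.integer(head_hidden),
                 leaky_slope = leaky_slope),
            class = "ordinal_model")
}

#' @export
print.ordinal_model <- function(x, ...) {
  cat(sprintf("<ordinal_model> K=%d (%d sub-classifiers), %s embedding dim %d, max_len=%d\n",
              x$partition$K, length(x$heads), x$table$kind, x$table$dim, x$max_len))
  print(x$encoder)
  invisible(x)
}

#' Construct an untrained scalar-regression ablation model
#'
#' Same shared encoder and pair fusion as [ordinal_model()], but the head is
#' a single MLP with scalar output trained by squared error on the raw
#' confidence score (the regression ablation of the ordinal design).
#'
#' @inheritParams ordinal_model
#' @return a list of class `regression_model`.
#' @export
regression_model <- function(partition, encoder_config, table, max_len,
                             head_hidden = 32L, leaky_slope = 0.01, seed = 1L) {
  encoder <- init_encoder_state(encoder_config, in_dim = table$dim, seed = seed)
  head <- withr_seed(seed + 1L, {
    new_mlp_head(encoder_config$hidden, head_hidden, 1L, leaky_slope)
  })
  structure(list(partition = partition, config = encoder_config,
                 encoder = encoder, head = head, table = table,
                 max_len = as.integer(max_len),
                 head_hidden = as.integer(head_hidden),
                 leaky_slope = leaky_slope),
            class = "regression_model")
}

#' Scalar regression head forward pass
#'
#' @param x fused pair vector (or matrix of rows).
#' @param head the regression head parameter block.
#' @param p an [interval_partition()]; the output is clamped to lie strictly
#'   inside `(cs_min, cs_max)`.
#' @return predicted confidence score(s).
#' @export
regression_head_forward <- function(x, head, p) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != nrow(head$W1)) {
    stop("input dimension ", ncol(X), " does not match regression head (",
         nrow(head$W1), ")")
  }
  y <- as.numeric(mlp_forward(X, head)$S)
  eps <- 1e-9 * (p$cs_max - p$cs_min)
  pmin(pmax(y, p$cs_min + eps), p$cs_max - eps)
}

# encode all unique sequences referenced by a pair table; returns the fused
# matrix plus the per-sequence embedding matrix
encode_pair_table <- function(model, pairs, records) {
  recs <- stats::setNames(records, vapply(records, `[[`, "", "id"))
  ids <- unique(c(pairs$id1, pairs$id2))
  missing <- setdiff(ids, names(recs))
  if (length(missing)) {
    stop("pair table references unknown sequence id(s): ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  E <- t(vapply(ids, function(id) {
    encode_sequence(embed_sequence(recs[[id]], model$table, model$max_len),
                    model$encoder)
  }, numeric(model$config$hidden)))
  i1 <- match(pairs$id1, ids)
  i2 <- match(pairs$id2, ids)
  list(X = E[i1, , drop = FALSE] * E[i2, , drop = FALSE], E = E, ids = ids)
}

#' Predict ranks, confidence scores and PPI calls for protein pairs
#'
#' Encodes every distinct sequence once through the shared encoder, fuses
#' each pair by element-wise multiplication, runs the K-1 sub-classifiers,
#' aggregates their decisions into a rank and decodes the rank into a
#' confidence score. For a `regression_model` the head predicts the score
#' directly (rank is then the score's sub-interval).
#'
#' @param model a trained [ordinal_model()] or [regression_model()].
#' @param pairs pair table with `id1`, `id2` columns.
#' @param records list of [protein_record()] covering all referenced ids.
#' @param score_mode rank decoding mode, see [score_from_rank()] (ordinal
#'   model only; the sub-interval middle value is the default).
#' @param theta optional threshold; when given, a logical `call` column
#'   (`score > theta`) is added.
#' @return a `data.frame` with columns `id1`, `id2`, `rank`, `score` (and
#'   `call`); the K-1 decision matrix is attached as attribute `decisions`
#'   for ordinal models.
#' @export
predict_pairs <- function(model, pairs, records,
                          score_mode = c("mid", "left", "right"),
                          theta = NULL) {
  score_mode <- match.arg(score_mode)
  enc <- encode_pair_table(model, pairs, records)
  if (inherits(model, "regression_model")) {
    score <- regression_head_forward(enc$X, model$head, model$partition)
    rank <- label_of_score(score, model$partition)
    decisions <- NULL
  } else {
    decisions <- vapply(model$heads, function(head) {
      P <- subclassifier_forward(enc$X, head)
      decide_fk(P[, 1L], P[, 2L])
    }, integer(nrow(enc$X)))
    if (!is.matrix(decisions)) decisions <- matrix(decisions, nrow = nrow(enc$X))
    rank <- aggregate_rank(decisions, K = model$partition$K)
    score <- score_from_rank(rank, model$partition, score_mode)
  }
  out <- data.frame(id1 = pairs$id1, id2 = pairs$id2, rank = rank,
                    score = score, stringsAsFactors = FALSE)
  if (!is.null(theta)) out$call <- call_ppi(score, theta)
  attr(out, "decisions") <- decisions
  out
}
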