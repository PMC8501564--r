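#' RCNN encoder configuration
#'
#' The encoder stacks `num_units` RCNN units (convolution of kernel width
#' `d`, n-max pooling of width `n`, bidirectional GRU with hidden dimension
#' `hidden` and a `merge` operator), followed by one final convolution and
#' global average pooling. The full-scale defaults follow the reference
#' setting (5 units, d = 3, 3-max pooling, hidden 50, concatenate merge).
#'
#' @param num_units number of stacked RCNN units.
#' @param d convolution kernel width.
#' @param hidden GRU hidden dimension d' (also the conv output channels).
#' @param n pooling width.
#' @param merge `"concatenate"` (append the layer input to the two GRU
#'   directions: output dim 3 d') or `"residual"` (add it: output dim 2 d').
#' @return a list of class `rcnn_config`.
#' @export
rcnn_config <- function(num_units = 5L, d = 3L, hidden = 50L, n = 3L,
                        merge = c("concatenate", "residual")) {
  merge <- match.arg(merge)
  stopifnot(num_units >= 1, d >= 1, hidden >= 1, n >= 1)
  structure(list(num_units = as.integer(num_units), d = as.integer(d),
                 hidden = as.integer(hidden), n = as.integer(n),
                 merge = merge),
            class = "rcnn_config")
}

merge_out_dim <- function(in_dim, hidden, merge) {
  if (merge == "concatenate") 2L * hidden + in_dim else 2L * hidden
}

#' Convolution layer parameters
#'
#' The kernel is a width-`d`, `in_dim`-channel, `out_dim`-output-channel 1-D
#' convolution stored as a `(d * in_dim) x out_dim` matrix `W` whose row
#' blocks correspond to window offsets 0..d-1, plus a bias vector `b`.
#'
#' @param d kernel width.
#' @param in_dim,out_dim input and output channel counts.
#' @param W,b kernel matrix and bias; random (uniform in +/- 1/sqrt(d *
#'   in_dim)) and zero respectively when omitted.
#' @return a list of class `conv_params`.
#' @export
conv_params <- function(d, in_dim, out_dim, W = NULL, b = NULL) {
  fan_in <- d * in_dim
  if (is.null(W)) W <- matrix(runif(fan_in * out_dim, -1, 1) / sqrt(fan_in),
                              fan_in, out_dim)
  if (is.null(b)) b <- numeric(out_dim)
  stopifnot(nrow(W) == fan_in, ncol(W) == out_dim, length(b) == out_dim)
  structure(list(d = as.integer(d), in_dim = as.integer(in_dim),
                 out_dim = as.integer(out_dim), W = W, b = as.numeric(b)),
            class = "conv_params")
}

#' GRU parameters for one direction
#'
#' Input-to-hidden matrices `Mz`, `Ms`, `Mr` (`in_dim x hidden`),
#' hidden-to-hidden matrices `Nz`, `Ns`, `Nr` (`hidden x hidden`) and biases
#' `bz`, `bs`, `br`, for the update gate (z), candidate state (s) and reset
#' gate (r).
#'
#' @param in_dim,hidden input and hidden dimensions.
#' @param ... optional named tensors overriding the random initialization
#'   (uniform in +/- 1/sqrt(fan-in), zero biases).
#' @return a list of class `gru_params`.
#' @export
gru_params <- function(in_dim, hidden, ...) {
  rnd <- function(nr, nc) matrix(runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
  p <- list(Mz = rnd(in_dim, hidden), Ms = rnd(in_dim, hidden),
            Mr = rnd(in_dim, hidden), Nz = rnd(hidden, hidden),
            Ns = rnd(hidden, hidden), Nr = rnd(hidden, hidden),
            bz = numeric(hidden), bs = numeric(hidden), br = numeric(hidden))
  over <- list(...)
  p[names(over)] <- over
  for (nm in c("Mz", "Ms", "Mr")) stopifnot(dim(p[[nm]]) == c(in_dim, hidden))
  for (nm in c("Nz", "Ns", "Nr")) stopifnot(dim(p[[nm]]) == c(hidden, hidden))
  for (nm in c("bz", "bs", "br")) stopifnot(length(p[[nm]]) == hidden)
  p$in_dim <- as.integer(in_dim)
  p$hidden <- as.integer(hidden)
  structure(p, class = "gru_params")
}

#' Initialize the shared encoder parameter bundle
#'
#' One parameter bundle serves both arms of the pair encoder (the siamese
#' arms reference the identical object, so they cannot diverge).
#'
#' @param config an [rcnn_config()].
#' @param in_dim dimension of the residue embedding feeding the first unit.
#' @param seed integer seed for the uniform +/- 1/sqrt(fan-in) initialization.
#' @return a list of class `encoder_state` with per-unit `conv`, `fwd`,
#'   `bwd` parameters and a `final_conv`.
#' @export
init_encoder_state <- function(config, in_dim, seed = 1L) {
  withr_seed(seed, {
    h <- config$hidden
    units <- vector("list", config$num_units)
    din <- as.integer(in_dim)
    for (u in seq_len(config$num_units)) {
      units[[u]] <- list(conv = conv_params(config$d, din, h),
                         fwd = gru_params(h, h), bwd = gru_params(h, h))
      din <- merge_out_dim(h, h, config$merge)
    }
    structure(list(config = config, in_dim = as.integer(in_dim),
                   units = units,
                   final_conv = conv_params(config$d, din, h)),
              class = "encoder_state")
  })
}

#' @export
print.encoder_state <- function(x, ...) {
  cat(sprintf("<encoder_state> %d units, d=%d, hidden=%d, n=%d, merge=%s, in_dim=%d\n",
              x$config$num_units, x$config$d, x$config$hidden, x$config$n,
              x$config$merge, x$in_dim))
  invisible(x)
}

.conv_windows <- function(X, d) {
  L <- nrow(X)
  do.call(cbind, lapply(seq_len(d), function(j) X[j:(L - d + j), , drop = FALSE]))
}

#' Affine convolution over sliding windows
#'
#' Position t of the output is `W' v_{t:t+d-1} + b` (no nonlinearity); the
#' output length is `l - d + 1` (no implicit padding).
#'
#' @param X input sequence, a `length x in_dim` matrix.
#' @param params a [conv_params()].
#' @param stage label used in error messages (which stage underflowed).
#' @return a `(l - d + 1) x out_dim` matrix.
#' @export
conv_layer <- function(X, params, stage = "convolution") {
  if (nrow(X) < params$d) {
    stop(stage, ": input length ", nrow(X), " is shorter than kernel width ",
         params$d)
  }
  if (ncol(X) != params$in_dim) {
    stop(stage, ": input dim ", ncol(X), " does not match kernel in_dim ",
         params$in_dim)
  }
  Xw <- .conv_windows(X, params$d)
  H <- Xw %*% params$W
  H + matrix(params$b, nrow(H), params$out_dim, byrow = TRUE)
}

# pooling with argmax bookkeeping for backprop
.pool_max <- function(H, n) {
  L <- nrow(H); dim_ <- ncol(H)
  out_len <- ceiling(L / n)
  val <- matrix(0, out_len, dim_)
  idx <- matrix(0L, out_len, dim_)
  for (b in seq_len(out_len)) {
    r1 <- (b - 1L) * n + 1L
    r2 <- min(b * n, L)
    sub <- H[r1:r2, , drop = FALSE]
    w <- max.col(t(sub), ties.method = "first")
    idx[b, ] <- r1 - 1L + w
    val[b, ] <- sub[cbind(w, seq_len(dim_))]
  }
  list(val = val, idx = idx)
}

#' n-max pooling over disjoint windows
#'
#' Per-dimension maximum over consecutive non-overlapping blocks of `n`
#' positions; a partial final block is pooled over its available entries.
#' The output keeps only 1/n of the convolution features.
#'
#' @param H input matrix (positions x dims).
#' @param n pooling width (`n = 1` is the identity).
#' @return a `ceiling(nrow(H) / n) x ncol(H)` matrix.
#' @export
n_max_pool <- function(H, n) {
  stopifnot(n >= 1)
  .pool_max(H, as.integer(n))$val
}

#' Run a GRU over a sequence
#'
#' Implements, per step t:
#' \deqn{z_t = \sigma(M_z v_t + N_z h_{t-1} + b_z)}
#' \deqn{r_t = \sigma(M_r v_t + N_r h_{t-1} + b_r)}
#' \deqn{\tilde h_t = \tanh(M_s v_t + r_t \odot (N_s h_{t-1}) + b_s)}
#' \deqn{h_t = z_t \odot \tilde h_t + (1 - z_t) \odot h_{t-1}}
#'
#' @param V input sequence (positions x in_dim).
#' @param params a [gru_params()].
#' @param h0 initial hidden state (defaults to the zero vector).
#' @return matrix of hidden states (positions x hidden).
#' @export
gru_sequence <- function(V, params, h0 = numeric(params$hidden)) {
  stopifnot(ncol(V) == params$in_dim, length(h0) == params$hidden)
  gru_forward_cpp(V, params$Mz, params$Ms, params$Mr,
                  params$Nz, params$Ns, params$Nr,
                  params$bz, params$bs, params$br, h0)$H
}

#' Bidirectional GRU with a merge operator
#'
#' The forward GRU reads the sequence left to right, the backward GRU reads
#' it reversed. `"concatenate"` returns `[fwd, bwd, input]` per position
#' (feature reuse; dim `2 * hidden + in_dim`); `"residual"` returns
#' `[fwd + input, bwd + input]` (dim `2 * hidden`, requires `in_dim ==
#' hidden`).
#'
#' @param V input sequence (positions x in_dim).
#' @param fwd,bwd [gru_params()] for the two directions.
#' @param merge `"concatenate"` or `"residual"`.
#' @return the merged matrix.
#' @export
bigru_merge <- function(V, fwd, bwd, merge = c("concatenate", "residual")) {
  merge <- match.arg(merge)
  if (merge == "residual" && ncol(V) != fwd$hidden) {
    stop("residual merge requires input dim (", ncol(V),
         ") == hidden dim (", fwd$hidden, ")")
  }
  L <- nrow(V)
  Hf <- gru_sequence(V, fwd)
  Hb <- gru_sequence(V[L:1, , drop = FALSE], bwd)[L:1, , drop = FALSE]
  if (merge == "concatenate") cbind(Hf, Hb, V) else cbind(Hf + V, Hb + V)
}

#' One RCNN unit: convolution, n-max pooling, bidirectional GRU
#'
#' @param V input sequence (positions x in_dim).
#' @param unit_params list with elements `conv` ([conv_params()]), `fwd` and
#'   `bwd` ([gru_params()]).
#' @param config an [rcnn_config()] providing `n` and `merge`.
#' @return the merged BiGRU output, length `ceiling((l - d + 1) / n)`.
#' @export
rcnn_unit <- function(V, unit_params, config) {
  H <- conv_layer(V, unit_params$conv)
  P <- n_max_pool(H, config$n)
  bigru_merge(P, unit_params$fwd, unit_params$bwd, config$merge)
}

#' Global average pooling
#'
#' Per-dimension arithmetic mean over all remaining positions, collapsing a
#' sequence of hidden states into one embedding vector.
#'
#' @param H non-empty matrix (positions x dims).
#' @return a vector of length `ncol(H)`.
#' @export
global_avg_pool <- function(H) {
  if (is.null(dim(H)) || nrow(H) == 0L) {
    stop("global average pooling over an empty sequence: ",
         "the encoder is misconfigured for this sequence length")
  }
  colMeans(H)
}

#' Encode one protein sequence into a d'-dimensional vector
#'
#' Applies `num_units` RCNN units, one final convolution, then global
#' average pooling. Zero-padding rows are processed like real positions (the
#' reference setting pads every sequence to a fixed length, with no masking
#' mechanism).
#'
#' @param emb an `embedded_sequence` from [embed_sequence()] (or a plain
#'   numeric matrix).
#' @param state an [init_encoder_state()] bundle.
#' @param config the [rcnn_config()]; defaults to the one stored in `state`.
#' @return the sequence embedding, a vector of length `config$hidden`.
#' @export
encode_sequence <- function(emb, state, config = state$config) {
  X <- if (inherits(emb, "embedded_sequence")) emb$matrix else emb
  for (u in seq_len(config$num_units)) {
    H <- conv_layer(X, state$units[[u]]$conv, stage = paste0("unit ", u, " convolution"))
    P <- n_max_pool(H, config$n)
    X <- bigru_merge(P, state$units[[u]]$fwd, state$units[[u]]$bwd, config$merge)
  }
  Hf <- conv_layer(X, state$final_conv, stage = "final convolution")
  global_avg_pool(Hf)
}

#' Encode a pair of sequences into one fused vector
#'
#' Both arms use the identical shared parameter bundle; the two embeddings
#' are fused by element-wise multiplication, which makes the pair encoding
#' exactly symmetric under argument swap.
#'
#' @param emb1,emb2 `embedded_sequence` objects (or matrices).
#' @param state shared [init_encoder_state()] bundle.
#' @param config the [rcnn_config()]; defaults to the one stored in `state`.
#' @return a vector of length `config$hidden`.
#' @export
encode_pair <- function(emb1, emb2, state, config = state$config) {
  encode_sequence(emb1, state, config) * encode_sequence(emb2, state, config)
}

#' Save / load a checkpoint archive
#'
#' A checkpoint is a single RDS archive holding a format-version field plus
#' the object (an `encoder_state`, `ordinal_model` or `regression_model`
#' including its configuration and all tensors).
#'
#' @param object the object to store.
#' @param path file path.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(list(format_version = 1L, class = class(object)[[1L]],
               object = object), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param config optional [rcnn_config()]; loading fails if the stored
#'   encoder configuration does not match it.
#' @export
load_checkpoint <- function(path, config = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  arch <- readRDS(path)
  if (!identical(arch$format_version, 1L)) {
    stop("unsupported checkpoint format version: ", arch$format_version)
  }
  obj <- arch$object
  if (!is.null(config)) {
    stored <- if (inherits(obj, "encoder_state")) obj$config else obj$encoder$config
    if (!identical(unclass(stored), unclass(config))) {
      stop("checkpoint encoder configuration does not match the requested one")
    }
  }
  obj
}
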