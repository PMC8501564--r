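#' Training configuration
#'
#' Reference full-scale defaults: AMSGrad with learning rate 0.001, beta1 =
#' 0.9, beta2 = 0.999, batch size 768. Epochs default to 30. The optimizer
#' is fixed to the AMSGrad variant (second-moment running maximum).
#'
#' @param learning_rate step size.
#' @param beta1,beta2 exponential decay rates of the first and second moment
#'   estimates (`0 < beta1 < beta2 < 1`).
#' @param batch_size pairs per gradient update.
#' @param epochs passes over the training pairs (an upper bound when early
#'   stopping is enabled).
#' @param seed integer seed for shuffling (and anything else stochastic).
#' @param epsilon denominator stabilizer.
#' @param validation_fraction fraction of the training pairs held out as a
#'   validation slice for early stopping; 0 (the default) disables early
#'   stopping entirely.
#' @param patience epochs without validation improvement before stopping;
#'   the best-validation parameters are restored.
#' @return a list of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                            batch_size = 768L, epochs = 30L, seed = 1L,
                            epsilon = 1e-8, validation_fraction = 0,
                            patience = 20L) {
  stopifnot(beta1 > 0, beta1 < beta2, beta2 < 1, batch_size >= 1, epochs >= 0,
            validation_fraction >= 0, validation_fraction < 1, patience >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 epsilon = epsilon, validation_fraction = validation_fraction,
                 patience = as.integer(patience)),
            class = "training_config")
}

#' Initialize AMSGrad optimizer state
#'
#' @param params named list of numeric tensors.
#' @return zeroed moment estimates `m`, `v` and running maximum `vhat`.
#' @export
amsgrad_init <- function(params) {
  z <- lapply(params, function(p) p * 0)
  list(m = z, v = z, vhat = z)
}

#' One AMSGrad update
#'
#' First and second moment estimates are decayed by beta1 / beta2 and the
#' update divides by the square root of the elementwise running *maximum* of
#' the second moment (no bias correction, following the original variant):
#' `theta <- theta - lr * m / (sqrt(max(vhat, v)) + eps)`.
#'
#' @param params named list of numeric tensors.
#' @param grads matching named list of gradients.
#' @param opt_state state from [amsgrad_init()].
#' @param config a [training_config()].
#' @return list with updated `params` and `opt_state`.
#' @export
amsgrad_step <- function(params, grads, opt_state, config) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    m <- config$beta1 * opt_state$m[[nm]] + (1 - config$beta1) * g
    v <- config$beta2 * opt_state$v[[nm]] + (1 - config$beta2) * g * g
    vh <- pmax(opt_state$vhat[[nm]], v)
    params[[nm]] <- params[[nm]] - config$learning_rate * m / (sqrt(vh) + config$epsilon)
    opt_state$m[[nm]] <- m
    opt_state$v[[nm]] <- v
    opt_state$vhat[[nm]] <- vh
  }
  list(params = params, opt_state = opt_state)
}

# ---- shared trainer scaffolding -------------------------------------------

head_tensors <- function(heads, prefix = "head") {
  out <- list()
  for (k in seq_along(heads)) {
    for (nm in c("W1", "b1", "W2", "b2")) {
      out[[paste0(prefix, k, ".", nm)]] <- heads[[k]][[nm]]
    }
  }
  out
}

head_set_tensors <- function(heads, tensors, prefix = "head") {
  for (k in seq_along(heads)) {
    for (nm in c("W1", "b1", "W2", "b2")) {
      heads[[k]][[nm]] <- tensors[[paste0(prefix, k, ".", nm)]]
    }
  }
  heads
}

# embed all unique sequences referenced by the pairs once, up front
prepare_embeddings <- function(pairs, records, table, max_len) {
  recs <- stats::setNames(records, vapply(records, `[[`, "", "id"))
  ids <- unique(c(pairs$id1, pairs$id2))
  missing <- setdiff(ids, names(recs))
  if (length(missing)) {
    stop("training pairs reference unknown sequence id(s): ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  stats::setNames(lapply(ids, function(id) {
    embed_sequence(recs[[id]], table, max_len)$matrix
  }), ids)
}

# generic minibatch loop over pairs; batch_fn(batch_pairs) must return the
# batch loss and a complete gradient tensor list, and is responsible for
# reading current parameters from the enclosing mutable state. val_fn, when
# given, scores the current parameters after each epoch; the best-scoring
# parameters are kept and training stops after `patience` epochs without
# improvement.
run_epochs <- function(pairs, config, params, batch_fn, apply_fn,
                       val_fn = NULL) {
  n <- nrow(pairs)
  opt <- amsgrad_init(params)
  trace <- numeric(0)
  val_trace <- numeric(0)
  best_val <- Inf
  best_params <- NULL
  stall <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      rows <- perm[s:min(s + config$batch_size - 1L, n)]
      bres <- batch_fn(pairs[rows, , drop = FALSE])
      if (!is.finite(bres$loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; lower the learning rate")
      }
      epoch_loss <- epoch_loss + bres$loss * length(rows)
      step <- amsgrad_step(params, bres$grads, opt, config)
      params <- step$params
      opt <- step$opt_state
      apply_fn(params)
    }
    trace[epoch] <- epoch_loss / n
    if (!is.null(val_fn)) {
      v <- val_fn()
      val_trace[epoch] <- v
      if (v < best_val - 1e-9) {
        best_val <- v
        best_params <- params
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  }
  if (!is.null(best_params)) {
    params <- best_params
    apply_fn(params)
  }
  list(params = params, trace = trace, val_trace = val_trace)
}

#' Train the ordinal model
#'
#' Joint training: one shared encoder plus all K-1 sub-classifier heads are
#' optimized together on the sum of the K-1 relabelled cross-entropy losses.
#' Every batch feeds all K-1 relabellings, so each sub-problem sees the
#' entire training set with its own division. Deterministic given
#' `config$seed` (single-threaded).
#'
#' @param model an [ordinal_model()].
#' @param train_pairs labeled pair table (see [label_pairs()]).
#' @param records list of [protein_record()] covering all referenced ids.
#' @param config a [training_config()].
#' @return list with the trained `model` and a `trace` data frame (epoch,
#'   mean summed loss, and validation loss when early stopping is on).
#' @export
train_ordinal <- function(model, train_pairs, records, config = training_config()) {
  if (is.null(train_pairs$label)) stop("train_pairs must carry ordinal labels")
  K <- model$partition$K
  if (config$epochs == 0L) {
    return(list(model = model, trace = data.frame(epoch = integer(),
                                                  loss = numeric())))
  }
  val_pairs <- NULL
  if (config$validation_fraction > 0) {
    vs <- suppressWarnings(
      split_train_test(train_pairs, 1 - config$validation_fraction,
                       seed = config$seed + 10007L))
    train_pairs <- vs$train
    val_pairs <- vs$test
  }
  embs <- prepare_embeddings(rbind(train_pairs, val_pairs)[, c("id1", "id2")],
                             records, model$table, model$max_len)
  env <- new.env(parent = emptyenv())
  env$model <- model
  params <- c(encoder_tensors(model$encoder), head_tensors(model$heads))

  batch_fn <- function(bp) {
    mdl <- env$model
    cpp <- encoder_cpp_params(mdl$encoder)
    ids <- unique(c(bp$id1, bp$id2))
    res <- batch_grad_cpp(embs[ids], cpp$units, cpp$final, mdl$heads,
                          match(bp$id1, ids), match(bp$id2, ids),
                          as.numeric(bp$label), mdl$config$d, mdl$config$n,
                          mdl$config$merge == "concatenate",
                          mdl$leaky_slope, 0L, K)
    hgrads <- list()
    for (k in seq_len(K - 1L)) {
      gk <- res$heads[[k]]
      hgrads[[paste0("head", k, ".W1")]] <- gk$W1
      hgrads[[paste0("head", k, ".b1")]] <- as.numeric(gk$b1)
      hgrads[[paste0("head", k, ".W2")]] <- gk$W2
      hgrads[[paste0("head", k, ".b2")]] <- as.numeric(gk$b2)
    }
    list(loss = res$loss, grads = c(cpp_grads_flatten(res$encoder), hgrads))
  }

  apply_fn <- function(params) {
    env$model$encoder <- encoder_set_tensors(env$model$encoder, params)
    env$model$heads <- head_set_tensors(env$model$heads, params)
  }

  val_fn <- if (is.null(val_pairs)) NULL else function() {
    ordinal_eval_loss(env$model, val_pairs, embs)
  }

  res <- withr_seed(config$seed, run_epochs(train_pairs, config, params,
                                            batch_fn, apply_fn, val_fn))
  trace <- data.frame(epoch = seq_along(res$trace), loss = res$trace)
  if (length(res$val_trace)) trace$val_loss <- res$val_trace
  list(model = env$model, trace = trace)
}

# forward-only summed cross-entropy of all sub-classifiers on held-out pairs
ordinal_eval_loss <- function(model, pairs, embs) {
  cpp <- encoder_cpp_params(model$encoder)
  ids <- unique(c(pairs$id1, pairs$id2))
  E <- t(vapply(ids, function(id) {
    as.numeric(encoder_forward_fast(embs[[id]], model$encoder, cpp)$embedding)
  }, numeric(model$config$hidden)))
  X <- E[match(pairs$id1, ids), , drop = FALSE] *
    E[match(pairs$id2, ids), , drop = FALSE]
  loss <- 0
  for (k in seq_along(model$heads)) {
    y <- ifelse(pairs$label > k, 1L, -1L)
    loss <- loss + cross_entropy_loss(X, y, model$heads[[k]])
  }
  loss
}

#' Train the scalar-regression ablation model
#'
#' Same encoder, fusion and optimizer as [train_ordinal()], but the single
#' scalar head minimizes the mean squared error against the raw confidence
#' score.
#'
#' @param model a [regression_model()].
#' @param train_pairs pair table with a `score` column.
#' @param records list of [protein_record()].
#' @param config a [training_config()].
#' @return list with the trained `model` and a `trace` data frame.
#' @export
train_regression <- function(model, train_pairs, records,
                             config = training_config()) {
  if (is.null(train_pairs$score)) stop("train_pairs must carry scores")
  if (config$epochs == 0L) {
    return(list(model = model, trace = data.frame(epoch = integer(),
                                                  loss = numeric())))
  }
  val_pairs <- NULL
  if (config$validation_fraction > 0) {
    set.seed(config$seed + 10007L)
    vrows <- sample.int(nrow(train_pairs),
                        max(1L, round(config$validation_fraction *
                                      nrow(train_pairs))))
    val_pairs <- train_pairs[vrows, , drop = FALSE]
    train_pairs <- train_pairs[-vrows, , drop = FALSE]
  }
  embs <- prepare_embeddings(rbind(train_pairs, val_pairs)[, c("id1", "id2")],
                             records, model$table, model$max_len)
  env <- new.env(parent = emptyenv())
  env$model <- model
  params <- c(encoder_tensors(model$encoder),
              head_tensors(list(model$head), prefix = "reg"))

  batch_fn <- function(bp) {
    mdl <- env$model
    cpp <- encoder_cpp_params(mdl$encoder)
    ids <- unique(c(bp$id1, bp$id2))
    res <- batch_grad_cpp(embs[ids], cpp$units, cpp$final, list(mdl$head),
                          match(bp$id1, ids), match(bp$id2, ids),
                          as.numeric(bp$score), mdl$config$d, mdl$config$n,
                          mdl$config$merge == "concatenate",
                          mdl$leaky_slope, 1L, 2L)
    gk <- res$heads[[1L]]
    hgrads <- list(reg1.W1 = gk$W1, reg1.b1 = as.numeric(gk$b1),
                   reg1.W2 = gk$W2, reg1.b2 = as.numeric(gk$b2))
    list(loss = res$loss, grads = c(cpp_grads_flatten(res$encoder), hgrads))
  }

  apply_fn <- function(params) {
    env$model$encoder <- encoder_set_tensors(env$model$encoder, params)
    env$model$head <- head_set_tensors(list(env$model$head), params,
                                       prefix = "reg")[[1L]]
  }

  val_fn <- if (is.null(val_pairs)) NULL else function() {
    mdl <- env$model
    cpp <- encoder_cpp_params(mdl$encoder)
    ids <- unique(c(val_pairs$id1, val_pairs$id2))
    E <- t(vapply(ids, function(id) {
      as.numeric(encoder_forward_fast(embs[[id]], mdl$encoder, cpp)$embedding)
    }, numeric(mdl$config$hidden)))
    X <- E[match(val_pairs$id1, ids), , drop = FALSE] *
      E[match(val_pairs$id2, ids), , drop = FALSE]
    mean((as.numeric(mlp_forward(X, mdl$head)$S) - val_pairs$score)^2)
  }

  res <- withr_seed(config$seed, run_epochs(train_pairs, config, params,
                                            batch_fn, apply_fn, val_fn))
  trace <- data.frame(epoch = seq_along(res$trace), loss = res$trace)
  if (length(res$val_trace)) trace$val_loss <- res$val_trace
  list(model = env$model, trace = trace)
}
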