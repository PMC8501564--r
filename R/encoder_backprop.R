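# Internal forward-with-cache / backward passes used by the trainers.
# The public encode_sequence() is the same computation without caches; the
# agreement of the two paths is asserted in the test suite.

conv_backward <- function(dH, X, params, need_dX = TRUE) {
  Xw <- .conv_windows(X, params$d)
  dW <- crossprod(Xw, dH)
  db <- colSums(dH)
  dX <- NULL
  if (need_dX) {
    dXw <- tcrossprod(dH, params$W)
    dX <- matrix(0, nrow(X), ncol(X))
    L <- nrow(X); d <- params$d; in_dim <- params$in_dim
    for (j in seq_len(d)) {
      cols <- ((j - 1L) * in_dim + 1L):(j * in_dim)
      rows <- j:(L - d + j)
      dX[rows, ] <- dX[rows, ] + dXw[, cols, drop = FALSE]
    }
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

pool_backward <- function(dP, idx, in_len) {
  dH <- matrix(0, in_len, ncol(dP))
  cols <- rep(seq_len(ncol(dP)), each = nrow(dP))
  dH[cbind(as.vector(idx), cols)] <- as.vector(dP)
  dH
}

gru_forward_cache <- function(V, p, h0 = numeric(p$hidden)) {
  gru_forward_cpp(V, p$Mz, p$Ms, p$Mr, p$Nz, p$Ns, p$Nr, p$bz, p$bs, p$br, h0)
}

gru_backward_cache <- function(V, p, cache, dH, h0 = numeric(p$hidden)) {
  gru_backward_cpp(V, p$Mz, p$Ms, p$Mr, p$Nz, p$Ns, p$Nr, h0,
                   cache$H, cache$Z, cache$R, cache$C, dH)
}

bigru_forward_cache <- function(V, fwd, bwd, merge) {
  L <- nrow(V)
  Vr <- V[L:1, , drop = FALSE]
  cf <- gru_forward_cache(V, fwd)
  cb <- gru_forward_cache(Vr, bwd)
  Hb <- cb$H[L:1, , drop = FALSE]
  out <- if (merge == "concatenate") cbind(cf$H, Hb, V) else cbind(cf$H + V, Hb + V)
  list(out = out, V = V, Vr = Vr, cf = cf, cb = cb)
}

bigru_backward_cache <- function(bc, fwd, bwd, merge, dM) {
  h <- fwd$hidden
  L <- nrow(bc$V)
  dHf <- dM[, seq_len(h), drop = FALSE]
  dHb <- dM[, h + seq_len(h), drop = FALSE]
  gf <- gru_backward_cache(bc$V, fwd, bc$cf, dHf)
  gb <- gru_backward_cache(bc$Vr, bwd, bc$cb, dHb[L:1, , drop = FALSE])
  dV <- gf$dV + gb$dV[L:1, , drop = FALSE]
  if (merge == "concatenate") {
    dV <- dV + dM[, 2L * h + seq_len(ncol(bc$V)), drop = FALSE]
  } else {
    dV <- dV + dHf + dHb
  }
  grad_of <- function(g) list(Mz = g$dMz, Ms = g$dMs, Mr = g$dMr,
                              Nz = g$dNz, Ns = g$dNs, Nr = g$dNr,
                              bz = as.numeric(g$dbz), bs = as.numeric(g$dbs),
                              br = as.numeric(g$dbr))
  list(dV = dV, fwd = grad_of(gf), bwd = grad_of(gb))
}

encoder_forward <- function(X, state, config = state$config) {
  caches <- vector("list", config$num_units)
  for (u in seq_len(config$num_units)) {
    H <- conv_layer(X, state$units[[u]]$conv,
                    stage = paste0("unit ", u, " convolution"))
    pm <- .pool_max(H, config$n)
    bc <- bigru_forward_cache(pm$val, state$units[[u]]$fwd,
                              state$units[[u]]$bwd, config$merge)
    caches[[u]] <- list(X = X, conv_len = nrow(H), pool_idx = pm$idx, bigru = bc)
    X <- bc$out
  }
  Hf <- conv_layer(X, state$final_conv, stage = "final convolution")
  list(embedding = global_avg_pool(Hf),
       caches = caches, final_X = X, final_len = nrow(Hf))
}

encoder_backward <- function(state, fw, dE, config = state$config) {
  grads <- list(units = vector("list", config$num_units), final_conv = NULL)
  # global average pooling spreads the embedding gradient uniformly
  dHf <- matrix(dE, fw$final_len, length(dE), byrow = TRUE) / fw$final_len
  cb <- conv_backward(dHf, fw$final_X, state$final_conv, need_dX = TRUE)
  grads$final_conv <- cb$grads
  dX <- cb$dX
  for (u in rev(seq_len(config$num_units))) {
    uc <- fw$caches[[u]]
    bg <- bigru_backward_cache(uc$bigru, state$units[[u]]$fwd,
                               state$units[[u]]$bwd, config$merge, dX)
    dH <- pool_backward(bg$dV, uc$pool_idx, uc$conv_len)
    cbk <- conv_backward(dH, uc$X, state$units[[u]]$conv, need_dX = (u > 1L))
    grads$units[[u]] <- list(conv = cbk$grads, fwd = bg$fwd, bwd = bg$bwd)
    dX <- cbk$dX
  }
  grads
}

# ---- flat parameter addressing shared by the optimizer --------------------

# named list of numeric tensors for an encoder state
encoder_tensors <- function(state) {
  out <- list()
  for (u in seq_along(state$units)) {
    pu <- state$units[[u]]
    out[[paste0("u", u, ".conv.W")]] <- pu$conv$W
    out[[paste0("u", u, ".conv.b")]] <- pu$conv$b
    for (dir in c("fwd", "bwd")) {
      for (nm in c("Mz", "Ms", "Mr", "Nz", "Ns", "Nr", "bz", "bs", "br")) {
        out[[paste0("u", u, ".", dir, ".", nm)]] <- pu[[dir]][[nm]]
      }
    }
  }
  out[["final.W"]] <- state$final_conv$W
  out[["final.b"]] <- state$final_conv$b
  out
}

encoder_grad_tensors <- function(grads) {
  out <- list()
  for (u in seq_along(grads$units)) {
    gu <- grads$units[[u]]
    out[[paste0("u", u, ".conv.W")]] <- gu$conv$W
    out[[paste0("u", u, ".conv.b")]] <- gu$conv$b
    for (dir in c("fwd", "bwd")) {
      for (nm in c("Mz", "Ms", "Mr", "Nz", "Ns", "Nr", "bz", "bs", "br")) {
        out[[paste0("u", u, ".", dir, ".", nm)]] <- gu[[dir]][[nm]]
      }
    }
  }
  out[["final.W"]] <- grads$final_conv$W
  out[["final.b"]] <- grads$final_conv$b
  out
}

encoder_set_tensors <- function(state, tensors) {
  for (u in seq_along(state$units)) {
    state$units[[u]]$conv$W <- tensors[[paste0("u", u, ".conv.W")]]
    state$units[[u]]$conv$b <- tensors[[paste0("u", u, ".conv.b")]]
    for (dir in c("fwd", "bwd")) {
      for (nm in c("Mz", "Ms", "Mr", "Nz", "Ns", "Nr", "bz", "bs", "br")) {
        state$units[[u]][[dir]][[nm]] <- tensors[[paste0("u", u, ".", dir, ".", nm)]]
      }
    }
  }
  state$final_conv$W <- tensors[["final.W"]]
  state$final_conv$b <- tensors[["final.b"]]
  state
}

tensor_add <- function(a, b) {
  if (is.null(a)) return(b)
  Map(`+`, a, b)
}

# ---- compiled fast path ---------------------------------------------------
# Identical semantics to encoder_forward()/encoder_backward(), used inside
# the training loops; equality of the two paths is asserted in the tests.

encoder_cpp_params <- function(state) {
  gru_fields <- c("Mz", "Ms", "Mr", "Nz", "Ns", "Nr", "bz", "bs", "br")
  list(units = lapply(state$units, function(u) {
         list(convW = u$conv$W, convb = u$conv$b,
              fwd = u$fwd[gru_fields], bwd = u$bwd[gru_fields])
       }),
       final = list(convW = state$final_conv$W, convb = state$final_conv$b))
}

encoder_forward_fast <- function(X, state, cpp = encoder_cpp_params(state)) {
  encoder_fwd_cpp(X, cpp$units, cpp$final, state$config$d, state$config$n,
                  state$config$merge == "concatenate")
}

# flatten the nested gradient list returned by the compiled backward into
# the tensor naming used by the optimizer
cpp_grads_flatten <- function(g) {
  out <- list()
  for (u in seq_along(g$units)) {
    gu <- g$units[[u]]
    out[[paste0("u", u, ".conv.W")]] <- gu$convW
    out[[paste0("u", u, ".conv.b")]] <- as.numeric(gu$convb)
    for (dir in c("fwd", "bwd")) {
      for (nm in c("Mz", "Ms", "Mr", "Nz", "Ns", "Nr")) {
        out[[paste0("u", u, ".", dir, ".", nm)]] <- gu[[dir]][[nm]]
      }
      for (nm in c("bz", "bs", "br")) {
        out[[paste0("u", u, ".", dir, ".", nm)]] <- as.numeric(gu[[dir]][[nm]])
      }
    }
  }
  out[["final.W"]] <- g$final_W
  out[["final.b"]] <- as.numeric(g$final_b)
  out
}

encoder_backward_fast <- function(state, fw, dE, cpp = encoder_cpp_params(state)) {
  g <- encoder_bwd_cpp(cpp$units, cpp$final, fw, dE, state$config$d,
                       state$config$n, state$config$merge == "concatenate")
  out <- list()
  for (u in seq_along(g$units)) {
    gu <- g$units[[u]]
    out[[paste0("u", u, ".conv.W")]] <- gu$convW
    out[[paste0("u", u, ".conv.b")]] <- as.numeric(gu$convb)
    for (dir in c("fwd", "bwd")) {
      for (nm in c("Mz", "Ms", "Mr", "Nz", "Ns", "Nr")) {
        out[[paste0("u", u, ".", dir, ".", nm)]] <- gu[[dir]][[nm]]
      }
      for (nm in c("bz", "bs", "br")) {
        out[[paste0("u", u, ".", dir, ".", nm)]] <- as.numeric(gu[[dir]][[nm]])
      }
    }
  }
  out[["final.W"]] <- g$final_W
  out[["final.b"]] <- as.numeric(g$final_b)
  out
}
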