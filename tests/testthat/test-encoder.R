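test_that("convolution contract: affine sliding window, length l - d + 1", {
  set.seed(1)
  p <- conv_params(3, 4, 5)
  X <- matrix(rnorm(2000 * 4), 2000, 4)
  H <- conv_layer(X, p)
  expect_equal(dim(H), c(1998L, 5L))

  zero <- conv_params(3, 4, 5, W = matrix(0, 12, 5), b = 1:5)
  expect_true(all(conv_layer(X[1:10, ], zero) ==
                  matrix(1:5, 8, 5, byrow = TRUE)))

  ident <- conv_params(1, 4, 4, W = diag(4), b = rep(0, 4))
  expect_equal(conv_layer(X[1:10, ], ident), X[1:10, ])

  expect_error(conv_layer(X[1:2, ], p), "shorter than kernel width")
})

test_that("convolution position t is the affine map of window t..t+d-1", {
  set.seed(2)
  p <- conv_params(3, 2, 3)
  X <- matrix(rnorm(12), 6, 2)
  H <- conv_layer(X, p)
  for (t in 1:4) {
    window <- as.numeric(t(X[t:(t + 2), ]))  # offset-major layout
    expect_equal(H[t, ], as.numeric(window %*% p$W) + p$b)
  }
})

test_that("n-max pooling over disjoint blocks, partial tail pooled as-is", {
  H <- matrix(c(3, 1, 2, 5, 4, 0), ncol = 1)
  expect_equal(n_max_pool(H, 3), matrix(c(3, 5), ncol = 1))
  set.seed(3)
  M <- matrix(rnorm(30), 10, 3)
  expect_equal(n_max_pool(M, 1), M)
  expect_equal(nrow(n_max_pool(M, 5)), 2L)   # divisible: exactly len/n
  expect_equal(nrow(n_max_pool(M, 4)), 3L)   # partial last block kept
  expect_equal(n_max_pool(M, 4)[3, ], apply(M[9:10, ], 2, max))
})

test_that("GRU matches the scalar-loop oracle on random instances", {
  set.seed(4)
  for (i in 1:8) {
    L <- sample(1:20, 1)
    din <- sample(1:8, 1)
    h <- sample(1:8, 1)
    p <- gru_params(din, h)
    V <- matrix(rnorm(L * din), L, din)
    expect_equal(gru_sequence(V, p), gru_oracle(V, p), tolerance = 1e-5)
  }
})

test_that("GRU gate limits: z = 1 tracks the candidate, z = 0 freezes h0", {
  din <- 3L; h <- 3L
  zeros <- matrix(0, din, h)
  zh <- matrix(0, h, h)
  V <- matrix(rnorm(15), 5, din)
  # large positive update-gate bias: h_t = candidate at every step
  p1 <- gru_params(din, h, Mz = zeros, Nz = zh, bz = rep(50, h))
  H1 <- gru_sequence(V, p1)
  h_prev <- numeric(h)
  for (t in 1:5) {
    r <- 1 / (1 + exp(-(as.numeric(V[t, ] %*% p1$Mr + h_prev %*% p1$Nr) + p1$br)))
    cand <- tanh(as.numeric(V[t, ] %*% p1$Ms) + r * as.numeric(h_prev %*% p1$Ns) + p1$bs)
    expect_equal(H1[t, ], cand, tolerance = 1e-12)
    h_prev <- H1[t, ]
  }
  # large negative bias: z = 0, state never leaves h0
  p0 <- gru_params(din, h, Mz = zeros, Nz = zh, bz = rep(-50, h))
  h0 <- rnorm(h)
  H0 <- gru_sequence(V, p0, h0 = h0)
  for (t in 1:5) expect_equal(H0[t, ], h0, tolerance = 1e-12)
})

test_that("BiGRU merge dimensions: concatenate 3d', residual 2d'", {
  set.seed(5)
  V50 <- matrix(rnorm(10 * 50), 10, 50)
  fwd <- gru_params(50, 50); bwd <- gru_params(50, 50)
  expect_equal(ncol(bigru_merge(V50, fwd, bwd, "concatenate")), 150L)
  expect_equal(ncol(bigru_merge(V50, fwd, bwd, "residual")), 100L)

  # concatenate appends the raw input on the right
  out <- bigru_merge(V50, fwd, bwd, "concatenate")
  expect_equal(out[, 101:150], V50)

  # backward direction reads the sequence reversed
  Hb <- out[, 51:100]
  expect_equal(Hb, gru_sequence(V50[10:1, ], bwd)[10:1, ])

  # length-1 sequence: both directions see the same single input
  V1 <- matrix(rnorm(50), 1, 50)
  out1 <- bigru_merge(V1, fwd, fwd, "concatenate")
  expect_equal(out1[, 1:50], out1[, 51:100])

  V8 <- matrix(rnorm(10 * 8), 10, 8)
  expect_error(bigru_merge(V8, fwd, bwd, "residual"), "hidden dim")
})

test_that("length and dimension bookkeeping holds across random unit configs", {
  set.seed(6)
  for (i in 1:6) {
    d <- sample(1:4, 1)
    n <- sample(1:4, 1)
    h <- sample(2:6, 1)
    din <- sample(2:6, 1)
    merge <- sample(c("concatenate", "residual"), 1)
    cfg <- rcnn_config(num_units = 1L, d = d, hidden = h, n = n, merge = merge)
    L <- sample((d + 1):40, 1)
    unit <- list(conv = conv_params(d, din, h),
                 fwd = gru_params(h, h), bwd = gru_params(h, h))
    out <- rcnn_unit(matrix(rnorm(L * din), L, din), unit, cfg)
    expect_equal(nrow(out), ceiling((L - d + 1) / n))
    expect_equal(ncol(out), if (merge == "concatenate") 3L * h else 2L * h)
  }
})

test_that("global average pooling is the per-dimension mean", {
  expect_equal(global_avg_pool(matrix(c(0, 2, 0, 2), 2, 2)), c(1, 1))
  row <- c(1.5, -2, 3)
  expect_equal(global_avg_pool(matrix(row, 4, 3, byrow = TRUE)), row)
  set.seed(7)
  M <- matrix(rnorm(60), 12, 5)
  brute <- vapply(1:5, function(j) sum(M[, j]) / 12, numeric(1))
  expect_equal(global_avg_pool(M), brute)
  expect_error(global_avg_pool(M[0, , drop = FALSE]), "empty")
})

test_that("encode_sequence returns a d'-vector, deterministically", {
  st <- small_encoder(in_dim = 7, hidden = 6)
  rec <- protein_record("p", random_residues(70))
  emb <- embed_sequence(rec, eh_table(), 80)
  v1 <- encode_sequence(emb, st)
  expect_length(v1, 6L)
  expect_identical(v1, encode_sequence(emb, st))

  # stacked shrinkage: 80 -> conv 78 -> pool 26 -> conv 24 -> pool 8 -> conv 6
  fw <- ordppi:::encoder_forward(emb$matrix, st)
  expect_equal(fw$final_len, 6L)

  # too-short input names the failing stage
  tiny <- small_encoder(in_dim = 7, hidden = 6, num_units = 4L)
  short <- embed_sequence(protein_record("q", random_residues(50)), eh_table(), 50)
  expect_error(encode_sequence(short, tiny), "unit .* convolution")
})

test_that("pair encoding is exactly symmetric for any shared weights", {
  for (seed in 1:5) {
    st <- small_encoder(in_dim = 7, seed = seed,
                        merge = if (seed %% 2) "concatenate" else "residual")
    e1 <- embed_sequence(protein_record("a", random_residues(60)), eh_table(), 70)
    e2 <- embed_sequence(protein_record("b", random_residues(65)), eh_table(), 70)
    expect_identical(encode_pair(e1, e2, st), encode_pair(e2, e1, st))
  }
})

test_that("all-ones arm embedding makes pair fusion the identity", {
  # with a zero final-conv kernel and bias 1, every sequence embeds to 1s
  st <- small_encoder(in_dim = 7, hidden = 6)
  st$final_conv$W[] <- 0
  st$final_conv$b[] <- 1
  e1 <- embed_sequence(protein_record("a", random_residues(60)), eh_table(), 70)
  e2 <- embed_sequence(protein_record("b", random_residues(60)), eh_table(), 70)
  expect_equal(encode_pair(e1, e2, st), encode_sequence(e2, st))
})

test_that("compiled training path reproduces the reference encoder exactly", {
  set.seed(8)
  for (merge in c("concatenate", "residual")) {
    st <- small_encoder(in_dim = 7, seed = 11, merge = merge)
    X <- matrix(rnorm(90 * 7), 90, 7)
    fwR <- ordppi:::encoder_forward(X, st)
    fwC <- ordppi:::encoder_forward_fast(X, st)
    expect_equal(as.numeric(fwC$embedding), fwR$embedding, tolerance = 1e-12)
    dE <- rnorm(6)
    gR <- ordppi:::encoder_grad_tensors(ordppi:::encoder_backward(st, fwR, dE))
    gC <- ordppi:::encoder_backward_fast(st, fwC, dE)
    for (nm in names(gR)) {
      expect_equal(unname(gC[[nm]]), unname(gR[[nm]]), tolerance = 1e-10)
    }
  }
})

test_that("encoder backward agrees with finite differences", {
  st <- small_encoder(in_dim = 5, hidden = 4, seed = 13)
  X <- matrix(rnorm(40 * 5), 40, 5)
  fw <- ordppi:::encoder_forward(X, st)
  g <- ordppi:::encoder_grad_tensors(
    ordppi:::encoder_backward(st, fw, 2 * fw$embedding))
  pt <- ordppi:::encoder_tensors(st)
  loss <- function(state) sum(ordppi:::encoder_forward(X, state)$embedding^2)
  eps <- 1e-6
  set.seed(14)
  for (nm in c("u1.conv.W", "u1.fwd.Ms", "u2.bwd.Nz", "final.W")) {
    i <- sample(length(pt[[nm]]), 1)
    pt2 <- pt
    pt2[[nm]][i] <- pt2[[nm]][i] + eps
    num <- (loss(ordppi:::encoder_set_tensors(st, pt2)) - loss(st)) / eps
    expect_equal(num, g[[nm]][i], tolerance = 1e-3)
  }
})

test_that("checkpoints round-trip and reject mismatched configurations", {
  st <- small_encoder(in_dim = 7, hidden = 6)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(st, path)
  back <- load_checkpoint(path, config = st$config)
  expect_equal(back, st)
  other <- rcnn_config(num_units = 3L, d = 3L, hidden = 6L, n = 3L)
  expect_error(load_checkpoint(path, config = other), "does not match")
})
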