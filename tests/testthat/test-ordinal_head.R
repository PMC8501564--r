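test_that("interval partition and labels reproduce the K = 20 sub-intervals", {
  p <- interval_partition(0, 1, 20)
  expect_equal(p$width, 0.05)
  # enumerate (0,0.05), [0.05,0.1), ..., [0.95,1): 0.72 sits in the 15th
  expect_equal(label_of_score(0.72, p), 15L)
  expect_equal(label_of_score(0.05, p), 2L)   # boundary goes right
  expect_equal(label_of_score(0.03, p), 1L)
  expect_equal(label_of_score(0.15, p), 4L)   # float-sensitive boundary
  expect_equal(label_of_score(0.7, p), 15L)
  expect_error(label_of_score(0, p), "outside")
  expect_error(label_of_score(1, p), "outside")
  # every boundary of every partition labels into the right interval
  for (K in c(2, 5, 7, 20)) {
    pk <- interval_partition(0, 1, K)
    ks <- 2:K
    expect_equal(label_of_score((ks - 1) / K, pk), as.integer(ks))
  }
})

test_that("relabeling partitions the set and nests monotonically", {
  set.seed(1)
  pairs <- data.frame(id1 = as.character(1:200), id2 = as.character(201:400),
                      score = runif(200, 0.01, 0.99))
  pairs <- label_pairs(pairs, interval_partition(0, 1, 8))
  prev_pos <- NULL
  for (k in 1:7) {
    rl <- relabel_for_k(pairs, k)
    expect_equal(nrow(rl$positives) + nrow(rl$negatives), nrow(pairs))
    expect_true(all(rl$positives$y == 1L))
    expect_true(all(rl$negatives$y == -1L))
    expect_true(all(rl$positives$label > k))
    if (!is.null(prev_pos)) {
      expect_true(all(paste(rl$positives$id1, rl$positives$id2) %in% prev_pos))
    }
    prev_pos <- paste(rl$positives$id1, rl$positives$id2)
  }
  rl7 <- relabel_for_k(pairs, 7)
  expect_true(all(rl7$positives$label == 8L))  # k = K-1: positives are label K
  expect_error(relabel_for_k(pairs[, 1:3], 1), "label")
})

test_that("sub-classifier softmax matches the two-term formula", {
  set.seed(2)
  head <- ordppi:::new_mlp_head(4, 8, 2, 0.01)
  # symmetric raw scores give (0.5, 0.5); limits saturate
  sm <- function(s) exp(s) / sum(exp(s))
  for (i in 1:10) {
    s <- rnorm(2, sd = 3)
    expect_equal(ordppi:::softmax2(matrix(s, 1))[1, ], sm(s),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_equal(ordppi:::softmax2(matrix(c(0, 0), 1))[1, ], c(0.5, 0.5),
               ignore_attr = TRUE)
  expect_gt(ordppi:::softmax2(matrix(c(30, -30), 1))[1, 1], 1 - 1e-12)

  P <- subclassifier_forward(matrix(rnorm(40), 10, 4), head)
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  expect_true(all(P > 0))
  expect_error(subclassifier_forward(rnorm(5), head), "dimension")
})

test_that("decision rule: +1 iff s1 > s2, ties to -1", {
  expect_equal(decide_fk(0.6, 0.4), 1L)
  expect_equal(decide_fk(0.5, 0.5), -1L)
  expect_equal(decide_fk(0.4999, 0.5001), -1L)
  expect_equal(decide_fk(c(0.6, 0.2), c(0.4, 0.8)), c(1L, -1L))
})

test_that("rank aggregation equals exhaustive counting for K <= 6", {
  for (K in 2:6) {
    grid <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), K - 1L)))
    for (i in seq_len(nrow(grid))) {
      dec <- grid[i, ]
      expect_equal(aggregate_rank(dec, K = K), 1L + sum(dec == 1L))
    }
  }
  expect_equal(aggregate_rank(rep(-1L, 19), K = 20), 1L)
  expect_equal(aggregate_rank(rep(1L, 19), K = 20), 20L)
  expect_equal(aggregate_rank(c(1L, -1L, 1L), K = 4), 3L)  # inconsistent ok
  expect_error(aggregate_rank(c(1L, -1L), K = 4), "expected 3")
})

test_that("rank decoding: mid/left/right and their spacing", {
  p <- interval_partition(0, 1, 20)
  expect_equal(score_from_rank(1, p, "mid"), 0.025)
  expect_equal(score_from_rank(5, p, "left"), 0.20)   # 0.05 * (5 - 1)
  expect_equal(score_from_rank(5, p, "right"), 0.25)  # 0.05 * 5
  r <- 1:20
  mids <- score_from_rank(r, p, "mid")
  lefts <- score_from_rank(r, p, "left")
  rights <- score_from_rank(r, p, "right")
  expect_true(all(diff(mids) > 0))
  expect_equal(rights - lefts, rep(p$width, 20))
  expect_equal(mids - lefts, rep(p$width / 2, 20))
  expect_error(score_from_rank(21, p), "rank outside")
  expect_error(score_from_rank(0, p), "rank outside")
})

test_that("decode/label round-trip holds for every rank and odd partitions", {
  for (p in list(interval_partition(0, 1, 20),
                 interval_partition(0, 1, 5),
                 interval_partition(0.2, 0.9, 7))) {
    r <- seq_len(p$K)
    expect_equal(label_of_score(score_from_rank(r, p, "mid"), p), r)
  }
})

test_that("PPI call is strictly greater-than and monotone over the sweep", {
  expect_true(call_ppi(0.51, 0.5))
  expect_false(call_ppi(0.5, 0.5))
  set.seed(3)
  scores <- runif(500)
  counts <- vapply(seq(0.1, 0.9, by = 0.1),
                   function(th) sum(call_ppi(scores, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cross-entropy: ln 2 at indifference, ~0 at certainty, oracle match", {
  set.seed(4)
  # zeroed head always outputs (0.5, 0.5)
  head <- ordppi:::new_mlp_head(3, 4, 2, 0.01)
  head$W1[] <- 0; head$W2[] <- 0; head$b1[] <- 0; head$b2[] <- 0
  X <- matrix(rnorm(30), 10, 3)
  y <- sample(c(-1L, 1L), 10, TRUE)
  expect_equal(cross_entropy_loss(X, y, head), log(2), tolerance = 1e-12)

  # confident correct head: loss near zero
  conf <- head
  conf$b2 <- c(30, -30)
  expect_lt(cross_entropy_loss(X, rep(1L, 10), conf), 1e-10)

  # per-item summation oracle on a random head
  rhead <- ordppi:::new_mlp_head(3, 4, 2, 0.01)
  P <- subclassifier_forward(X, rhead)
  manual <- -mean(log(ifelse(y > 0, P[, 1], P[, 2])))
  expect_equal(cross_entropy_loss(X, y, rhead), manual, tolerance = 1e-12)
})

test_that("regression head outputs a deterministic scalar inside the range", {
  set.seed(5)
  p <- interval_partition(0, 1, 5)
  head <- ordppi:::new_mlp_head(6, 8, 1, 0.01)
  x <- rnorm(6)
  y <- regression_head_forward(x, head, p)
  expect_length(y, 1L)
  expect_identical(y, regression_head_forward(x, head, p))
  big <- head; big$b2 <- 100
  expect_lt(regression_head_forward(x, big, p), 1)
  small <- head; small$b2 <- -100
  expect_gt(regression_head_forward(x, small, p), 0)
})

test_that("an ordinal model carries exactly K - 1 sub-classifiers", {
  m <- ordinal_model(interval_partition(0, 1, 20),
                     rcnn_config(num_units = 1L, hidden = 4L),
                     eh_table(), max_len = 60)
  expect_length(m$heads, 19L)
  m5 <- ordinal_model(interval_partition(0, 1, 5),
                      rcnn_config(num_units = 1L, hidden = 4L),
                      eh_table(), max_len = 60)
  expect_length(m5$heads, 4L)
})

test_that("predict_pairs is symmetric under pair order and thresholds strictly", {
  set.seed(6)
  recs <- random_records(6, c(50, 60), seed = 6)
  ids <- vapply(recs, `[[`, "", "id")
  m <- ordinal_model(interval_partition(0, 1, 5),
                     rcnn_config(num_units = 1L, hidden = 4L),
                     eh_table(), max_len = 60, seed = 2)
  pairs <- data.frame(id1 = ids[c(1, 3, 5)], id2 = ids[c(2, 4, 6)])
  swapped <- data.frame(id1 = pairs$id2, id2 = pairs$id1)
  a <- predict_pairs(m, pairs, recs)
  b <- predict_pairs(m, swapped, recs)
  expect_equal(a$rank, b$rank)
  expect_equal(a$score, b$score)
  expect_true(all(a$rank == 1L + rowSums(attr(a, "decisions") > 0)))
  withcall <- predict_pairs(m, pairs, recs, theta = a$score[1])
  expect_false(withcall$call[1])  # strict inequality
})
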