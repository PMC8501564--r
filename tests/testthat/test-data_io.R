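test_that("FASTA round-trip: ids from first header token, sequences uppercased", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "mkvl", "AADD",
               ">P2", "ACDEFGHIKLMNPQRSTVWY"), path)
  recs <- read_fasta(path)
  expect_length(recs, 2L)
  expect_equal(vapply(recs, `[[`, "", "id"), c("P1", "P2"))
  expect_equal(recs[[1]]$residues, "MKVLAADD")  # multi-line joined, uppercased
  expect_false(recs[[2]]$has_unknown)
})

test_that("FASTA edge cases: empty file, sequence before header, bad characters", {
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_identical(read_fasta(empty), list())

  bad <- tempfile(fileext = ".fasta")
  writeLines(c("MKVL", ">P1", "ACDE"), bad)
  expect_error(read_fasta(bad), "line 1")

  digits <- tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKV2L"), digits)
  expect_error(read_fasta(digits))

  expect_error(read_fasta(tempfile()), "not found")
})

test_that("unknown residues are kept but flagged", {
  r <- protein_record("u1", "MKVXLLB")
  expect_true(r$has_unknown)
  expect_error(protein_record("u2", ""), "empty")
})

test_that("pair table parsing enforces the open (0,1) score interval", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.72", "A\tC\t1.0", "B\tC\t0.05", "C\tD\t0", "D\tE\t0.999\textra"),
             path)
  expect_message(tab <- read_pair_table(path), "2 pair\\(s\\) rejected")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$score, c(0.72, 0.05, 0.999))  # 0.05 is an interior point
  expect_equal(attr(tab, "n_rejected"), 2L)

  nonnum <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.5", "A\tC\thigh"), nonnum)
  expect_error(read_pair_table(nonnum), "row 2")
  expect_error(read_pair_table(tempfile()), "not found")
})

test_that("pair table header flag skips the first line", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id1\tid2\tscore", "A\tB\t0.72"), path)
  tab <- read_pair_table(path, header = TRUE)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$score, 0.72)
})

test_that("length filter keeps the closed [min, max] range in order", {
  recs <- list(protein_record("a", strrep("A", 49)),
               protein_record("b", strrep("C", 50)),
               protein_record("c", strrep("D", 2000)),
               protein_record("d", strrep("E", 2001)))
  kept <- filter_by_length(recs, 50, 2000)
  expect_equal(vapply(kept, `[[`, "", "id"), c("b", "c"))
})

test_that("balance_subsample caps each label class deterministically", {
  pairs <- data.frame(id1 = paste0("a", 1:1000), id2 = paste0("b", 1:1000),
                      score = runif(1000, 0.01, 0.99))
  pairs$label <- rep(1:2, c(300, 700))
  out <- balance_subsample(pairs, cap = 500, seed = 11)
  expect_equal(as.integer(table(out$label)), c(300L, 500L))  # small class whole
  out2 <- balance_subsample(pairs, cap = 500, seed = 11)
  expect_identical(out, out2)
  expect_identical(balance_subsample(pairs, cap = 5000, seed = 1)$id1, pairs$id1)
  expect_error(balance_subsample(pairs, cap = 0, seed = 1), "positive")
  expect_error(balance_subsample(pairs[, 1:3], cap = 10, seed = 1), "label")
})

test_that("stratified split follows the 90/10 protocol with half-up rounding", {
  pairs <- data.frame(id1 = paste0("a", 1:5400), id2 = paste0("b", 1:5400),
                      score = runif(5400, 0.01, 0.99), label = 1L)
  sp <- split_train_test(pairs, 0.9, seed = 5)
  expect_equal(nrow(sp$train), 4860L)
  expect_equal(nrow(sp$test), 540L)

  pairs2 <- data.frame(id1 = paste0("a", 1:100), id2 = paste0("b", 1:100),
                       score = runif(100, 0.01, 0.99), label = rep(1:2, 50))
  sp2 <- split_train_test(pairs2, 0.5, seed = 5)
  expect_equal(nrow(sp2$train), 50L)
  expect_equal(nrow(sp2$test), 50L)

  # .5 ties go to training: 5 items at 0.5 -> 3 train (floor(2.5+0.5))
  pairs3 <- data.frame(id1 = letters[1:5], id2 = LETTERS[1:5],
                       score = runif(5, 0.1, 0.9), label = 1L)
  sp3 <- split_train_test(pairs3, 0.5, seed = 5)
  expect_equal(nrow(sp3$train), 3L)
})

test_that("split outputs partition the input per label", {
  set.seed(3)
  pairs <- data.frame(id1 = as.character(1:500), id2 = as.character(501:1000),
                      score = runif(500, 0.01, 0.99),
                      label = sample(1:5, 500, TRUE))
  sp <- split_train_test(pairs, 0.8, seed = 9)
  got <- rbind(sp$train, sp$test)
  expect_equal(nrow(got), nrow(pairs))
  expect_setequal(paste(got$id1, got$id2), paste(pairs$id1, pairs$id2))
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0L)
  for (k in 1:5) {
    n_k <- sum(pairs$label == k)
    expect_equal(sum(sp$train$label == k), floor(0.8 * n_k + 0.5))
  }
  expect_warning(split_train_test(pairs[1, ], 0.9, seed = 1), "entirely to training")
})

test_that("prediction TSV round-trips exactly, with >= 4 decimal scores", {
  preds <- data.frame(id1 = c("A", "B"), id2 = c("B", "C"),
                      rank = c(1L, 15L), score = c(0.025, 0.725),
                      call = c(FALSE, TRUE))
  path <- tempfile(fileext = ".tsv")
  write_predictions(preds, path)
  lines <- readLines(path)
  expect_equal(lines[[1L]], "id1\tid2\trank\tconfidence_score\tppi_call")
  expect_match(lines[[2L]], "0\\.025000")  # K=20 mid-points distinguishable
  back <- read_predictions(path)
  expect_identical(back$rank, preds$rank)
  expect_equal(back$score, preds$score)
  expect_identical(back$call, preds$call)

  empty <- preds[0, ]
  path2 <- tempfile(fileext = ".tsv")
  write_predictions(empty, path2)
  expect_length(readLines(path2), 1L)  # header only
  expect_error(write_predictions(preds, file.path(tempdir(), "no/such/dir/x.tsv")))
})

test_that("filter -> label -> balance -> split is deterministic under a fixed seed", {
  run <- function() {
    cfg <- synthetic_config(n_sequences = 40L, n_pairs = 300L, seed = 21L)
    recs <- filter_by_length(gen_sequences(cfg), 50, 2000)
    pairs <- label_pairs(gen_scored_pairs(recs, cfg), interval_partition(0, 1, 5))
    sp <- split_train_test(balance_subsample(pairs, 60, seed = 2), 0.9, seed = 3)
    sp
  }
  a <- run(); b <- run()
  expect_identical(a, b)
  prepped <- rbind(a$train, a$test)
  expect_true(all(prepped$score > 0 & prepped$score < 1))
})
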