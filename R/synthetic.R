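#' Synthetic data configuration
#'
#' Desk-scale defaults: 300 sequences of length 50-120, 3000 pairs, a K = 5
#' partition, score noise 0.05 and clipping to (0.02, 0.98). These sizes
#' train in minutes on one CPU while preserving the structure of the real
#' preparation protocol.
#'
#' @param n_sequences number of sequences.
#' @param length_range inclusive length bounds, within `[50, 2000]`.
#' @param n_pairs number of scored pairs.
#' @param K number of score sub-intervals for downstream labeling.
#' @param noise_sd standard deviation of the Gaussian score noise.
#' @param seed integer seed; every generator is a pure function of this
#'   config.
#' @param score_floor,score_ceiling clipping bounds inside (0, 1).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sequences = 300L, length_range = c(50L, 120L),
                             n_pairs = 3000L, K = 5L, noise_sd = 0.05,
                             seed = 1L, score_floor = 0.02,
                             score_ceiling = 0.98) {
  stopifnot(length_range[1] >= 50, length_range[2] <= 2000,
            length_range[1] <= length_range[2],
            score_floor > 0, score_floor < score_ceiling, score_ceiling < 1,
            noise_sd >= 0)
  structure(list(n_sequences = as.integer(n_sequences),
                 length_range = as.integer(length_range),
                 n_pairs = as.integer(n_pairs), K = as.integer(K),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 score_floor = score_floor, score_ceiling = score_ceiling),
            class = "synthetic_config")
}

#' Generate random protein sequences
#'
#' Residues are i.i.d. uniform over the 20-letter alphabet; lengths are
#' uniform over `length_range`. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list of [protein_record()] with ids `seq00001`, ...
#' @export
gen_sequences <- function(config = synthetic_config()) {
  if (config$n_sequences == 0L) return(list())
  withr_seed(config$seed, {
    lens <- sample(config$length_range[1]:config$length_range[2],
                   config$n_sequences, replace = TRUE)
    lapply(seq_len(config$n_sequences), function(i) {
      protein_record(sprintf("seq%05d", i),
                     paste(sample(AA_ALPHABET, lens[i], replace = TRUE),
                           collapse = ""))
    })
  })
}

# pair similarity statistic behind the planted score: cosine of the two
# sequences' 7-class composition deviations from the expected composition
# of a uniform-residue sequence. Centering is what spreads the statistic
# over (-1, 1): raw compositions of uniform sequences all hug the expected
# frequencies, so their raw cosines pile up near 1 and carry almost no
# ordinal signal.
.expected_composition <- lengths(AA_CLASSES) / 20

pair_composition_similarity <- function(res1, res2) {
  u <- .class_composition(res1) - .expected_composition
  v <- .class_composition(res2) - .expected_composition
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Generate scored pairs with a planted monotone structure
#'
#' Pairs are sampled uniformly (with replacement) from the records. The true
#' score is `clip(0.5 + 0.5 * sim + noise, floor, ceiling)` where `sim` is
#' the cosine similarity of the two sequences' centered 7-class composition
#' vectors -- a monotone function of pair-composition similarity that the
#' encoder can learn. A sequence paired with itself at zero noise scores
#' exactly the ceiling (cosine 1, clipped).
#'
#' @param records list of at least two [protein_record()].
#' @param config a [synthetic_config()].
#' @return a pair table (`id1`, `id2`, `score`) with the planted similarity
#'   attached as column `similarity`.
#' @export
gen_scored_pairs <- function(records, config = synthetic_config()) {
  if (length(records) < 2L) stop("need at least two records to form pairs")
  withr_seed(config$seed + 1L, {
    n <- length(records)
    i1 <- sample.int(n, config$n_pairs, replace = TRUE)
    i2 <- sample.int(n, config$n_pairs, replace = TRUE)
    sim <- vapply(seq_len(config$n_pairs), function(j) {
      pair_composition_similarity(records[[i1[j]]]$residues,
                                  records[[i2[j]]]$residues)
    }, numeric(1))
    raw <- 0.5 + 0.5 * sim +
      if (config$noise_sd > 0) rnorm(config$n_pairs, 0, config$noise_sd) else 0
    score <- pmin(pmax(raw, config$score_floor), config$score_ceiling)
    data.frame(id1 = vapply(records[i1], `[[`, "", "id"),
               id2 = vapply(records[i2], `[[`, "", "id"),
               score = score, similarity = sim, stringsAsFactors = FALSE)
  })
}

#' Generate a skip-gram test corpus with planted co-occurrence
#'
#' Sequences are drawn from a first-order Markov chain in which each member
#' of a planted symbol pair jumps to its partner with probability
#' `partner_prob`, while `forbidden` symbol pairs never sit adjacent. The
#' planted adjacencies therefore occur far above the uniform expectation,
#' giving skip-gram a recoverable co-occurrence structure.
#'
#' @param config a [synthetic_config()] (`n_sequences`, `length_range`,
#'   `seed` are used).
#' @param planted list of symbol pairs to over-represent.
#' @param forbidden list of symbol pairs that never co-occur adjacently.
#' @param partner_prob jump probability to the planted partner.
#' @return list of [protein_record()]; the planted structure is attached as
#'   attributes `planted`, `forbidden` and `partner_prob`.
#' @export
gen_skipgram_corpus <- function(config = synthetic_config(),
                                planted = list(c("A", "G"), c("C", "M")),
                                forbidden = list(c("A", "W")),
                                partner_prob = 0.5) {
  trans <- matrix(1 / 20, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (pr in planted) {
    trans[pr[1], ] <- (1 - partner_prob) / 20
    trans[pr[1], pr[2]] <- trans[pr[1], pr[2]] + partner_prob
    trans[pr[2], ] <- (1 - partner_prob) / 20
    trans[pr[2], pr[1]] <- trans[pr[2], pr[1]] + partner_prob
  }
  for (fb in forbidden) {
    trans[fb[1], fb[2]] <- 0
    trans[fb[2], fb[1]] <- 0
  }
  trans <- trans / rowSums(trans)
  recs <- withr_seed(config$seed + 2L, {
    lens <- sample(config$length_range[1]:config$length_range[2],
                   config$n_sequences, replace = TRUE)
    lapply(seq_len(config$n_sequences), function(i) {
      s <- character(lens[i])
      s[1] <- sample(AA_ALPHABET, 1L)
      for (t in seq_len(lens[i] - 1L)) {
        s[t + 1L] <- sample(AA_ALPHABET, 1L, prob = trans[s[t], ])
      }
      protein_record(sprintf("cor%05d", i), paste(s, collapse = ""))
    })
  })
  attr(recs, "planted") <- planted
  attr(recs, "forbidden") <- forbidden
  attr(recs, "partner_prob") <- partner_prob
  recs
}

#' Write a complete synthetic fixture to disk
#'
#' Emits FASTA (`sequences.fasta`), a scored-pair TSV (`pairs.tsv`) and a
#' key=value metadata file (`metadata.txt`) recording the configuration, so
#' every downstream stage is testable without any download.
#'
#' @param dir output directory (created if needed).
#' @param config a [synthetic_config()].
#' @return invisibly, the list of written paths.
#' @export
write_synthetic_fixture <- function(dir, config = synthetic_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- gen_sequences(config)
  pairs <- gen_scored_pairs(records, config)
  fasta <- file.path(dir, "sequences.fasta")
  writeLines(unlist(lapply(records, function(r) c(paste0(">", r$id), r$residues))),
             fasta)
  tsv <- file.path(dir, "pairs.tsv")
  data.table::fwrite(pairs[, c("id1", "id2", "score")], tsv, sep = "\t",
                     col.names = FALSE)
  meta <- file.path(dir, "metadata.txt")
  writeLines(c(
    paste0("generator=planted-composition-similarity"),
    vapply(names(unclass(config)), function(nm) {
      paste0(nm, "=", paste(config[[nm]], collapse = ","))
    }, character(1))
  ), meta)
  invisible(list(fasta = fasta, pairs = tsv, metadata = meta))
}
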