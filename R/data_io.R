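#' Construct a protein record
#'
#' A protein record is an identifier plus an upper-case residue string over
#' the 20-letter amino-acid alphabet. Letters outside the standard alphabet
#' (e.g. X, B, Z, U) are tolerated but flagged via the `has_unknown` field;
#' the embedding layer later maps them to the zero vector, so they behave
#' like padding.
#'
#' @param id free-text identifier.
#' @param residues residue string (letters only).
#' @return an object of class `protein_record` with fields `id`, `residues`,
#'   `length` and `has_unknown`.
#' @export
protein_record <- function(id, residues) {
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("protein record '", id, "': empty sequence")
  if (grepl("[^A-Z]", residues)) {
    bad <- regmatches(residues, regexpr("[^A-Z]", residues))
    stop("protein record '", id, "': invalid residue character '", bad, "'")
  }
  structure(
    list(id = as.character(id), residues = residues,
         length = nchar(residues),
         has_unknown = anyNA(.residue_indices(residues))),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa%s)\n", x$id, x$length,
              if (x$has_unknown) ", non-standard residues" else ""))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; a cheap pre-scan
#' rejects files whose first non-empty line is not a header, naming the
#' offending line. Header tokens before the first whitespace become record
#' ids and sequences are upper-cased. Digits or other non-letter characters
#' in a sequence are a parse error.
#'
#' @param path path to a FASTA file (multi-line sequences allowed).
#' @return a list of [protein_record()] objects (empty for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(list())
  first <- nonempty[[1L]]
  if (!startsWith(trimws(lines[[first]]), ">")) {
    stop("malformed FASTA at line ", first,
         ": sequence data before the first '>' header")
  }
  aa <- withCallingHandlers(
    tryCatch(
      Biostrings::readAAStringSet(path),
      error = function(e) stop("malformed FASTA file '", path, "': ",
                               conditionMessage(e))
    ),
    warning = function(w) {
      # Biostrings silently drops invalid codes; treat that as a parse error
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("malformed FASTA file '", path,
             "': invalid sequence characters (non-amino-acid codes)")
      }
      invokeRestart("muffleWarning")
    }
  )
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad)) {
    stop("malformed FASTA record '", ids[bad][[1L]],
         "': non-letter characters in sequence")
  }
  unname(Map(protein_record, ids, seqs))
}

#' Read a scored-pair table
#'
#' Expects a TSV with at least three columns `id1 <TAB> id2 <TAB> score`
#' (further columns ignored, no header by default -- STRING exports vary).
#' Scores must be real numbers in the open interval (0, 1); rows outside it
#' are dropped with a reported count, matching the open first sub-interval of
#' the score partition.
#'
#' @param path path to the TSV file.
#' @param header logical; skip a header line first.
#' @return a `data.frame` with columns `id1`, `id2`, `score`; the number of
#'   rejected rows is attached as attribute `n_rejected`.
#' @export
read_pair_table <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("pair table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = header,
                          colClasses = "character", fill = TRUE,
                          data.table = FALSE)
  if (nrow(dt) == 0L) {
    out <- data.frame(id1 = character(), id2 = character(), score = numeric())
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  if (ncol(dt) < 3L) stop("pair table needs >= 3 columns (id1, id2, score), got ",
                          ncol(dt))
  score <- suppressWarnings(as.numeric(dt[[3L]]))
  if (anyNA(score)) {
    stop("pair table row ", which(is.na(score))[[1L]],
         ": non-numeric score '", dt[[3L]][is.na(score)][[1L]], "'")
  }
  keep <- score > 0 & score < 1
  n_rejected <- sum(!keep)
  if (n_rejected > 0L) {
    message(n_rejected, " pair(s) rejected: score outside the open interval (0, 1)")
  }
  out <- data.frame(id1 = dt[[1L]][keep], id2 = dt[[2L]][keep],
                    score = score[keep], stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Keep records whose sequence length lies within bounds
#'
#' @param records list of [protein_record()] objects.
#' @param min_len,max_len inclusive length bounds (defaults 50 and 2000,
#'   the preparation rule applied to the STRING-derived data).
#' @return the filtered list, input order preserved.
#' @export
filter_by_length <- function(records, min_len = 50L, max_len = 2000L) {
  stopifnot(min_len <= max_len)
  keep <- vapply(records, function(r) r$length >= min_len && r$length <= max_len,
                 logical(1))
  records[keep]
}

#' Cap the size of each label class by uniform subsampling
#'
#' Mirrors the preparation of the real data sets, where over-populated score
#' sub-intervals were capped (5400 pairs per sub-interval) while small ones
#' were kept whole.
#'
#' @param pairs labeled pair table (needs a `label` column, see
#'   [label_pairs()]).
#' @param cap maximum number of pairs retained per label.
#' @param seed integer seed making the subsample reproducible.
#' @return the subsampled pair table (row order: by label, then original).
#' @export
balance_subsample <- function(pairs, cap, seed) {
  if (is.null(pairs$label)) stop("pairs must carry labels; run label_pairs() first")
  if (cap <= 0) stop("cap must be a positive integer")
  rows <- withr_seed(seed, {
    unlist(lapply(split(seq_len(nrow(pairs)), pairs$label), function(idx) {
      if (length(idx) > cap) sort(sample(idx, cap)) else idx
    }), use.names = FALSE)
  })
  pairs[rows, , drop = FALSE]
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stratified train/test split of labeled pairs
#'
#' Each label class is split independently: `round(train_fraction * n_k)`
#' pairs go to the training set (ties at .5 rounded up, i.e. to training),
#' the remainder to the test set. A class with fewer than two members goes
#' entirely to training with a warning.
#'
#' @param pairs labeled pair table.
#' @param train_fraction fraction in (0, 1); 0.9 reproduces the 90/10
#'   protocol used on the real data.
#' @param seed integer seed.
#' @return a list with elements `train` and `test`.
#' @export
split_train_test <- function(pairs, train_fraction = 0.9, seed = 1L) {
  if (is.null(pairs$label)) stop("pairs must carry labels; run label_pairs() first")
  stopifnot(train_fraction > 0, train_fraction < 1)
  train_rows <- withr_seed(seed, {
    unlist(lapply(split(seq_len(nrow(pairs)), pairs$label), function(idx) {
      n <- length(idx)
      if (n < 2L) {
        warning("label class with ", n, " member(s): assigned entirely to training")
        return(idx)
      }
      n_train <- floor(train_fraction * n + 0.5)  # half-up: ties to training
      sort(sample(idx, n_train))
    }), use.names = FALSE)
  })
  list(train = pairs[train_rows, , drop = FALSE],
       test = pairs[setdiff(seq_len(nrow(pairs)), train_rows), , drop = FALSE])
}

#' Write predictions to a TSV file
#'
#' Columns: `id1`, `id2`, `rank`, `confidence_score`, `ppi_call`, with a
#' header line. Scores are printed with six decimals so that all K = 20
#' sub-interval mid-points stay distinguishable.
#'
#' @param preds prediction table as returned by [predict_pairs()].
#' @param path output path.
#' @export
write_predictions <- function(preds, path) {
  out <- data.frame(
    id1 = preds$id1, id2 = preds$id2, rank = preds$rank,
    confidence_score = sprintf("%.6f", preds$score),
    ppi_call = if (is.null(preds$call)) NA else preds$call
  )
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write predictions to: ", path)
  invisible(path)
}

#' Read back a prediction TSV written by [write_predictions()]
#' @param path path to the prediction file.
#' @return a `data.frame` with columns `id1`, `id2`, `rank`, `score`, `call`.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  data.frame(id1 = as.character(dt$id1), id2 = as.character(dt$id2),
             rank = as.integer(dt$rank),
             score = as.numeric(dt$confidence_score),
             call = if (all(is.na(dt$ppi_call))) NA else as.logical(dt$ppi_call),
             stringsAsFactors = FALSE)
}
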