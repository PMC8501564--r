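#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return a list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

# tally counts from logical prediction/truth vectors
count_confusion <- function(pred, truth) {
  confusion_counts(tp = sum(pred & truth), fp = sum(pred & !truth),
                   tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' The five classification criteria from confusion counts
#'
#' accuracy = (tp+tn)/total, precision = tp/(tp+fp), recall (sensitivity) =
#' tp/(tp+fn), specificity = tn/(tn+fp), F1 = 2 P R / (P + R). A metric
#' whose denominator is zero is reported as `NA` (undefined), never silently
#' coerced to 0.
#'
#' @param c a [confusion_counts()].
#' @return named list with `accuracy`, `precision`, `recall`, `specificity`,
#'   `f1`.
#' @export
confusion_metrics <- function(c) {
  total <- c$tp + c$fp + c$tn + c$fn
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- sdiv(c$tp, c$tp + c$fp)
  recall <- sdiv(c$tp, c$tp + c$fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(accuracy = sdiv(c$tp + c$tn, total), precision = precision,
       recall = recall, specificity = sdiv(c$tn, c$tn + c$fp), f1 = f1)
}

#' MAE and MSE of predicted confidence scores
#'
#' @param pred,truth equal-length numeric vectors.
#' @return a list of class `score_errors` with fields `mae` and `mse`
#'   (always `mae^2 <= mse`).
#' @export
score_errors <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth have different lengths (", length(pred), " vs ",
         length(truth), ")")
  }
  if (length(pred) == 0L) stop("empty score vectors")
  err <- pred - truth
  out <- structure(list(mae = mean(abs(err)), mse = mean(err^2)),
                   class = "score_errors")
  stopifnot(out$mae^2 <= out$mse + 1e-12)
  out
}

#' Evaluate one sub-classifier on test pairs
#'
#' Relabels the test pairs by `label > k`, runs sub-classifier k on the
#' fused pair encodings, and reports the five confusion criteria. The
#' reported trio in the reference analysis is k in {5, 10, 15} at K = 20.
#'
#' @param model a trained [ordinal_model()].
#' @param k sub-classifier index in `1..K-1`.
#' @param test_pairs labeled pair table.
#' @param records list of [protein_record()].
#' @return the [confusion_metrics()] list, with counts attached as attribute
#'   `counts`.
#' @export
eval_subclassifier <- function(model, k, test_pairs, records) {
  stopifnot(k >= 1, k <= model$partition$K - 1L)
  if (is.null(test_pairs$label)) stop("test_pairs must carry ordinal labels")
  enc <- encode_pair_table(model, test_pairs, records)
  P <- subclassifier_forward(enc$X, model$heads[[k]])
  pred <- decide_fk(P[, 1L], P[, 2L]) > 0
  truth <- test_pairs$label > k
  cc <- count_confusion(pred, truth)
  out <- confusion_metrics(cc)
  attr(out, "counts") <- cc
  out
}

#' Metrics across a sweep of PPI thresholds
#'
#' For each theta, both the predicted and the true interaction status are
#' the strict threshold call `score > theta` on the predicted and true
#' confidence scores respectively; the five criteria are reported per row.
#'
#' @param pred predicted confidence scores.
#' @param truth true confidence scores.
#' @param thetas thresholds, default `0.1, 0.2, ..., 0.9`.
#' @return a `data.frame`, one row per theta (ordered), with the five
#'   metrics and the positive-call count; undefined metrics are `NA`.
#' @export
threshold_sweep <- function(pred, truth, thetas = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(length(pred) == length(truth))
  thetas <- sort(thetas)
  rows <- lapply(thetas, function(th) {
    m <- confusion_metrics(count_confusion(call_ppi(pred, th),
                                           call_ppi(truth, th)))
    data.frame(theta = th, accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, specificity = m$specificity, f1 = m$f1,
               n_positive = sum(call_ppi(pred, th)))
  })
  do.call(rbind, rows)
}

#' Percent reduction of a metric relative to a reference
#'
#' `100 * (reference - new) / reference`; e.g. an MAE falling from 12.210 to
#' 6.131 is a 49.79 percent reduction.
#'
#' @param reference baseline value (non-zero).
#' @param new new value.
#' @return percent change (positive = reduction).
#' @export
percent_change <- function(reference, new) {
  if (reference == 0) stop("reference value must be non-zero")
  100 * (reference - new) / reference
}
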