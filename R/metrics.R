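# Binary-classification metrics for binding-site evaluation.

#' Confusion counts for a predicted position set
#'
#' @param pred Predicted positive positions (subset of `universe`).
#' @param truth True positive positions (subset of `universe`).
#' @param universe All evaluable positions.
#' @return Tibble with one row: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, truth, universe) {
  if (!all(pred %in% universe)) abort("pred contains positions outside the universe")
  if (!all(truth %in% universe)) abort("truth contains positions outside the universe")
  pred <- unique(pred); truth <- unique(truth)
  tp <- length(intersect(pred, truth))
  fp <- length(setdiff(pred, truth))
  fn <- length(setdiff(truth, pred))
  tn <- length(universe) - tp - fp - fn
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Binding-site evaluation metrics from confusion counts
#'
#' Computes sensitivity `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`,
#' precision `PRE = TP/(TP+FP)`, accuracy `ACC = (TP+TN)/all`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`,
#' `Strength = (SN+SP)/2` and `F = 2*PRE*SN/(PRE+SN)`. A metric whose
#' denominator is zero is reported as 0 and named in the `flagged`
#' list-column (keeps per-target averaging total).
#'
#' @param counts Data frame with columns `tp`, `fp`, `tn`, `fn` (one or
#'   more rows), or four scalars via `tp`, `fp`, `tn`, `fn`.
#' @return Tibble with columns `sn`, `sp`, `pre`, `acc`, `mcc`,
#'   `strength`, `f` and `flagged` (character vector of zero-denominator
#'   metrics per row).
#' @export
evaluate_confusion <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  one <- function(tp, fp, tn, fn) {
    if (tp + fp + tn + fn < 1) abort("empty confusion table")
    flagged <- character()
    div <- function(num, den, name) {
      if (den == 0) { flagged <<- c(flagged, name); 0 } else num / den
    }
    sn <- div(tp, tp + fn, "sn")
    sp <- div(tn, tn + fp, "sp")
    pre <- div(tp, tp + fp, "pre")
    acc <- (tp + tn) / (tp + fp + tn + fn)
    mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fp, tn + fn)))
    mcc <- div(tp * tn - fp * fn, mcc_den, "mcc")
    strength <- (sn + sp) / 2
    f <- div(2 * pre * sn, pre + sn, "f")
    tibble::tibble(sn = sn, sp = sp, pre = pre, acc = acc, mcc = mcc,
                   strength = strength, f = f, flagged = list(flagged))
  }
  dplyr::bind_rows(purrr::pmap(counts[, c("tp", "fp", "tn", "fn")], one))
}

#' Rank-based AUC (Mann-Whitney with midrank ties)
#'
#' Area under the ROC curve computed from the rank statistic: the
#' probability that a randomly chosen positive scores above a randomly
#' chosen negative, counting ties as one half.
#'
#' @param score Numeric prediction scores (higher = more positive).
#' @param label Logical or 0/1 truth labels.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when only one class
#'   is present.
#' @export
auc <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), !anyNA(label))
  n_pos <- sum(label); n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0) {
    warn("AUC undefined with a single class")
    return(NA_real_)
  }
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
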