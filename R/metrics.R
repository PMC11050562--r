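# Binary-classification metric suite: the nine confusion-based and ranking
# metrics reported for the ADR tasks (accuracy, recall rate, precision,
# MCC, BACC, F1 score, AUROC, AUPRC, specificity).

#' Confusion counts from hard labels
#'
#' @param y_true,y_pred Character vectors over
#'   `{"positive", "negative"}` of equal length.
#' @return A `confusion_counts` list: `TP`, `FP`, `TN`, `FN` plus derived
#'   `TPR`, `TNR`, `FPR` (NA when undefined).
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0L) {
    stop("input error: y_true and y_pred must have equal positive length",
         call. = FALSE)
  }
  stopifnot(all(y_true %in% c("positive", "negative")),
            all(y_pred %in% c("positive", "negative")))
  tp <- sum(y_true == "positive" & y_pred == "positive")
  fp <- sum(y_true == "negative" & y_pred == "positive")
  tn <- sum(y_true == "negative" & y_pred == "negative")
  fn <- sum(y_true == "positive" & y_pred == "negative")
  structure(
    list(TP = tp, FP = fp, TN = tn, FN = fn,
         TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         TNR = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         FPR = if (fp + tn > 0) fp / (fp + tn) else NA_real_),
    class = "confusion_counts"
  )
}

#' Nine-metric report from confusion counts and scores
#'
#' Computes accuracy, recall rate, precision, Matthews correlation
#' coefficient, balanced accuracy, F1 score, AUROC, AUPRC and specificity.
#' Degenerate denominators follow the documented conventions: MCC is 0
#' when any marginal is zero; precision/recall/specificity/F1 are 0 when
#' undefined (a degenerate-count warning is issued). AUROC uses the
#' rank-sum (Mann-Whitney) statistic with midrank tie handling; AUPRC uses
#' step-interpolated precision-recall integration.
#'
#' @param counts A `confusion_counts`.
#' @param scores Optional numeric vector of positive-class probabilities
#'   aligned with `y_true`; required for AUROC/AUPRC.
#' @param y_true Required with `scores`.
#' @return A one-row tibble with the nine metrics.
#' @export
compute_metrics <- function(counts, scores = NULL, y_true = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  n <- tp + fp + tn + fn
  degen <- character(0)
  div0 <- function(num, den, what) {
    if (den == 0) {
      degen <<- c(degen, what)
      0
    } else {
      num / den
    }
  }
  accuracy <- (tp + tn) / n
  recall <- div0(tp, tp + fn, "recall")
  precision <- div0(tp, tp + fp, "precision")
  specificity <- div0(tn, tn + fp, "specificity")
  mcc_den <- sqrt(as.double(tp + fp) * as.double(tp + fn) *
                    as.double(tn + fp) * as.double(tn + fn))
  mcc <- if (mcc_den == 0) {
    degen <- c(degen, "mcc")
    0
  } else {
    (as.double(tp) * tn - as.double(fp) * fn) / mcc_den
  }
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  tnr <- if (tn + fp > 0) tn / (tn + fp) else 0
  bacc <- (tpr + tnr) / 2
  f1 <- div0(2 * precision * recall, precision + recall, "f1")
  if (!is.null(scores)) {
    if (is.null(y_true)) {
      stop("input error: y_true is required with scores", call. = FALSE)
    }
    auroc <- auroc_rank(y_true, scores)
    auprc <- auprc_step(y_true, scores)
  } else {
    auroc <- NA_real_
    auprc <- NA_real_
  }
  if (length(degen) > 0L) {
    warning(sprintf("degenerate denominator(s) set to 0: %s",
                    paste(unique(degen), collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(
    accuracy = accuracy, recall_rate = recall, precision = precision,
    mcc = mcc, bacc = bacc, f1 = f1, auroc = auroc, auprc = auprc,
    specificity = specificity
  )
}

#' AUROC by the rank statistic
#'
#' Mann-Whitney formulation with midranks for ties; equivalent to the area
#' under the ROC curve.
#'
#' @param y_true Labels over `{"positive", "negative"}`.
#' @param scores Positive-class scores.
#' @return AUROC in [0, 1]; `NA` if a class is absent.
#' @export
auroc_rank <- function(y_true, scores) {
  pos <- y_true == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUPRC by step interpolation
#'
#' Area under the precision-recall curve using step (not linear)
#' interpolation between operating points, descending over distinct score
#' thresholds.
#'
#' @inheritParams auroc_rank
#' @return AUPRC in [0, 1]; `NA` if no positives.
#' @export
auprc_step <- function(y_true, scores) {
  pos <- y_true == "positive"
  n_pos <- sum(pos)
  if (n_pos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- pos[ord]
  s <- scores[ord]
  # collapse tied scores into single operating points
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(!y)
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cum_tp[last_of_block]
  fp <- cum_fp[last_of_block]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  prev_recall <- c(0, recall[-length(recall)])
  sum((recall - prev_recall) * precision)
}
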