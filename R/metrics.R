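#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts. `tn` may be `NA` when no
#'   negative-candidate universe was supplied.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  vals <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.na(vals) & vals < 0)) rlang::abort("counts must be >= 0")
  structure(as.list(vals), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %s FP %s TN %s FN %s\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Match detections to ground truth and count the confusion table
#'
#' Greedy one-to-one matching in descending score order: each detection
#' claims the unused ground-truth box with the highest IoU at or above the
#' threshold (ties by lower ground-truth index). Matched detections are TP,
#' unmatched detections FP, unclaimed ground-truth boxes FN. True negatives
#' only exist at candidate level, so the number of evaluated negative
#' candidates is an explicit input: `TN = negatives_evaluated - FP`.
#'
#' @param dets Box tibble with a `score` column (may be empty).
#' @param gts Box tibble of ground truth (may be empty).
#' @param iou_threshold Match threshold in (0, 1], default 0.5.
#' @param negatives_evaluated Count of negative candidates that were
#'   evaluated, or `NULL` (TN reported as `NA`).
#' @return A [confusion_counts()].
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5,
                             negatives_evaluated = NULL) {
  if (iou_threshold <= 0 || iou_threshold > 1) {
    rlang::abort("iou_threshold must be in (0, 1]")
  }
  n_det <- if (is.null(dets)) 0L else nrow(dets)
  n_gt <- if (is.null(gts)) 0L else nrow(gts)
  tp <- 0L
  if (n_det > 0 && n_gt > 0) {
    dets <- validate_boxes(dets)
    if (!"score" %in% names(dets)) rlang::abort("detections need a score column")
    gts <- validate_boxes(gts)
    ord <- order(-dets$score, seq_len(n_det))
    iou <- box_iou(dets, gts)
    used <- logical(n_gt)
    for (i in ord) {
      cand <- which(!used & iou[i, ] >= iou_threshold)
      if (length(cand) > 0) {
        best <- cand[which.max(iou[i, cand])]
        used[best] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- n_det - tp
  fn <- n_gt - tp
  tn <- NA_integer_
  if (!is.null(negatives_evaluated)) {
    if (negatives_evaluated < fp) {
      rlang::abort("inconsistent accounting: more false positives than evaluated negatives")
    }
    tn <- as.integer(negatives_evaluated - fp)
  }
  confusion_counts(tp, fp, tn, fn)
}

safe_ratio <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den

#' Compute the five detection indicators from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`, sensitivity
#' (recall) `TP/(TP+FN)`, specificity `TN/(FP+TN)` and the F1 score (harmonic
#' mean of precision and sensitivity). A metric whose denominator is zero or
#' unknown is reported as `NA`, never silently as 0.
#'
#' @param counts A [confusion_counts()].
#' @return A one-row tibble: `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `f1`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (all(c(tp, fp, fn) == 0) && (is.na(tn) || tn == 0)) {
    rlang::abort("all-zero confusion counts: nothing was evaluated")
  }
  precision <- safe_ratio(tp, tp + fp)
  sensitivity <- safe_ratio(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(sensitivity)) NA_real_
        else if (precision + sensitivity == 0) NA_real_
        else 2 * precision * sensitivity / (precision + sensitivity)
  tibble::tibble(
    accuracy = if (is.na(tn)) NA_real_ else
      safe_ratio(tp + tn, tp + fp + tn + fn),
    precision = precision,
    sensitivity = sensitivity,
    specificity = if (is.na(tn)) NA_real_ else safe_ratio(tn, fp + tn),
    f1 = f1
  )
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 p r / (p + r)`. Vectorized.
#'
#' @param precision,recall Numeric vectors in `[0, 1]` with `p + r > 0`.
#' @return Numeric vector of F1 scores.
#' @export
f1_from_pr <- function(precision, recall) {
  if (any(precision + recall <= 0)) {
    rlang::abort("precision + recall must be > 0")
  }
  2 * precision * recall / (precision + recall)
}

#' Assign items to k cross-validation folds
#'
#' Balanced random partition: fold sizes differ by at most one, every item is
#' assigned exactly once, deterministic under the seed.
#'
#' @param n_items Number of items.
#' @param k Number of folds (<= n_items).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, length `n_items`.
#' @export
kfold_split <- function(n_items, k = 5, seed = 1L) {
  if (k > n_items) rlang::abort("k must not exceed the number of items")
  withr::with_seed(seed, sample(rep(seq_len(k), length.out = n_items)))
}

#' Per-fold and pooled metrics
#'
#' @param fold_counts A list of [confusion_counts()], one per fold.
#' @return A tibble with one row per fold plus a pooled row (counts summed
#'   before computing the indicators), identified by the `fold` column.
#' @export
summarize_folds <- function(fold_counts) {
  per <- purrr::imap(fold_counts, function(cc, i) {
    dplyr::bind_cols(tibble::tibble(fold = as.character(i)), compute_metrics(cc))
  })
  tot <- confusion_counts(
    sum(vapply(fold_counts, `[[`, numeric(1), "tp")),
    sum(vapply(fold_counts, `[[`, numeric(1), "fp")),
    if (any(vapply(fold_counts, function(cc) is.na(cc$tn), logical(1))))
      NA_integer_ else sum(vapply(fold_counts, `[[`, numeric(1), "tn")),
    sum(vapply(fold_counts, `[[`, numeric(1), "fn")))
  dplyr::bind_rows(
    dplyr::bind_rows(per),
    dplyr::bind_cols(tibble::tibble(fold = "pooled"), compute_metrics(tot)))
}
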