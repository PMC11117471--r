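#' RPN configuration
#'
#' Thresholds for anchor labeling, suppression and proposal selection.
#'
#' @param pos_iou Anchors with IoU >= this against any ground-truth box are
#'   positive. Default 0.7.
#' @param neg_iou Anchors with best IoU < this are negative. Default 0.3.
#' @param nms_iou Suppression threshold. Default 0.7.
#' @param top_n Number of proposals kept after suppression. Default 300.
#' @return A named list of class `rpn_config`.
#' @export
rpn_config <- function(pos_iou = 0.7, neg_iou = 0.3, nms_iou = 0.7,
                       top_n = 300) {
  if (!(neg_iou >= 0 && neg_iou < pos_iou && pos_iou <= 1)) {
    rlang::abort("need 0 <= neg_iou < pos_iou <= 1")
  }
  structure(list(pos_iou = pos_iou, neg_iou = neg_iou, nms_iou = nms_iou,
                 top_n = as.integer(top_n)), class = "rpn_config")
}

#' Tile anchor shapes over a feature grid
#'
#' One box per (cell, anchor shape), centred at `((j + 0.5) * stride,
#' (i + 0.5) * stride)` for cell row i, column j (0-based). Boxes may extend
#' beyond the image; clip downstream if needed.
#'
#' @param feature_shape Length-2 integer vector `(height, width)` of the
#'   feature grid.
#' @param stride Pixels per feature cell (>= 1).
#' @param anchors An [anchor_set()] or [box_wh()] tibble of shapes.
#' @return A box tibble with `H * W * K` rows and columns `x_min`, `y_min`,
#'   `x_max`, `y_max`, `cell_row`, `cell_col`, `anchor_id`. Order: cells in
#'   row-major order, anchor shapes within each cell.
#' @export
generate_anchor_grid <- function(feature_shape, stride, anchors) {
  shapes <- if (inherits(anchors, "anchor_set")) anchors$shapes else
    tibble::as_tibble(anchors)
  if (nrow(shapes) == 0) rlang::abort("anchor set is empty")
  if (stride < 1) rlang::abort("stride must be >= 1")
  h <- feature_shape[1]; w <- feature_shape[2]
  cells <- tidyr::expand_grid(cell_row = seq_len(h) - 1L,
                              cell_col = seq_len(w) - 1L)
  grid <- tidyr::expand_grid(cells, anchor_id = seq_len(nrow(shapes)))
  cx <- (grid$cell_col + 0.5) * stride
  cy <- (grid$cell_row + 0.5) * stride
  aw <- shapes$width[grid$anchor_id]
  ah <- shapes$height[grid$anchor_id]
  dplyr::bind_cols(
    boxes(cx - aw / 2, cy - ah / 2, cx + aw / 2, cy + ah / 2),
    grid
  )
}

#' Label anchors against ground truth
#'
#' An anchor is positive when its IoU with some ground-truth box reaches
#' `pos_iou`, or when it attains the maximum IoU for some ground-truth box
#' (so every object recruits at least one positive anchor even if all
#' overlaps are weak). It is negative when its best IoU is below `neg_iou`;
#' anything else is ignored. With no ground truth, all anchors are negative.
#'
#' @param anchors Box tibble of anchors.
#' @param gt Box tibble of ground-truth objects (may be empty).
#' @param config An [rpn_config()].
#' @return A tibble with one row per anchor: `label` (factor with levels
#'   positive/negative/ignore), `max_iou`, `best_gt` (index or NA).
#' @export
label_anchors <- function(anchors, gt, config = rpn_config()) {
  anchors <- validate_boxes(anchors)
  n <- nrow(anchors)
  lv <- c("positive", "negative", "ignore")
  if (is.null(gt) || nrow(gt) == 0) {
    return(tibble::tibble(label = factor(rep("negative", n), levels = lv),
                          max_iou = rep(0, n), best_gt = rep(NA_integer_, n)))
  }
  gt <- validate_boxes(gt)
  iou <- box_iou(anchors, gt)
  max_iou <- apply(iou, 1, max)
  best_gt <- apply(iou, 1, which.max)
  label <- rep("ignore", n)
  label[max_iou < config$neg_iou] <- "negative"
  label[max_iou >= config$pos_iou] <- "positive"
  # argmax rule: anchors attaining a ground-truth box's best IoU are positive
  col_best <- apply(iou, 2, max)
  for (g in seq_len(ncol(iou))) {
    if (col_best[g] > 0) label[iou[, g] == col_best[g]] <- "positive"
  }
  tibble::tibble(label = factor(label, levels = lv), max_iou = max_iou,
                 best_gt = ifelse(max_iou > 0, best_gt, NA_integer_))
}

#' Encode ground-truth boxes as offsets relative to anchors
#'
#' The standard detection parameterization: with anchor centre/size
#' `(xa, ya, wa, ha)` and target `(xg, yg, wg, hg)`, the offsets are
#' `((xg - xa)/wa, (yg - ya)/ha, log(wg/wa), log(hg/ha))`.
#'
#' @param gt,anchor Box tibbles of equal length (row-wise pairing).
#' @return A tibble with columns `dx`, `dy`, `dw`, `dh`.
#' @export
encode_offsets <- function(gt, anchor) {
  gt <- validate_boxes(gt); anchor <- validate_boxes(anchor)
  stopifnot(nrow(gt) == nrow(anchor))
  wa <- anchor$x_max - anchor$x_min; ha <- anchor$y_max - anchor$y_min
  if (any(wa <= 0 | ha <= 0)) rlang::abort("anchors must have positive size")
  wg <- gt$x_max - gt$x_min; hg <- gt$y_max - gt$y_min
  tibble::tibble(
    dx = ((gt$x_min + gt$x_max) / 2 - (anchor$x_min + anchor$x_max) / 2) / wa,
    dy = ((gt$y_min + gt$y_max) / 2 - (anchor$y_min + anchor$y_max) / 2) / ha,
    dw = log(wg / wa),
    dh = log(hg / ha)
  )
}

#' Decode offsets relative to anchors back into boxes
#'
#' Inverse of [encode_offsets()]: zero offsets decode to the anchor itself.
#'
#' @param offsets Tibble with columns `dx`, `dy`, `dw`, `dh`.
#' @param anchor Box tibble of the same length.
#' @return A box tibble.
#' @export
decode_offsets <- function(offsets, anchor) {
  anchor <- validate_boxes(anchor)
  stopifnot(nrow(offsets) == nrow(anchor))
  wa <- anchor$x_max - anchor$x_min; ha <- anchor$y_max - anchor$y_min
  cx <- (anchor$x_min + anchor$x_max) / 2 + offsets$dx * wa
  cy <- (anchor$y_min + anchor$y_max) / 2 + offsets$dy * ha
  w <- wa * exp(offsets$dw); h <- ha * exp(offsets$dh)
  boxes(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

# canonical ordering: descending score, then box coordinates; this makes
# suppression deterministic and independent of input row order
nms_order <- function(scored) {
  order(-scored$score, scored$x_min, scored$y_min, scored$x_max, scored$y_max)
}

#' Greedy non-maximum suppression
#'
#' Boxes are visited in descending score order (ties broken by box
#' coordinates, so the result does not depend on input order); a box is kept
#' when its IoU with every already-kept box is below the threshold.
#'
#' @param scored Box tibble with a `score` column.
#' @param iou_threshold Suppression threshold in `(0, 1]`.
#' @return The surviving rows, in descending score order.
#' @export
nms <- function(scored, iou_threshold = 0.7) {
  scored <- validate_boxes(scored)
  if (!"score" %in% names(scored)) rlang::abort("scored boxes need a score column")
  if (nrow(scored) == 0) return(scored)
  ord <- nms_order(scored)
  sorted <- scored[ord, , drop = FALSE]
  keep <- logical(nrow(sorted))
  for (i in seq_len(nrow(sorted))) {
    kept <- which(keep)
    if (length(kept) == 0 ||
        all(box_iou(sorted[i, ], sorted[kept, , drop = FALSE]) < iou_threshold)) {
      keep[i] <- TRUE
    }
  }
  sorted[keep, , drop = FALSE]
}

#' Select the top proposals
#'
#' Non-maximum suppression followed by truncation to the `top_n`
#' highest-scoring survivors.
#'
#' @param scored Box tibble with a `score` column.
#' @param config An [rpn_config()].
#' @return A box tibble with at most `config$top_n` rows, descending score.
#' @export
select_proposals <- function(scored, config = rpn_config()) {
  out <- nms(scored, config$nms_iou)
  utils::head(out, config$top_n)
}
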