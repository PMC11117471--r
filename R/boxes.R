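#' Construct a tibble of axis-aligned boxes
#'
#' Boxes are 0-based, half-open pixel rectangles: a box covers pixel columns
#' `x_min .. x_max - 1` and rows `y_min .. y_max - 1`, so its area is
#' `(x_max - x_min) * (y_max - y_min)`. This convention is used everywhere in
#' the package: ground truth, anchors, proposals and detections.
#'
#' @param x_min,y_min,x_max,y_max Numeric vectors of equal length.
#' @param score Optional numeric vector of objectness scores in `[0, 1]`.
#' @return A tibble with columns `x_min`, `y_min`, `x_max`, `y_max` and,
#'   when supplied, `score`.
#' @examples
#' boxes(0, 0, 10, 10)
#' @export
boxes <- function(x_min = numeric(), y_min = numeric(),
                  x_max = numeric(), y_max = numeric(), score = NULL) {
  out <- tibble::tibble(
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max)
  )
  if (!is.null(score)) out$score <- as.numeric(score)
  validate_boxes(out)
}

#' Validate a box tibble
#'
#' @param box_df A data frame with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @return The input as a tibble, invisibly checked.
#' @export
validate_boxes <- function(box_df) {
  box_df <- tibble::as_tibble(box_df)
  need <- c("x_min", "y_min", "x_max", "y_max")
  missing_cols <- setdiff(need, names(box_df))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("box table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(box_df) > 0) {
    bad <- which(box_df$x_min >= box_df$x_max | box_df$y_min >= box_df$y_max)
    if (length(bad) > 0) {
      rlang::abort(paste0("degenerate box(es) at row(s) ",
                          paste(utils::head(bad, 5), collapse = ", "),
                          ": need x_min < x_max and y_min < y_max"))
    }
    if ("score" %in% names(box_df) &&
        any(box_df$score < 0 | box_df$score > 1, na.rm = TRUE)) {
      rlang::abort("box scores must lie in [0, 1]")
    }
  }
  box_df
}

#' Intersection over union of two sets of boxes
#'
#' Computes the full IoU cross matrix between the rows of `a` and the rows of
#' `b`. For two single boxes the result is a 1 x 1 matrix; use `drop = TRUE`
#' to get a bare number.
#'
#' @param a,b Box tibbles (see [boxes()]).
#' @param drop If `TRUE` and both inputs have one row, return a scalar.
#' @return A `nrow(a)` x `nrow(b)` matrix of IoU values in `[0, 1]`.
#' @examples
#' box_iou(boxes(0, 0, 2, 2), boxes(1, 1, 3, 3), drop = TRUE)  # 1/7
#' @export
box_iou <- function(a, b, drop = FALSE) {
  a <- validate_boxes(a); b <- validate_boxes(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(matrix(numeric(0), nrow = nrow(a), ncol = nrow(b)))
  }
  ix <- pmax(0, outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax))
  iy <- pmax(0, outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  un <- outer(area_a, area_b, `+`) - inter
  out <- inter / un
  if (drop && nrow(a) == 1 && nrow(b) == 1) out[1, 1] else out
}

#' Width/height shape table
#'
#' Anchor shapes and clustered box populations are stored as tibbles with
#' `width` and `height` columns (pixels), with no position: shapes are compared
#' as if co-centred at the origin.
#'
#' @param width,height Positive numeric vectors.
#' @return A tibble with columns `width`, `height`.
#' @export
box_wh <- function(width = numeric(), height = numeric()) {
  out <- tibble::tibble(width = as.numeric(width), height = as.numeric(height))
  if (nrow(out) > 0 && any(out$width <= 0 | out$height <= 0)) {
    rlang::abort("box widths and heights must be > 0")
  }
  out
}

#' IoU between co-centred width/height shapes
#'
#' @param a,b Shape tibbles from [box_wh()].
#' @return A `nrow(a)` x `nrow(b)` IoU matrix.
#' @export
wh_iou <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(matrix(numeric(0), nrow = nrow(a), ncol = nrow(b)))
  }
  inter <- outer(a$width, b$width, pmin) * outer(a$height, b$height, pmin)
  un <- outer(a$width * a$height, b$width * b$height, `+`) - inter
  inter / un
}
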