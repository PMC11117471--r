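#' Preprocessing configuration
#'
#' Tunable parameters of the lung-field extraction pipeline. All thresholds
#' are in Hounsfield units.
#'
#' @param binarize_threshold_hu Air/tissue cut: pixels strictly below this HU
#'   are treated as air-like. Default -400, between lung air (about -850) and
#'   soft tissue (about +40).
#' @param window_hu Length-2 display window mapped linearly onto `[0, 255]`.
#'   Default `c(-1200, 600)` covers lung through bone.
#' @param bone_threshold_hu Pixels above this HU are treated as bone.
#'   Default +300.
#' @param closing_radius_px Disc radius for the per-lung morphological
#'   closing. Default 5.
#' @param expand_radius_px Disc radius of the final per-lung dilation margin.
#'   Default 2.
#' @return A named list of class `preprocess_config`.
#' @export
preprocess_config <- function(binarize_threshold_hu = -400,
                              window_hu = c(-1200, 600),
                              bone_threshold_hu = 300,
                              closing_radius_px = 5,
                              expand_radius_px = 2) {
  stopifnot(length(window_hu) == 2, window_hu[1] < window_hu[2],
            closing_radius_px >= 0, expand_radius_px >= 0)
  structure(list(binarize_threshold_hu = binarize_threshold_hu,
                 window_hu = window_hu,
                 bone_threshold_hu = bone_threshold_hu,
                 closing_radius_px = closing_radius_px,
                 expand_radius_px = expand_radius_px),
            class = "preprocess_config")
}

#' Convert raw scanner values to Hounsfield units
#'
#' The standard linear CT calibration: `HU = raw * slope + intercept`.
#'
#' @param raw Numeric matrix of raw scanner values.
#' @param slope Rescale slope (non-zero).
#' @param intercept Rescale intercept.
#' @param spacing Pixel spacing in mm.
#' @return An [hu_image()].
#' @export
to_hu <- function(raw, slope = 1, intercept = 0, spacing = 1) {
  if (slope == 0) rlang::abort("rescale slope must be non-zero")
  hu_image(raw * slope + intercept, spacing)
}

#' Threshold an HU image into an air-like binary map
#'
#' A pixel is TRUE when its HU value is strictly below the threshold, so the
#' exterior air and the air-filled lungs come out TRUE while soft tissue and
#' bone come out FALSE.
#'
#' @param img An [hu_image()].
#' @param threshold_hu Cut in HU (default -400).
#' @return A logical matrix.
#' @export
binarize_lungs <- function(img, threshold_hu = -400) {
  stopifnot(inherits(img, "hu_image"), is.finite(threshold_hu))
  img$values < threshold_hu
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels that
# touch diagonally with a small union-find pass over the label graph.
label_components8 <- function(binary) {
  lab <- EBImage::bwlabel(binary * 1)
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal pairs
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

disc_brush <- function(radius) {
  if (radius < 1) return(matrix(1, 1, 1))
  EBImage::makeBrush(2 * radius + 1, shape = "disc")
}

# fill the convex hull of the TRUE pixels of a binary matrix (scanline over
# the chull polygon of pixel centres)
convex_fill <- function(binary) {
  idx <- which(binary, arr.ind = TRUE)
  if (nrow(idx) < 3) return(binary)
  px <- idx[, 2] - 0.5  # x = column centre
  py <- idx[, 1] - 0.5  # y = row centre
  h <- grDevices::chull(px, py)
  hx <- px[h]; hy <- py[h]
  k <- length(h)
  out <- binary
  nxt <- c(seq_len(k)[-1], 1)
  rows <- seq_len(nrow(binary)) - 0.5
  for (j in seq_along(rows)) {
    yc <- rows[j]
    xs <- c()
    for (e in seq_len(k)) {
      y1 <- hy[e]; y2 <- hy[nxt[e]]
      if ((y1 <= yc && y2 >= yc) || (y2 <= yc && y1 >= yc)) {
        if (y1 == y2) {
          xs <- c(xs, hx[e], hx[nxt[e]])
        } else {
          xs <- c(xs, hx[e] + (yc - y1) / (y2 - y1) * (hx[nxt[e]] - hx[e]))
        }
      }
    }
    if (length(xs) >= 1) {
      lo <- ceiling(min(xs) + 0.5); hi <- floor(max(xs) + 0.5)
      if (hi >= lo) out[j, lo:hi] <- TRUE
    }
  }
  out
}

#' Extract the lung mask from a binarized slice
#'
#' Follows the classical lung-field recipe: drop every air component that
#' touches the image border (the exterior), split the remaining interior air
#' components into left and right lungs by their horizontal position, then
#' expand each lung by a morphological closing followed by a convex-hull fill
#' so that nodules attached to the lung wall remain covered by the mask.
#'
#' @param binary Logical matrix from [binarize_lungs()].
#' @param closing_radius_px Disc radius for the closing step.
#' @param expand_radius_px Disc radius of the final dilation that adds the
#'   wall margin (default 2), so nodules attached to the lung wall stay
#'   inside the mask.
#' @param min_area_px Interior components smaller than this are treated as
#'   noise and dropped (default 32).
#' @return A [lung_mask()]. When no interior air component survives, an empty
#'   mask is returned with a warning rather than an error.
#' @export
extract_lung_mask <- function(binary, closing_radius_px = 5,
                              expand_radius_px = 2, min_area_px = 32) {
  stopifnot(is.matrix(binary), is.logical(binary))
  lab <- label_components8(binary)
  nr <- nrow(lab); nc <- ncol(lab)
  border_labels <- setdiff(unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc])), 0)
  interior <- lab
  interior[interior %in% border_labels] <- 0
  sizes <- tabulate(interior[interior > 0])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0) {
    rlang::warn("no interior air component found; returning an empty lung mask")
    return(lung_mask(matrix(FALSE, nr, nc), n_components = 0L))
  }
  cx <- vapply(keep, function(l) mean(which(interior == l, arr.ind = TRUE)[, 2]),
               numeric(1))
  mid <- (nc + 1) / 2
  groups <- list(left = keep[cx < mid], right = keep[cx >= mid])
  out <- matrix(FALSE, nr, nc)
  for (g in groups) {
    if (length(g) == 0) next
    part <- interior %in% g
    dim(part) <- c(nr, nc)
    if (closing_radius_px >= 1) {
      part <- EBImage::closing(part * 1, disc_brush(closing_radius_px)) > 0.5
      dim(part) <- c(nr, nc)
    }
    part <- convex_fill(part)
    if (expand_radius_px >= 1) {
      part <- EBImage::dilate(part * 1, disc_brush(expand_radius_px)) > 0.5
      dim(part) <- c(nr, nc)
    }
    out <- out | part
  }
  lung_mask(out, n_components = length(keep))
}

# round half away from zero is not needed; displays use round-half-up
round_half_up <- function(x) floor(x + 0.5)

#' Window an HU image to 8-bit grayscale
#'
#' Linear map of the window onto `[0, 255]` with clipping outside and
#' half-up rounding.
#'
#' @param img An [hu_image()].
#' @param window_hu Length-2 HU window, min < max.
#' @return A [uint8_image()].
#' @export
hu_to_uint8 <- function(img, window_hu = c(-1200, 600)) {
  stopifnot(inherits(img, "hu_image"))
  if (window_hu[1] >= window_hu[2]) rlang::abort("degenerate display window")
  scaled <- (img$values - window_hu[1]) / (window_hu[2] - window_hu[1]) * 255
  uint8_image(matrix(pmin(255, pmax(0, round_half_up(scaled))),
                     nrow(img$values), ncol(img$values)))
}

#' Apply a lung mask to an 8-bit image
#'
#' Pixel-wise product: intensities survive inside the mask and are zeroed
#' outside. Idempotent for a fixed mask.
#'
#' @param img A [uint8_image()].
#' @param mask A [lung_mask()] of the same shape.
#' @return A [uint8_image()].
#' @export
apply_mask <- function(img, mask) {
  stopifnot(inherits(img, "uint8_image"), inherits(mask, "lung_mask"))
  if (!same_shape(img$values, mask$values)) rlang::abort("image/mask shape mismatch")
  uint8_image(img$values * (mask$values * 1L))
}

#' Remove bone from a masked slice
#'
#' Pixels whose HU exceeds the bone threshold, together with detected edge
#' pixels in their immediate neighbourhood (gradient-magnitude edges at an
#' Otsu cut, within a 2-px dilation of the bone), are set to zero. With no
#' bone present the image is returned unchanged.
#'
#' @param img A [uint8_image()].
#' @param hu The aligned [hu_image()] the slice came from.
#' @param bone_threshold_hu Bone cut in HU (default +300).
#' @return A [uint8_image()].
#' @export
remove_bone <- function(img, hu, bone_threshold_hu = 300) {
  stopifnot(inherits(img, "uint8_image"), inherits(hu, "hu_image"))
  if (!same_shape(img$values, hu$values)) rlang::abort("image/HU shape mismatch")
  bone <- hu$values > bone_threshold_hu
  if (!any(bone)) return(img)
  g <- img$values / 255
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(g, kx)
  gy <- EBImage::filter2(g, t(kx))
  gm <- sqrt(gx^2 + gy^2)
  mx <- max(gm)
  edges <- if (mx > 0) {
    gmn <- matrix(gm / mx, nrow(gm), ncol(gm))
    gmn > EBImage::otsu(EBImage::Image(gmn), range = c(0, 1))
  } else matrix(FALSE, nrow(gm), ncol(gm))
  near_bone <- EBImage::dilate(bone * 1, disc_brush(2)) > 0.5
  dim(near_bone) <- dim(bone)
  kill <- bone | (edges & near_bone)
  out <- img$values
  out[kill] <- 0L
  uint8_image(out)
}

#' Full lung-field preprocessing of one slice
#'
#' Composes the pipeline: HU calibration, air binarization, lung-mask
#' extraction, 8-bit windowing, masking, bone removal.
#'
#' @param raw A numeric matrix of raw values, or an [hu_image()] (in which
#'   case `slope`/`intercept`/`spacing` are ignored).
#' @param slope,intercept CT rescale calibration.
#' @param spacing Pixel spacing in mm.
#' @param config A [preprocess_config()].
#' @return A list: `image` (masked, bone-free [uint8_image()]), `mask`
#'   ([lung_mask()]), `hu` (the calibrated [hu_image()]).
#' @export
preprocess_slice <- function(raw, slope = 1, intercept = 0, spacing = 1,
                             config = preprocess_config()) {
  hu <- if (inherits(raw, "hu_image")) raw else to_hu(raw, slope, intercept, spacing)
  binary <- binarize_lungs(hu, config$binarize_threshold_hu)
  mask <- extract_lung_mask(binary, config$closing_radius_px,
                            config$expand_radius_px)
  u8 <- hu_to_uint8(hu, config$window_hu)
  masked <- apply_mask(u8, mask)
  cleaned <- remove_bone(masked, hu, config$bone_threshold_hu)
  list(image = cleaned, mask = mask, hu = hu)
}
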