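# ---- integral-image proposal scoring ---------------------------------------

integral_image <- function(m) {
  ii <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed double cumsum
  t(ii)
}

# mean intensity inside boxes (clipped to the image), via one integral image
box_means <- function(ii, box_df, nr, nc) {
  x0 <- pmax(0, pmin(nc, floor(box_df$x_min)))
  x1 <- pmax(0, pmin(nc, ceiling(box_df$x_max)))
  y0 <- pmax(0, pmin(nr, floor(box_df$y_min)))
  y1 <- pmax(0, pmin(nr, ceiling(box_df$y_max)))
  area <- (x1 - x0) * (y1 - y0)
  at <- function(r, c) ifelse(r == 0 | c == 0, 0, ii[cbind(pmax(r, 1), pmax(c, 1))])
  s <- at(y1, x1) - at(y0, x1) - at(y1, x0) + at(y0, x0)
  ifelse(area > 0, s / area, 0)
}

#' Score anchor boxes by centre-surround contrast
#'
#' A training-free objectness proxy for the demo pipeline: each box is scored
#' by the difference between its mean masked intensity and the mean intensity
#' of a surrounding ring (the box dilated by half its size), scaled to
#' `[0, 1]`. Bright compact structures inside the lung (nodule candidates)
#' score high; uniform background and masked-out regions score near zero.
#'
#' @param img A [uint8_image()] (masked slice).
#' @param box_df Box tibble.
#' @return The input with a `score` column.
#' @export
score_boxes_contrast <- function(img, box_df) {
  nr <- nrow(img$values); nc <- ncol(img$values)
  ii <- integral_image(img$values)
  inner <- box_means(ii, box_df, nr, nc)
  w <- box_df$x_max - box_df$x_min; h <- box_df$y_max - box_df$y_min
  ring <- tibble::tibble(x_min = box_df$x_min - w / 2, y_min = box_df$y_min - h / 2,
                         x_max = box_df$x_max + w / 2, y_max = box_df$y_max + h / 2)
  outer_mean <- box_means(ii, ring, nr, nc)
  box_df$score <- pmin(1, pmax(0, (inner - outer_mean) / 255))
  box_df
}

#' Extract a fixed-size patch over a box
#'
#' Nearest-neighbour resampling of the box region onto an `out_size` square,
#' intensities scaled to `[0, 1]`. Samples outside the image read as 0.
#'
#' @param img A [uint8_image()].
#' @param box One-row box tibble.
#' @param out_size Patch side in pixels (default 16).
#' @return An `out_size` x `out_size` numeric matrix.
#' @export
extract_patch <- function(img, box, out_size = 16) {
  nr <- nrow(img$values); nc <- ncol(img$values)
  xs <- box$x_min + (seq_len(out_size) - 0.5) / out_size * (box$x_max - box$x_min)
  ys <- box$y_min + (seq_len(out_size) - 0.5) / out_size * (box$y_max - box$y_min)
  ci <- floor(xs) + 1; ri <- floor(ys) + 1
  ok_c <- ci >= 1 & ci <= nc; ok_r <- ri >= 1 & ri <= nr
  out <- matrix(0, out_size, out_size)
  out[ok_r, ok_c] <- img$values[ri[ok_r], ci[ok_c], drop = FALSE] / 255
  out
}

# ---- stage configs ----------------------------------------------------------

#' Synthetic dataset configuration
#'
#' @param n_slices Number of phantom slices.
#' @param image_size Pixels per side (default 128 for the demo scale).
#' @param spacing mm per pixel (default 1).
#' @param max_nodules_per_slice Per-slice nodule count is drawn uniformly
#'   from `0..max_nodules_per_slice`.
#' @param diameter_range mm range for nodule diameters.
#' @param noise_sd Additive HU noise (default 0).
#' @param seed Integer seed.
#' @return A named list of class `synth_config`.
#' @export
synth_config <- function(n_slices = 20, image_size = 128, spacing = 1.0,
                         max_nodules_per_slice = 3, diameter_range = c(4, 16),
                         noise_sd = 0, seed = 1L) {
  structure(list(n_slices = as.integer(n_slices),
                 image_size = as.integer(image_size), spacing = spacing,
                 max_nodules_per_slice = as.integer(max_nodules_per_slice),
                 diameter_range = diameter_range, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "synth_config")
}

#' Generate and write a synthetic phantom dataset
#'
#' Draws a per-slice nodule count, samples nodules inside the lungs,
#' rasterizes each slice, and writes the MetaImage volume, annotation CSV and
#' manifest with [write_dataset()]. Deterministic under the config seed.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory.
#' @return The dataset directory, invisibly; attributes carry the slice list
#'   and nodule table.
#' @export
cmd_synth <- function(config = synth_config(), out_dir) {
  spec <- phantom_spec(image_size = config$image_size,
                       spacing = config$spacing,
                       noise_sd = config$noise_sd, seed = config$seed)
  slices <- vector("list", config$n_slices)
  all_nod <- list()
  if (config$n_slices > 0) {
    counts <- withr::with_seed(config$seed,
      sample.int(config$max_nodules_per_slice + 1L, config$n_slices,
                 replace = TRUE) - 1L)
    for (z in seq_len(config$n_slices)) {
      nod <- if (counts[z] > 0) {
        sample_nodules(spec, counts[z], config$diameter_range,
                       seed = config$seed + 1000L + z)
      } else nodule_spec()
      sl <- make_phantom_slice(spec, nod)
      slices[[z]] <- sl$image
      if (nrow(nod) > 0) {
        nod$slice <- z - 1L
        all_nod[[length(all_nod) + 1]] <- nod
      }
    }
  }
  nodules <- if (length(all_nod) > 0) dplyr::bind_rows(all_nod) else
    tibble::tibble(slice = integer(), x_mm = numeric(), y_mm = numeric(),
                   diameter_mm = numeric())
  write_dataset(slices, nodules, out_dir,
                manifest = list(seed = config$seed,
                                image_size = config$image_size,
                                spacing = config$spacing,
                                n_requested = config$n_slices))
  out <- out_dir
  attr(out, "slices") <- slices
  attr(out, "nodules") <- nodules
  invisible(out)
}

#' Preprocess every slice of a dataset
#'
#' Runs [preprocess_slice()] on each slice; optionally writes the mask and
#' masked slice as PNG files.
#'
#' @param dataset_dir Directory written by [cmd_synth()] / [write_dataset()].
#' @param config A [preprocess_config()].
#' @param out_dir Optional directory for PNG output.
#' @return A list: `results` (per-slice preprocess output), `summary`
#'   (tibble: slice, mask_area, n_components, nodules covered).
#' @export
cmd_preprocess <- function(dataset_dir, config = preprocess_config(),
                           out_dir = NULL) {
  ds <- read_dataset(dataset_dir)
  results <- lapply(ds$slices, preprocess_slice, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (z in seq_along(results)) {
      EBImage::writeImage(t(results[[z]]$mask$values * 1),
                          file.path(out_dir, sprintf("mask_%03d.png", z - 1)))
      EBImage::writeImage(t(results[[z]]$image$values / 255),
                          file.path(out_dir, sprintf("masked_%03d.png", z - 1)))
    }
  }
  covered <- vapply(seq_along(results), function(z) {
    gt <- ds$gt_boxes[[z]]
    if (nrow(gt) == 0) return(NA_integer_)
    m <- results[[z]]$mask$values
    sum(vapply(seq_len(nrow(gt)), function(i) {
      rows <- (max(0, gt$y_min[i]) + 1):min(nrow(m), gt$y_max[i])
      cols <- (max(0, gt$x_min[i]) + 1):min(ncol(m), gt$x_max[i])
      all(m[rows, cols])
    }, logical(1)))
  }, integer(1))
  summary <- tibble::tibble(
    slice = seq_along(results) - 1L,
    mask_area = vapply(results, function(r) sum(r$mask$values), numeric(1)),
    n_components = vapply(results, function(r) r$mask$n_components, integer(1)),
    gt_total = vapply(ds$gt_boxes, nrow, integer(1)),
    gt_covered = covered)
  list(results = results, summary = summary, dataset = ds)
}

#' Fit anchors from a dataset or a box table
#'
#' @param source A [box_wh()] tibble, or a dataset directory whose
#'   ground-truth box shapes are used.
#' @param method `"fcm"` or `"kmeans"`.
#' @param k Number of anchor shapes.
#' @param m Fuzzifier for FCM.
#' @param seed Integer seed.
#' @param out Optional JSON path for the anchor set (shapes, config,
#'   mean best IoU).
#' @return The fit object ([fcm_fit()] or [kmeans_fit()]).
#' @export
cmd_anchors <- function(source, method = c("fcm", "kmeans"), k = 5, m = 2,
                        seed = 1L, out = NULL) {
  method <- match.arg(method)
  pts <- if (is.character(source)) {
    ds <- read_dataset(source)
    gt <- dplyr::bind_rows(ds$gt_boxes)
    box_wh(gt$x_max - gt$x_min, gt$y_max - gt$y_min)
  } else tibble::as_tibble(source)
  fit <- if (method == "fcm") fcm_fit(pts, c = k, m = m, seed = seed) else
    kmeans_fit(pts, k = k, seed = seed)
  if (!is.null(out)) {
    jsonlite::write_json(list(
      shapes = fit$anchors$shapes, method = fit$anchors$method,
      config = fit$anchors$config,
      mean_best_iou = mean_best_iou(pts, fit$anchors)),
      out, auto_unbox = TRUE, digits = NA)
  }
  fit
}

#' Pipeline configuration
#'
#' @param anchor_method `"fcm"` or `"kmeans"`.
#' @param k Anchor cluster count (default 5).
#' @param m FCM fuzzifier (default 2).
#' @param stride Anchor grid stride in pixels (default 2).
#' @param rpn An [rpn_config()]; the demo default keeps 12 proposals per
#'   slice after suppression at IoU 0.3.
#' @param match_iou IoU at which a detection counts as hitting a nodule
#'   (default 0.3, suited to small objects on a coarse anchor grid).
#' @param family,attention Backbone family and attention variant of the
#'   primary branch.
#' @param fusion_family Second branch for multi-backbone fusion, or `"none"`.
#' @param fusion A [fusion_rule()].
#' @param score_threshold Classifier score above which a candidate becomes a
#'   detection.
#' @param patch_size Classifier input patch side.
#' @param n_folds Cross-validation folds over slices (default 5).
#' @param seed Integer seed.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(anchor_method = "fcm", k = 5, m = 2, stride = 2,
                            rpn = rpn_config(nms_iou = 0.3, top_n = 12),
                            match_iou = 0.3, family = "resnet",
                            attention = "ca1", fusion_family = "densenet",
                            fusion = fusion_rule("union_positive", 0.5),
                            score_threshold = 0.5, patch_size = 16,
                            n_folds = 5, seed = 1L) {
  structure(list(anchor_method = anchor_method, k = k, m = m, stride = stride,
                 rpn = rpn, match_iou = match_iou, family = family,
                 attention = attention, fusion_family = fusion_family,
                 fusion = fusion, score_threshold = score_threshold,
                 patch_size = patch_size, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the full detection pipeline on a dataset
#'
#' Orchestrates the stages in order: preprocessing, anchor-prior fitting on
#' the ground-truth box shapes, anchor-grid scoring and proposal selection
#' per slice, patch classification with a demo-trained backbone head under
#' slice-level k-fold cross-validation, optional multi-backbone fusion, and
#' confusion counting with the five indicators.
#'
#' @param dataset_dir Dataset directory (see [cmd_synth()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `metrics.json`, `metrics.csv`, `proposals.csv`, `anchors.json` and a
#'   `config.yaml` snapshot there.
#' @return An object of class `nodule_pipeline`: `metrics` (per-fold +
#'   pooled tibble for the primary branch), `fused_metrics`,
#'   `branch_sensitivity` (primary, secondary, fused), `anchor_fit`,
#'   `proposals`, `config`.
#' @export
cmd_pipeline <- function(dataset_dir, config = pipeline_config(),
                         out_dir = NULL) {
  prep <- cmd_preprocess(dataset_dir)
  ds <- prep$dataset
  n_slices <- length(ds$slices)
  if (n_slices == 0) rlang::abort("dataset has no slices", class = "lungrpn_stage_error")

  # anchor priors from the annotated box shapes
  gt_all <- dplyr::bind_rows(ds$gt_boxes)
  if (nrow(gt_all) < config$k) {
    rlang::abort("anchors stage: fewer ground-truth boxes than clusters",
                 class = "lungrpn_stage_error")
  }
  wh <- box_wh(gt_all$x_max - gt_all$x_min, gt_all$y_max - gt_all$y_min)
  anchor_fit <- if (config$anchor_method == "fcm") {
    fcm_fit(wh, c = config$k, m = config$m, seed = config$seed)
  } else {
    kmeans_fit(wh, k = config$k, seed = config$seed)
  }

  # proposals per slice: tiled anchors scored by contrast, suppressed, top-N
  img_n <- nrow(ds$slices[[1]]$values)
  feat_hw <- img_n %/% config$stride
  grid <- generate_anchor_grid(c(feat_hw, feat_hw), config$stride,
                               anchor_fit$anchors)
  proposals <- purrr::map(seq_len(n_slices), function(z) {
    scored <- score_boxes_contrast(prep$results[[z]]$image, grid)
    scored <- scored[scored$score > 0, , drop = FALSE]
    scored <- utils::head(scored[order(-scored$score), , drop = FALSE], 300)
    props <- select_proposals(scored, config$rpn)
    if (nrow(props) > 0) props$slice <- z - 1L
    props
  })
  prop_tbl <- dplyr::bind_rows(proposals)
  if (nrow(prop_tbl) == 0) {
    rlang::abort("rpn stage produced no proposals", class = "lungrpn_stage_error")
  }

  # candidate patches + labels (IoU >= match_iou with ground truth)
  patches <- vector("list", nrow(prop_tbl))
  labels <- integer(nrow(prop_tbl))
  row <- 0L
  for (z in seq_len(n_slices)) {
    props <- proposals[[z]]
    if (is.null(props) || nrow(props) == 0) next
    gt <- ds$gt_boxes[[z]]
    iou_max <- if (nrow(gt) > 0) apply(box_iou(props, gt), 1, max) else
      rep(0, nrow(props))
    for (i in seq_len(nrow(props))) {
      row <- row + 1L
      patches[[row]] <- extract_patch(prep$results[[z]]$image, props[i, ],
                                      config$patch_size)
      labels[row] <- as.integer(iou_max[i] >= config$match_iou)
    }
  }
  batch <- as_batch(patches)

  build_branch <- function(family) {
    build_backbone(backbone_config(
      family = family, attention = config$attention,
      input_size = config$patch_size, seed = config$seed))
  }
  model_a <- build_branch(config$family)
  feats_a <- forward_backbone(model_a, batch)$features
  use_fusion <- !identical(config$fusion_family, "none")
  model_b <- if (use_fusion) build_branch(config$fusion_family) else NULL
  feats_b <- if (use_fusion) forward_backbone(model_b, batch)$features else NULL

  folds <- kfold_split(n_slices, config$n_folds, config$seed)
  slice_of_prop <- prop_tbl$slice + 1L
  eval_branch <- function(feats, model) {
    scores <- numeric(nrow(prop_tbl))
    for (f in seq_len(config$n_folds)) {
      tr <- which(!(slice_of_prop %in% which(folds == f)))
      te <- which(slice_of_prop %in% which(folds == f))
      if (length(te) == 0) next
      fit <- train_demo(list(features = feats[tr, , drop = FALSE],
                             y = labels[tr]),
                        model, seed = config$seed + f)
      scores[te] <- classify_features(fit$model, feats[te, , drop = FALSE])
    }
    scores
  }
  scores_a <- eval_branch(feats_a, model_a)
  scores_b <- if (use_fusion) eval_branch(feats_b, model_b) else NULL

  count_decisions <- function(positive) {
    fold_counts <- lapply(seq_len(config$n_folds), function(f) {
      zs <- which(folds == f) - 1L
      tp <- fp <- fn <- 0L; n_cand <- 0L
      for (z in zs) {
        sel <- which(prop_tbl$slice == z)
        n_cand <- n_cand + length(sel)
        dets <- prop_tbl[sel[positive[sel]], , drop = FALSE]
        cc <- match_detections(dets, ds$gt_boxes[[z + 1]], config$match_iou)
        tp <- tp + cc$tp; fp <- fp + cc$fp; fn <- fn + cc$fn
      }
      confusion_counts(tp, fp, max(0L, n_cand - tp - fp), fn)
    })
    fold_counts
  }

  pos_a <- scores_a > config$score_threshold
  counts_a <- count_decisions(pos_a)
  metrics_a <- summarize_folds(counts_a)
  fused <- fused_metrics <- counts_f <- NULL
  branch_sens <- c(primary = metrics_a$sensitivity[metrics_a$fold == "pooled"])
  if (use_fusion) {
    fused <- fuse_multibackbone(scores_a, scores_b, config$fusion)
    pos_b <- scores_b > config$fusion$threshold
    counts_b <- count_decisions(pos_b)
    metrics_b <- summarize_folds(counts_b)
    counts_f <- count_decisions(fused$positive)
    fused_metrics <- summarize_folds(counts_f)
    branch_sens <- c(branch_sens,
                     secondary = metrics_b$sensitivity[metrics_b$fold == "pooled"],
                     fused = fused_metrics$sensitivity[fused_metrics$fold == "pooled"])
  }

  out <- structure(list(
    metrics = metrics_a, fused_metrics = fused_metrics,
    branch_sensitivity = branch_sens, anchor_fit = anchor_fit,
    proposals = prop_tbl, labels = labels,
    scores = list(primary = scores_a, secondary = scores_b),
    folds = folds, config = config, n_slices = n_slices),
    class = "nodule_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- out$metrics[out$metrics$fold == "pooled", ]
    jsonlite::write_json(as.list(report), file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(out$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(prop_tbl[, c("x_min", "y_min", "x_max", "y_max",
                                  "score", "slice")],
                     file.path(out_dir, "proposals.csv"), row.names = FALSE)
    jsonlite::write_json(list(shapes = anchor_fit$anchors$shapes,
                              method = anchor_fit$anchors$method,
                              config = anchor_fit$anchors$config),
                         file.path(out_dir, "anchors.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_plain <- rapply(unclass(config), identity, how = "list")
    yaml::write_yaml(cfg_plain, file.path(out_dir, "config.yaml"))
  }
  out
}

#' @export
print.nodule_pipeline <- function(x, ...) {
  cat(sprintf("<nodule_pipeline> %d slices, %d proposals, anchors via %s\n",
              x$n_slices, nrow(x$proposals), x$anchor_fit$anchors$method))
  print(x$metrics[x$metrics$fold == "pooled", ])
  invisible(x)
}

#' Check the published-table F1 identity and print a pass/fail listing
#'
#' @param tol Absolute tolerance (default 1e-4, the rounding of the inputs).
#' @param quiet Suppress the listing.
#' @return The [check_f1_consistency()] tibble, invisibly.
#' @export
cmd_check_tables <- function(tol = 1e-4, quiet = FALSE) {
  res <- check_f1_consistency(tol = tol)
  if (!quiet) {
    for (i in seq_len(nrow(res))) {
      cat(sprintf("table %2d %-9s %-8s %-6s f1 %.4f recomputed %.4f  %s\n",
                  res$table[i], res$backbone[i], res$clustering[i],
                  res$setting[i], res$f1[i], res$f1_recomputed[i],
                  if (res$pass[i]) "PASS" else "FAIL"))
    }
    cat(sprintf("%d/%d rows consistent at +/-%g\n", sum(res$pass), nrow(res), tol))
  }
  invisible(res)
}
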