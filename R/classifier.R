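# ---- minimal batched 2D layers on (N, C, H, W) arrays ----------------------

relu <- function(x) pmax(x, 0)

pad_nchw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], d[3] + 2 * p, d[4] + 2 * p))
  out[, , p + seq_len(d[3]), p + seq_len(d[4])] <- x
  out
}

# standard convolution, stride 1, same padding (odd kernels)
conv2d <- function(x, w, b = NULL) {
  d <- dim(x); O <- dim(w)[1]; C <- dim(w)[2]; kh <- dim(w)[3]; kw <- dim(w)[4]
  stopifnot(d[2] == C)
  p <- (kh - 1) %/% 2
  xp <- pad_nchw(x, p)
  N <- d[1]; H <- d[3]; W <- d[4]
  acc <- matrix(0, O, N * H * W)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    S <- xp[, , i:(i + H - 1), j:(j + W - 1), drop = FALSE]
    M <- matrix(aperm(S, c(2, 1, 3, 4)), nrow = C)
    acc <- acc + matrix(w[, , i, j], O, C) %*% M
  }
  if (!is.null(b)) acc <- acc + b
  aperm(array(acc, dim = c(O, N, H, W)), c(2, 1, 3, 4))
}

# depthwise convolution: one k x k filter per channel, stride 1, same padding
depthwise_conv2d <- function(x, w, b = NULL) {
  d <- dim(x); C <- dim(w)[1]; kh <- dim(w)[2]; kw <- dim(w)[3]
  stopifnot(d[2] == C)
  p <- (kh - 1) %/% 2
  xp <- pad_nchw(x, p)
  N <- d[1]; H <- d[3]; W <- d[4]
  out <- array(0, dim = d)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    S <- xp[, , i:(i + H - 1), j:(j + W - 1), drop = FALSE]
    out <- out + S * rep(rep(w[, i, j], each = N), times = H * W)
  }
  if (!is.null(b)) out <- out + rep(rep(b, each = N), times = H * W)
  out
}

avg_pool2 <- function(x) {
  d <- dim(x)
  h2 <- d[3] %/% 2; w2 <- d[4] %/% 2
  oi <- seq_len(h2) * 2 - 1; oj <- seq_len(w2) * 2 - 1
  (x[, , oi, oj, drop = FALSE] + x[, , oi + 1, oj, drop = FALSE] +
     x[, , oi, oj + 1, drop = FALSE] + x[, , oi + 1, oj + 1, drop = FALSE]) / 4
}

global_avg_pool <- function(x) apply(x, c(1, 2), mean)

he_init <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)

# ---- backbone configuration -------------------------------------------------

#' Backbone configuration
#'
#' Describes a scaled-down patch classifier. The stage structure of each
#' family is preserved (residual additions, dense concatenation growth,
#' depthwise-separable factorization, mixed kernel sizes) while channel
#' counts and depths are scaled so the model runs quickly on a CPU.
#'
#' @param family `"resnet"`, `"densenet"`, `"mobilenet"` or `"mixnet"`.
#' @param depth_scale,width_scale Positive reals scaling blocks-per-stage and
#'   channel widths.
#' @param attention `"none"`, `"se"`, `"ca1"` or `"ca2"` — a gating block
#'   inserted after every stage.
#' @param input_size Square patch side in pixels (default 16).
#' @param in_channels Input channels (default 1, grayscale CT patches).
#' @param n_stages Number of stages (default 2); each stage halves the
#'   spatial size.
#' @param reduction_ratio Attention bottleneck ratio.
#' @param seed Seed for parameter initialization.
#' @return A list of class `backbone_config`.
#' @export
backbone_config <- function(family = c("resnet", "densenet", "mobilenet", "mixnet"),
                            depth_scale = 1, width_scale = 1,
                            attention = c("none", "se", "ca1", "ca2"),
                            input_size = 16, in_channels = 1, n_stages = 2,
                            reduction_ratio = 8, seed = 1L) {
  family <- match.arg(family); attention <- match.arg(attention)
  if (depth_scale <= 0 || width_scale <= 0) {
    rlang::abort("depth_scale and width_scale must be > 0")
  }
  base <- max(2L, as.integer(round(8 * width_scale)))
  structure(list(family = family, depth_scale = depth_scale,
                 width_scale = width_scale, attention = attention,
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 n_stages = as.integer(n_stages),
                 base_channels = base,
                 blocks_per_stage = max(1L, as.integer(round(2 * depth_scale))),
                 growth = max(2L, as.integer(round(4 * width_scale))),
                 reduction_ratio = reduction_ratio, seed = as.integer(seed)),
            class = "backbone_config")
}

mixnet_groups <- function(channels) {
  kernels <- c(1, 3, 5)
  sizes <- rep(channels %/% 3, 3)
  sizes[seq_len(channels %% 3)] <- sizes[seq_len(channels %% 3)] + 1
  keep <- sizes > 0
  list(kernels = kernels[keep], sizes = sizes[keep])
}

#' Build a scaled-down backbone classifier
#'
#' Constructs the parameter tree for the requested family, inserts attention
#' blocks after each stage when asked, and attaches a 2-neuron output head
#' (nodule vs non-nodule). Parameters are randomly initialized under the
#' config seed; [train_demo()] fits the head.
#'
#' @param config A [backbone_config()].
#' @return An object of class `nodule_classifier` with elements `config`,
#'   `stem`, `stages`, `head`, `structure` (tibble of per-layer input/output
#'   channels) and `n_params`.
#' @export
build_backbone <- function(config) {
  stopifnot(inherits(config, "backbone_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    structure_rows <- list()
    note <- function(stage, block, kind, c_in, c_out) {
      structure_rows[[length(structure_rows) + 1]] <<-
        tibble::tibble(stage = stage, block = block, kind = kind,
                       c_in = c_in, c_out = c_out)
    }
    c0 <- cfg$base_channels
    stem <- list(w = he_init(c(c0, cfg$in_channels, 3, 3), cfg$in_channels * 9),
                 b = numeric(c0))
    note(0L, 0L, "stem", cfg$in_channels, c0)
    channels <- c0
    stages <- vector("list", cfg$n_stages)
    for (s in seq_len(cfg$n_stages)) {
      blocks <- vector("list", cfg$blocks_per_stage)
      for (bidx in seq_len(cfg$blocks_per_stage)) {
        blocks[[bidx]] <- switch(cfg$family,
          resnet = {
            note(s, bidx, "residual", channels, channels)
            list(conv1 = list(w = he_init(c(channels, channels, 3, 3), channels * 9),
                              b = numeric(channels)),
                 conv2 = list(w = he_init(c(channels, channels, 3, 3), channels * 9),
                              b = numeric(channels)))
          },
          densenet = {
            note(s, bidx, "dense", channels, channels + cfg$growth)
            lay <- list(w = he_init(c(cfg$growth, channels, 3, 3), channels * 9),
                        b = numeric(cfg$growth))
            channels <- channels + cfg$growth
            lay
          },
          mobilenet = {
            note(s, bidx, "separable", channels, channels)
            list(dw = list(w = he_init(c(channels, 3, 3), 9), b = numeric(channels)),
                 pw = list(w = he_init(c(channels, channels, 1, 1), channels),
                           b = numeric(channels)))
          },
          mixnet = {
            note(s, bidx, "mixed", channels, channels)
            grp <- mixnet_groups(channels)
            dws <- purrr::map2(grp$kernels, grp$sizes, function(k, sz) {
              list(w = he_init(c(sz, k, k), k * k), b = numeric(sz))
            })
            list(groups = grp, dws = dws,
                 pw = list(w = he_init(c(channels, channels, 1, 1), channels),
                           b = numeric(channels)))
          })
      }
      att <- if (cfg$attention != "none") {
        attention_params(channels, cfg$attention, cfg$reduction_ratio,
                         init = "random", seed = cfg$seed + s)
      } else NULL
      trans <- if (s < cfg$n_stages) {
        c_next <- c0 * 2^s
        note(s, cfg$blocks_per_stage + 1L, "transition", channels, c_next)
        tr <- list(w = he_init(c(c_next, channels, 1, 1), channels),
                   b = numeric(c_next))
        channels <- c_next
        tr
      } else NULL
      stages[[s]] <- list(blocks = blocks, attention = att, transition = trans)
    }
    head <- list(w = matrix(stats::rnorm(2 * channels, 0, 0.01), 2, channels),
                 b = numeric(2))
    note(cfg$n_stages + 1L, 0L, "head", channels, 2L)
    model <- structure(list(config = cfg, stem = stem, stages = stages,
                            head = head,
                            structure = dplyr::bind_rows(structure_rows),
                            feature_channels = channels),
                       class = "nodule_classifier")
    model$n_params <- count_parameters(model)
    model
  })
}

#' Count the parameters of a classifier
#'
#' @param model A `nodule_classifier`.
#' @return Total number of scalar parameters.
#' @export
count_parameters <- function(model) {
  n <- 0
  walk <- function(x) {
    if (is.numeric(x)) n <<- n + length(x)
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(model$stem); walk(model$stages); walk(model$head)
  n
}

block_forward <- function(x, blk, family) {
  switch(family,
    resnet = relu(x + conv2d(relu(conv2d(x, blk$conv1$w, blk$conv1$b)),
                             blk$conv2$w, blk$conv2$b)),
    densenet = {
      new <- relu(conv2d(x, blk$w, blk$b))
      d <- dim(x); dn <- dim(new)
      out <- array(0, dim = c(d[1], d[2] + dn[2], d[3], d[4]))
      out[, seq_len(d[2]), , ] <- x
      out[, d[2] + seq_len(dn[2]), , ] <- new
      out
    },
    mobilenet = relu(conv2d(relu(depthwise_conv2d(x, blk$dw$w, blk$dw$b)),
                            blk$pw$w, blk$pw$b)),
    mixnet = {
      off <- 0
      parts <- vector("list", length(blk$groups$kernels))
      for (gi in seq_along(blk$groups$kernels)) {
        sz <- blk$groups$sizes[gi]
        xs <- x[, off + seq_len(sz), , , drop = FALSE]
        parts[[gi]] <- depthwise_conv2d(xs, blk$dws[[gi]]$w, blk$dws[[gi]]$b)
        off <- off + sz
      }
      d <- dim(x)
      mixed <- array(0, dim = d)
      off <- 0
      for (gi in seq_along(parts)) {
        sz <- blk$groups$sizes[gi]
        mixed[, off + seq_len(sz), , ] <- parts[[gi]]
        off <- off + sz
      }
      relu(conv2d(relu(mixed), blk$pw$w, blk$pw$b))
    })
}

apply_attention_batch <- function(x, params) {
  d <- dim(x)
  for (n in seq_len(d[1])) {
    xi <- array(x[n, , , ], dim = d[2:4])
    x[n, , , ] <- attention_forward(xi, params)
  }
  x
}

#' Forward pass through a classifier backbone
#'
#' @param model A `nodule_classifier`.
#' @param x A batch array `(N, C, H, W)`; a single `C x H x W` array or a
#'   list of `H x W` matrices is promoted.
#' @param return_stages If `TRUE`, also return each stage's output feature
#'   map (before the transition), for structural inspection.
#' @return A list: `logits` (N x 2), `scores` (numeric N, softmax probability
#'   of the nodule class), `features` (N x C), and optionally `stage_maps`.
#' @export
forward_backbone <- function(model, x, return_stages = FALSE) {
  x <- as_batch(x, model$config$in_channels)
  cfg <- model$config
  h <- relu(conv2d(x, model$stem$w, model$stem$b))
  stage_maps <- list()
  for (s in seq_along(model$stages)) {
    st <- model$stages[[s]]
    for (blk in st$blocks) h <- block_forward(h, blk, cfg$family)
    if (!is.null(st$attention)) h <- apply_attention_batch(h, st$attention)
    if (return_stages) stage_maps[[s]] <- h
    if (!is.null(st$transition)) {
      h <- avg_pool2(relu(conv2d(h, st$transition$w, st$transition$b)))
    }
  }
  feats <- global_avg_pool(h)
  logits <- feats %*% t(model$head$w) +
    matrix(model$head$b, nrow(feats), 2, byrow = TRUE)
  scores <- softmax2(logits)
  out <- list(logits = logits, scores = scores, features = feats)
  if (return_stages) out$stage_maps <- stage_maps
  out
}

softmax2 <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e[, 2] / (e[, 1] + e[, 2])
}

as_batch <- function(x, in_channels = 1) {
  if (is.list(x)) {
    x <- array(unlist(lapply(x, as.vector)), dim = c(dim(x[[1]]), length(x)))
    x <- aperm(x, c(3, 1, 2))
  }
  d <- dim(x)
  if (length(d) == 2) x <- array(x, dim = c(1, 1, d))
  else if (length(d) == 3) {
    # (N, H, W) single-channel batch
    x <- array(x, dim = c(d[1], 1, d[2], d[3]))
  }
  if (dim(x)[2] != in_channels) rlang::abort("patch channel count mismatch")
  x
}

#' Score patches with a classifier
#'
#' Deterministic inference: one nodule-probability score per patch.
#'
#' @param model A `nodule_classifier` (optionally after [train_demo()]).
#' @param patches Batch of patches (see [forward_backbone()]).
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
classify_patches <- function(model, patches) {
  forward_backbone(model, patches)$scores
}

#' @export
print.nodule_classifier <- function(x, ...) {
  cat(sprintf("<nodule_classifier> %s, %d stages, %d parameters, attention %s\n",
              x$config$family, x$config$n_stages, x$n_params,
              x$config$attention))
  invisible(x)
}

# ---- demo trainer -----------------------------------------------------------

#' Demo training configuration
#'
#' @param epochs Gradient-descent epochs on the head (default 200).
#' @param lr Learning rate (default 1).
#' @param val_fraction Fraction of samples held out for the validation trace.
#' @param l2 Ridge penalty on the head weights.
#' @param class_balance If `TRUE` (default) samples are weighted inversely to
#'   their class frequency, so a minority nodule class still drives the fit.
#' @return A named list.
#' @export
demo_train_config <- function(epochs = 200, lr = 1, val_fraction = 0.2,
                              l2 = 1e-4, class_balance = TRUE) {
  list(epochs = as.integer(epochs), lr = lr, val_fraction = val_fraction,
       l2 = l2, class_balance = class_balance)
}

ce_loss <- function(scores, y, wt = NULL, eps = 1e-12) {
  ll <- y * log(scores + eps) + (1 - y) * log(1 - scores + eps)
  if (is.null(wt)) -mean(ll) else -sum(wt * ll) / sum(wt)
}

#' Train the classifier head on a labelled patch set
#'
#' A CPU-scale stand-in for full network training: backbone features are
#' frozen at their seeded random initialization (random convolutional
#' features), and the 2-neuron softmax head is fitted by full-batch gradient
#' descent on cross-entropy. Deterministic under the seed; returns per-epoch
#' training and validation loss traces. A non-finite loss raises a
#' structured `lungrpn_divergence` error.
#'
#' @param dataset A list with `x` (batch of patches, see
#'   [forward_backbone()]) and `y` (0/1 labels, 1 = nodule).
#' @param model A `nodule_classifier` from [build_backbone()].
#' @param config A [demo_train_config()].
#' @param seed Integer seed controlling the train/validation split.
#' @return An object of class `demo_fit`: the updated `model`, `trace`
#'   (tibble: epoch, train_loss, val_loss), `train_accuracy`, `config`.
#' @export
train_demo <- function(dataset, model, config = demo_train_config(), seed = 1L) {
  y <- as.numeric(dataset$y)
  stopifnot(all(y %in% c(0, 1)))
  feats <- if (!is.null(dataset$features)) dataset$features else
    forward_backbone(model, dataset$x)$features
  n <- nrow(feats)
  idx_val <- withr::with_seed(seed, {
    nv <- max(1L, as.integer(round(config$val_fraction * n)))
    sort(sample.int(n, nv))
  })
  idx_tr <- setdiff(seq_len(n), idx_val)
  Ft <- feats[idx_tr, , drop = FALSE]; yt <- y[idx_tr]
  Fv <- feats[idx_val, , drop = FALSE]; yv <- y[idx_val]
  wt <- rep(1, length(yt))
  if (isTRUE(config$class_balance) && length(unique(yt)) == 2) {
    wt <- ifelse(yt == 1, 0.5 / mean(yt == 1), 0.5 / mean(yt == 0))
  }
  W <- model$head$w; b <- model$head$b
  trace <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
  score_of <- function(Fm, W, b) {
    softmax2(Fm %*% t(W) + matrix(b, nrow(Fm), 2, byrow = TRUE))
  }
  for (ep in 0:config$epochs) {
    st <- score_of(Ft, W, b)
    sv <- score_of(Fv, W, b)
    lt <- ce_loss(st, yt, wt); lv <- ce_loss(sv, yv)
    if (!is.finite(lt) || !is.finite(lv)) {
      rlang::abort("training diverged: non-finite loss",
                   class = "lungrpn_divergence")
    }
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      epoch = ep, train_loss = lt, val_loss = lv))
    if (ep == config$epochs) break
    # gradient of weighted CE wrt the two-logit head
    err <- (st - yt) * wt / sum(wt)      # d loss / d (logit2 - logit1)
    g2 <- t(err) %*% Ft
    grad_W <- rbind(-g2, g2) + config$l2 * W
    grad_b <- c(-sum(err), sum(err))
    W <- W - config$lr * grad_W
    b <- b - config$lr * grad_b
  }
  model$head$w <- W; model$head$b <- b
  acc <- mean((score_of(Ft, W, b) > 0.5) == (yt == 1))
  structure(list(model = model, trace = trace, train_accuracy = acc,
                 config = config, seed = seed),
            class = "demo_fit")
}

#' @export
print.demo_fit <- function(x, ...) {
  cat(sprintf("<demo_fit> %d epochs, train loss %.4f -> %.4f, accuracy %.3f\n",
              max(x$trace$epoch), x$trace$train_loss[1],
              utils::tail(x$trace$train_loss, 1), x$train_accuracy))
  invisible(x)
}

#' Score precomputed backbone features with a classifier head
#'
#' @param model A `nodule_classifier`.
#' @param features An N x C feature matrix from [forward_backbone()].
#' @return Numeric vector of nodule-probability scores.
#' @export
classify_features <- function(model, features) {
  softmax2(features %*% t(model$head$w) +
             matrix(model$head$b, nrow(features), 2, byrow = TRUE))
}

# ---- multi-backbone fusion --------------------------------------------------

#' Fusion rule for a multi-backbone classifier
#'
#' @param mode `"union_positive"` (positive when either branch exceeds the
#'   threshold) or `"mean_score"` (mean of the two scores, then a strict
#'   `>` threshold).
#' @param threshold Decision threshold in (0, 1).
#' @return A named list of class `fusion_rule`.
#' @export
fusion_rule <- function(mode = c("union_positive", "mean_score"),
                        threshold = 0.5) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold >= 1) rlang::abort("threshold must be in (0,1)")
  structure(list(mode = mode, threshold = threshold), class = "fusion_rule")
}

#' Fuse the scores of two classifier branches
#'
#' @param scores_a,scores_b Aligned numeric score vectors in `[0, 1]`.
#' @param rule A [fusion_rule()].
#' @return A tibble: `score_a`, `score_b`, `fused_score`, `positive`.
#' @export
fuse_multibackbone <- function(scores_a, scores_b, rule = fusion_rule()) {
  if (length(scores_a) != length(scores_b)) {
    rlang::abort("score vectors must have equal length")
  }
  if (rule$mode == "union_positive") {
    fused <- pmax(scores_a, scores_b)
    positive <- scores_a > rule$threshold | scores_b > rule$threshold
  } else {
    fused <- (scores_a + scores_b) / 2
    positive <- fused > rule$threshold
  }
  tibble::tibble(score_a = scores_a, score_b = scores_b,
                 fused_score = fused, positive = positive)
}
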