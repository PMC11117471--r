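#' Hard swish
#'
#' `x * relu6(x + 3) / 6` — the nonlinearity used inside the attention
#' bottlenecks. Zero maps to zero, so zero-initialized blocks produce neutral
#' gates.
#' @param x Numeric.
#' @return Numeric of the same shape.
#' @export
hard_swish <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp_reduction <- function(channels, reduction_ratio) {
  max(4L, as.integer(ceiling(channels / reduction_ratio))) |>
    min(as.integer(channels)) |> max(1L)
}

#' Parameters for an attention block
#'
#' Builds the parameter container for one gating block. The bottleneck width
#' is `ceiling(channels / reduction_ratio)`, clamped to at least 4 (and never
#' above the channel count). Batch-normalization inside the coordinate
#' variants runs in inference mode on stored statistics (mean 0, variance 1,
#' unit gain by default), so forward passes are deterministic.
#'
#' @param channels Input channel count.
#' @param variant `"se"`, `"ca1"` or `"ca2"`.
#' @param reduction_ratio Bottleneck reduction ratio r, default 16.
#' @param init `"zero"` (neutral gates) or `"random"`.
#' @param seed Seed for random initialization.
#' @return A list of class `attention_params`.
#' @export
attention_params <- function(channels, variant = c("se", "ca1", "ca2"),
                             reduction_ratio = 16, init = c("zero", "random"),
                             seed = 1L) {
  variant <- match.arg(variant); init <- match.arg(init)
  r <- clamp_reduction(channels, reduction_ratio)
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc) else matrix(stats::rnorm(nr * nc, 0, 0.1), nr, nc)
  }
  p <- withr::with_seed(seed, {
    if (variant == "se") {
      list(W1 = mk(r, channels), b1 = numeric(r),
           W2 = mk(channels, r), b2 = numeric(channels))
    } else {
      list(W1 = mk(r, channels), b1 = numeric(r),
           bn = list(gamma = rep(1, r), beta = numeric(r),
                     mean = numeric(r), var = rep(1, r), eps = 1e-5),
           Wh = mk(channels, r), bh = numeric(channels),
           Ww = mk(channels, r), bw = numeric(channels))
    }
  })
  structure(c(list(variant = variant, channels = as.integer(channels), r = r),
              p), class = "attention_params")
}

check_feature_map <- function(x, params = NULL) {
  if (length(dim(x)) != 3) rlang::abort("feature map must be a C x H x W array")
  if (!all(is.finite(x))) rlang::abort("feature map must be finite")
  if (!is.null(params) && dim(x)[1] != params$channels) {
    rlang::abort(sprintf("feature map has %d channels but params expect %d",
                         dim(x)[1], params$channels))
  }
  invisible(x)
}

bn_inference <- function(v, bn) {
  (v - bn$mean) / sqrt(bn$var + bn$eps) * bn$gamma + bn$beta
}

#' Squeeze-and-excitation forward pass
#'
#' Global average pool per channel, two-layer bottleneck with hard-swish,
#' sigmoid channel gates, channel-wise multiply. With all weights and biases
#' zero every gate is `sigmoid(0) = 0.5`, so the output is exactly half the
#' input.
#'
#' @param x A `C x H x W` numeric array.
#' @param params [attention_params()] with `variant = "se"`.
#' @return An array of the same shape.
#' @export
se_forward <- function(x, params) {
  check_feature_map(x, params)
  s <- apply(x, 1, mean)                               # C
  z <- hard_swish(as.vector(params$W1 %*% s + params$b1))
  g <- sigmoid(as.vector(params$W2 %*% z + params$b2)) # C gates
  x * array(g, dim = dim(x))                           # g varies along dim 1
}

ca_descriptors <- function(x, use_max) {
  h_avg <- apply(x, c(1, 2), mean)  # C x H (pooled along width)
  w_avg <- apply(x, c(1, 3), mean)  # C x W (pooled along height)
  if (!use_max) return(list(h = h_avg, w = w_avg))
  h_max <- apply(x, c(1, 2), max)
  w_max <- apply(x, c(1, 3), max)
  # mean of the average- and max-pooled descriptors: reduces to plain average
  # pooling on spatially constant inputs
  list(h = (h_avg + h_max) / 2, w = (w_avg + w_max) / 2)
}

ca_forward_impl <- function(x, params, use_max) {
  check_feature_map(x, params)
  dms <- dim(x); H <- dms[2]; W <- dms[3]
  d <- ca_descriptors(x, use_max)
  y <- cbind(d$h, d$w)                                  # C x (H + W)
  mid <- params$W1 %*% y + params$b1                    # r x (H + W)
  mid <- hard_swish(bn_inference(mid, params$bn))
  gh <- sigmoid(params$Wh %*% mid[, seq_len(H), drop = FALSE] + params$bh)  # C x H
  gw <- sigmoid(params$Ww %*% mid[, H + seq_len(W), drop = FALSE] + params$bw) # C x W
  gh_arr <- array(rep(gh, times = W), dim = dms)
  gw_arr <- aperm(array(rep(gw, times = H), dim = c(dms[1], W, H)), c(1, 3, 2))
  x * gh_arr * gw_arr
}

#' Coordinate attention (type I) forward pass
#'
#' Direction-wise 1D average pooling (along width and along height), a shared
#' bottleneck transform with inference-mode batch normalization and
#' hard-swish, a split into per-row and per-column sigmoid gates, and a
#' two-way gated multiply. With zero weights both gates are 0.5, so the
#' output is exactly a quarter of the input.
#'
#' @inheritParams se_forward
#' @param params [attention_params()] with `variant = "ca1"`.
#' @return An array of the same shape.
#' @export
ca1_forward <- function(x, params) ca_forward_impl(x, params, use_max = FALSE)

#' Coordinate attention (type II) forward pass
#'
#' Identical to [ca1_forward()] except each directional descriptor combines
#' average and maximum pooling along the pooled axis (their mean), in the
#' spirit of CBAM's dual pooling. On spatially constant inputs average and
#' maximum coincide, so CA-II reduces exactly to CA-I.
#'
#' @inheritParams se_forward
#' @param params [attention_params()] with `variant = "ca2"`.
#' @return An array of the same shape.
#' @export
ca2_forward <- function(x, params) ca_forward_impl(x, params, use_max = TRUE)

#' Apply an attention block
#'
#' Dispatches to the forward pass matching `params$variant`.
#'
#' @inheritParams se_forward
#' @return An array of the same shape as `x`.
#' @export
attention_forward <- function(x, params) {
  switch(params$variant,
         se = se_forward(x, params),
         ca1 = ca1_forward(x, params),
         ca2 = ca2_forward(x, params),
         rlang::abort("unknown attention variant"))
}
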