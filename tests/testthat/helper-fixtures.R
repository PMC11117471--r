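# shared fixtures, built in code at test time

small_phantom <- function(image_size = 96, spacing = 0.6, ...) {
  phantom_spec(image_size = image_size, spacing = spacing, ...)
}

# a nodule centred in the left lung of `spec`, in world mm
centered_nodule <- function(spec, diameter_mm = 6, intensity = -50) {
  e <- spec$left_lung_ellipse
  nodule_spec(e$cx * spec$spacing, e$cy * spec$spacing, diameter_mm, intensity)
}

# independent disk rasterizer used as an oracle (deliberately written with
# plain loops, unlike the package's vectorized path)
oracle_disk_pixels <- function(n, cx_px, cy_px, r_px) {
  hits <- matrix(FALSE, n, n)
  for (row in seq_len(n)) for (col in seq_len(n)) {
    if ((col - 0.5 - cx_px)^2 + (row - 0.5 - cy_px)^2 <= r_px^2) {
      hits[row, col] <- TRUE
    }
  }
  hits
}

# two well-separated log-normal shape components
two_mode_components <- function(log_sd = 0.08) {
  tibble::tibble(mean_log_w = c(log(8), log(24)),
                 mean_log_h = c(log(10), log(20)),
                 log_sd = log_sd, weight = c(0.5, 0.5))
}

random_boxes <- function(n, lim = 100, seed = 1) {
  withr::with_seed(seed, {
    x0 <- runif(n, 0, lim); y0 <- runif(n, 0, lim)
    boxes(x0, y0, x0 + runif(n, 1, lim / 2), y0 + runif(n, 1, lim / 2))
  })
}

# linearly separable bright-blob vs background patch set
separable_patches <- function(n = 120, size = 16, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    x <- array(0, dim = c(n, size, size))
    ctr <- (size %/% 2 - 2):(size %/% 2 + 3)
    for (i in seq_len(n)) {
      b <- matrix(runif(size * size, 0, 0.2), size, size)
      if (y[i] == 1) b[ctr, ctr] <- b[ctr, ctr] + 0.8
      x[i, , ] <- b
    }
    list(x = x, y = y)
  })
}

# independent loop-based same-padding convolution (oracle for forward passes);
# x is an (N, H, W) single-channel batch, w is (O, 1, kh, kw)
conv_ref <- function(x, w, b) {
  N <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  O <- dim(w)[1]; kh <- dim(w)[3]; kw <- dim(w)[4]
  p <- (kh - 1) %/% 2
  out <- array(0, dim = c(N, O, H, W))
  for (n in seq_len(N)) for (o in seq_len(O)) for (r in seq_len(H)) for (cc in seq_len(W)) {
    acc <- b[o]
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      rr <- r + i - 1 - p; cj <- cc + j - 1 - p
      if (rr >= 1 && rr <= H && cj >= 1 && cj <= W) {
        acc <- acc + w[o, 1, i, j] * x[n, rr, cj]
      }
    }
    out[n, o, r, cc] <- acc
  }
  out
}

# exhaustive-partition k-means optimum for tiny instances (oracle)
brute_force_inertia <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      ss <- 0
      for (g in seq_len(k)) {
        pts <- X[assign == g, , drop = FALSE]
        ctr <- colMeans(pts)
        ss <- ss + sum(sweep(pts, 2, ctr)^2)
      }
      best <- min(best, ss)
    }
    i <- 1L
    while (i <= n && assign[i] == k) { assign[i] <- 1L; i <- i + 1L }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}
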