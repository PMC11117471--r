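#' Anchor set
#'
#' A fitted set of anchor shapes (width/height priors) plus a snapshot of how
#' it was obtained.
#'
#' @param shapes A [box_wh()] tibble of anchor shapes.
#' @param method `"kmeans"` or `"fcm"`.
#' @param config Named list snapshot of the fitting configuration.
#' @return An object of class `anchor_set`.
#' @export
anchor_set <- function(shapes, method = c("kmeans", "fcm"), config = list()) {
  method <- match.arg(method)
  shapes <- box_wh(shapes$width, shapes$height)
  structure(list(shapes = shapes, method = method, config = config),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set> %d shapes via %s\n", nrow(x$shapes), x$method))
  print(x$shapes)
  invisible(x)
}

as_wh_matrix <- function(points) {
  points <- tibble::as_tibble(points)
  if (!all(c("width", "height") %in% names(points))) {
    rlang::abort("points need columns width, height")
  }
  cbind(points$width, points$height)
}

# distance from every point (rows) to every centre (rows): n x c matrix
shape_distances <- function(X, C, dist = c("euclidean", "iou")) {
  dist <- match.arg(dist)
  if (dist == "euclidean") {
    sq <- outer(rowSums(X^2), rep(1, nrow(C))) +
      outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
    sqrt(pmax(sq, 0))
  } else {
    1 - wh_iou(box_wh(X[, 1], X[, 2]), box_wh(C[, 1], C[, 2]))
  }
}

#' Fuzzy membership degrees of points to cluster centres
#'
#' The fuzzy c-means membership update: for point j and centre i with
#' distances d,
#' \deqn{u_{ij} = \left[ \sum_{k=1}^{c} (d_{ij}/d_{kj})^{2/(m-1)} \right]^{-1}}
#' Rows sum to one; nearer centres receive larger memberships. A point that
#' coincides with one or more centres gets membership 1 on the lowest-index
#' coincident centre and 0 elsewhere.
#'
#' @param points A [box_wh()] tibble (one row per point).
#' @param centers A [box_wh()] tibble (one row per centre).
#' @param m Fuzzifier, > 1. Default 2.
#' @param dist Distance in shape space: `"euclidean"` on (width, height), or
#'   `"iou"` (1 - IoU of co-centred shapes).
#' @return An n x c membership matrix.
#' @export
fcm_memberships <- function(points, centers, m = 2, dist = "euclidean") {
  if (m <= 1) rlang::abort("fuzzifier m must be > 1")
  X <- as_wh_matrix(points); C <- as_wh_matrix(centers)
  if (nrow(C) == 0) rlang::abort("centers must be nonempty")
  d <- shape_distances(X, C, dist)
  memberships_from_distances(d, m)
}

memberships_from_distances <- function(d, m) {
  p <- 2 / (m - 1)
  w <- d^(-p)
  u <- w / rowSums(w)
  zero_rows <- which(apply(d, 1, function(r) any(r == 0)))
  for (j in zero_rows) {
    u[j, ] <- 0
    u[j, which(d[j, ] == 0)[1]] <- 1
  }
  u
}

# k-means++ style seeding in shape space
seed_centers <- function(X, c, seed) {
  withr::with_seed(seed, {
    n <- nrow(X)
    idx <- sample.int(n, 1)
    for (i in seq_len(c - 1)) {
      d2 <- apply(shape_distances(X, X[idx, , drop = FALSE])^2, 1, min)
      if (all(d2 == 0)) {
        idx <- c(idx, sample.int(n, 1))
      } else {
        idx <- c(idx, sample.int(n, 1, prob = d2))
      }
    }
    X[idx, , drop = FALSE]
  })
}

#' Fit anchor shapes by fuzzy c-means
#'
#' Alternates the fuzzy membership update with weighted-mean centre updates
#' (weights \eqn{u^m}) until the largest centre displacement falls below
#' `tol` or `max_iter` is reached. The objective
#' \eqn{J = \sum_j \sum_i u_{ij}^m d_{ij}^2} is recorded after every
#' iteration and is non-increasing.
#'
#' @param points A [box_wh()] tibble, n rows (n >= c).
#' @param c Number of clusters.
#' @param m Fuzzifier (> 1), default 2.
#' @param tol Convergence tolerance on the maximum centre displacement,
#'   default 1e-5.
#' @param max_iter Iteration cap, default 300.
#' @param seed Integer seed for the centre initialization.
#' @param dist Distance in shape space, see [fcm_memberships()].
#' @return An object of class `fcm_fit`: `anchors` ([anchor_set()]),
#'   `memberships` (n x c matrix), `objective` (per-iteration trace),
#'   `iterations`, `converged`, `points`.
#' @export
fcm_fit <- function(points, c, m = 2, tol = 1e-5, max_iter = 300,
                    seed = 1L, dist = "euclidean") {
  X <- as_wh_matrix(points)
  if (c < 1) rlang::abort("c must be >= 1")
  if (nrow(X) < c) rlang::abort("need at least c points")
  if (m <= 1 || tol <= 0) rlang::abort("need m > 1 and tol > 0")
  C <- seed_centers(X, c, seed)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0
  u <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    d <- shape_distances(X, C, dist)
    u <- memberships_from_distances(d, m)
    um <- u^m
    Cnew <- t(um) %*% X / colSums(um)
    # objective after the centre update, so the trace is monotone
    dnew <- shape_distances(X, Cnew, dist)
    objective <- c(objective, sum(um * dnew^2))
    shift <- max(abs(Cnew - C))
    C <- Cnew
    if (shift < tol) { converged <- TRUE; break }
  }
  u <- memberships_from_distances(shape_distances(X, C, dist), m)
  cfg <- list(c = c, m = m, tol = tol, max_iter = max_iter, seed = seed,
              dist = dist)
  structure(list(
    anchors = anchor_set(box_wh(C[, 1], C[, 2]), "fcm", cfg),
    memberships = u, objective = objective, iterations = iter,
    converged = converged, points = tibble::as_tibble(points)),
    class = "fcm_fit")
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("<fcm_fit> c = %d, m = %g, %d iterations (%s), objective %.6g\n",
              nrow(x$anchors$shapes), x$anchors$config$m, x$iterations,
              if (x$converged) "converged" else "iteration cap",
              utils::tail(x$objective, 1)))
  invisible(x)
}

# Lloyd iterations from a fixed set of initial centres, with empty-cluster
# repair: an emptied cluster is reseeded on the point farthest from its centre
lloyd <- function(X, centers, iter_max = 200) {
  for (it in seq_len(iter_max)) {
    d <- shape_distances(X, centers)
    cl <- max.col(-d, ties.method = "first")
    new_centers <- centers
    for (g in seq_len(nrow(centers))) {
      members <- which(cl == g)
      if (length(members) == 0) {
        far <- which.max(apply(d, 1, min))
        new_centers[g, ] <- X[far, ]
        cl[far] <- g
      } else {
        new_centers[g, ] <- colMeans(X[members, , drop = FALSE])
      }
    }
    if (all(new_centers == centers)) break
    centers <- new_centers
  }
  d <- shape_distances(X, centers)
  cl <- max.col(-d, ties.method = "first")
  inertia <- sum(d[cbind(seq_len(nrow(X)), cl)]^2)
  list(centers = centers, cluster = cl, inertia = inertia)
}

#' Fit anchor shapes by k-means
#'
#' Lloyd's algorithm: initial centres are k points drawn from the data,
#' assignments and centre updates alternate until the centres stop moving,
#' and an emptied cluster is reseeded on the farthest point. The best of
#' `nstart` random restarts (under the given seed) is kept; on small inputs
#' every distinct initial subset is tried instead.
#'
#' @param points A [box_wh()] tibble, n rows (n >= k).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nstart Number of random restarts, default 10.
#' @return An object of class `kmeans_fit`: `anchors` ([anchor_set()]),
#'   `inertia` (total within-cluster sum of squares), `cluster`
#'   (assignments), `points`.
#' @export
kmeans_fit <- function(points, k, seed = 1L, nstart = 10) {
  X <- as_wh_matrix(points)
  n <- nrow(X)
  if (n < k) rlang::abort("need at least k points")
  inits <- if (n <= 10) {
    utils::combn(n, k, simplify = FALSE)
  } else {
    withr::with_seed(seed,
      lapply(seq_len(nstart), function(i) sample.int(n, k)))
  }
  best <- NULL
  for (idx in inits) {
    fit <- lloyd(X, X[idx, , drop = FALSE])
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  cfg <- list(k = k, seed = seed, nstart = nstart)
  structure(list(
    anchors = anchor_set(box_wh(best$centers[, 1], best$centers[, 2]),
                         "kmeans", cfg),
    inertia = best$inertia, cluster = best$cluster,
    points = tibble::as_tibble(points)),
    class = "kmeans_fit")
}

#' @export
print.kmeans_fit <- function(x, ...) {
  cat(sprintf("<kmeans_fit> k = %d, inertia %.6g\n",
              nrow(x$anchors$shapes), x$inertia))
  invisible(x)
}

#' Mean best IoU of a box population against an anchor set
#'
#' For every box, the best IoU achievable by any anchor when both are centred
#' at the origin; averaged over boxes. A standard summary of how well a small
#' set of anchor shapes covers a population of object shapes.
#'
#' @param boxes A [box_wh()] tibble of object shapes.
#' @param anchors An [anchor_set()] or a [box_wh()] tibble.
#' @return A number in `[0, 1]`.
#' @export
mean_best_iou <- function(boxes, anchors) {
  shapes <- if (inherits(anchors, "anchor_set")) anchors$shapes else
    tibble::as_tibble(anchors)
  if (nrow(boxes) == 0 || nrow(shapes) == 0) {
    rlang::abort("boxes and anchors must both be nonempty")
  }
  mean(apply(wh_iou(box_wh(boxes$width, boxes$height),
                    box_wh(shapes$width, shapes$height)), 1, max))
}
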