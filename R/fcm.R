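#' Parameters for fuzzy C-means clustering
#'
#' @param n_clusters number of clusters `c`; 3 for the three brain tissues.
#' @param fuzziness membership exponent `p > 1`; 2 is the conventional
#'   choice and the package default.
#' @param eps stop when the objective `J` changes by less than this between
#'   iterations.
#' @param max_iters iteration cap.
#' @param seed RNG seed used only for the degenerate-cluster fallback
#'   (an empty cluster is re-seeded at a random feature).
#' @return An object of class `fcm_params`.
#' @export
fcm_params <- function(n_clusters = 3L, fuzziness = 2, eps = 1e-5,
                       max_iters = 300L, seed = 1L) {
  if (n_clusters < 1L) .stopf("n_clusters must be >= 1")
  if (fuzziness <= 1) .stopf("fuzziness must be > 1")
  if (eps <= 0 || max_iters < 1L) .stopf("invalid eps or max_iters")
  structure(list(n_clusters = as.integer(n_clusters), fuzziness = fuzziness,
                 eps = eps, max_iters = as.integer(max_iters),
                 seed = as.integer(seed)),
            class = "fcm_params")
}

#' Fuzzy membership update
#'
#' Computes `u_ik = (1 / d_ik^2)^(1/(p-1)) / sum_j (1 / d_jk^2)^(1/(p-1))`
#' with `d_ik = |y_k - v_i|`. Every row sums to 1. A feature coinciding
#' with one or more centers receives crisp membership split equally among
#' the coincident centers.
#'
#' @param features numeric vector of scalar features (one per object).
#' @param centers numeric vector of cluster centers.
#' @param p fuzziness exponent (> 1).
#' @return A `length(features)` x `length(centers)` membership matrix.
#' @export
update_memberships <- function(features, centers, p = 2) {
  d2 <- outer(features, centers, function(y, v) (y - v)^2)
  zero <- d2 <= .Machine$double.eps^2
  u <- (1 / pmax(d2, .Machine$double.xmin))^(1 / (p - 1))
  u <- u / rowSums(u)
  hit <- rowSums(zero) > 0L
  if (any(hit)) {
    u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' Cluster center update
#'
#' Computes `v_i = sum_k u_ik^p y_k / sum_k u_ik^p`.
#'
#' @param features numeric vector of scalar features.
#' @param U membership matrix (rows = objects, columns = clusters).
#' @param p fuzziness exponent.
#' @return Numeric vector of updated centers.
#' @export
update_centers <- function(features, U, p = 2) {
  uw <- U^p
  denom <- colSums(uw)
  if (any(denom <= 0)) .stopf("membership column with zero total weight")
  colSums(uw * features) / denom
}

#' Fuzzy C-means clustering of scalar features
#'
#' Alternates [update_memberships] and [update_centers] from a
#' deterministic initialisation (centers at `c` evenly spaced quantiles of
#' the features) until the objective `J = sum u^p d^2` changes by less than
#' `eps` or `max_iters` is reached. The returned centers are sorted
#' ascending with membership columns reordered to match, so on brain data
#' cluster 1 is the darkest tissue (CSF) and cluster `c` the brightest
#' (white matter). If a cluster ever empties it is re-seeded at a random
#' feature drawn under `params$seed`.
#'
#' @param features numeric vector with at least `n_clusters` distinct
#'   values.
#' @param params an [fcm_params].
#' @return An object of class `fcm_result`: list with `centers` (ascending),
#'   `memberships`, `objective_trace`, `iterations`, `converged`.
#' @examples
#' r <- fcm_cluster(c(1, 1.1, 5, 5.2, 9, 9.1), fcm_params(n_clusters = 3))
#' round(r$centers, 2)
#' @export
fcm_cluster <- function(features, params = fcm_params()) {
  features <- as.numeric(features)
  cc <- params$n_clusters
  p <- params$fuzziness
  if (length(unique(features)) < cc) {
    .stopf("need at least %d distinct feature values, got %d",
           cc, length(unique(features)))
  }
  centers <- stats::quantile(features, probs = (2 * seq_len(cc) - 1) / (2 * cc),
                             names = FALSE, type = 7)
  if (anyDuplicated(centers)) {
    centers <- .with_seed(params$seed, sort(sample(unique(features), cc)))
  }
  trace <- numeric(0)
  J_prev <- Inf
  converged <- FALSE
  U <- NULL
  rng_bump <- 0L
  for (q in seq_len(params$max_iters)) {
    U <- update_memberships(features, centers, p)
    uw_sum <- colSums(U^p)
    if (any(uw_sum <= .Machine$double.xmin)) {
      dead <- which(uw_sum <= .Machine$double.xmin)
      rng_bump <- rng_bump + 1L
      centers[dead] <- .with_seed(params$seed + rng_bump,
                                  sample(unique(features), length(dead)))
      U <- update_memberships(features, centers, p)
    }
    centers <- update_centers(features, U, p)
    d2 <- outer(features, centers, function(y, v) (y - v)^2)
    J <- sum(U^p * d2)
    trace <- c(trace, J)
    if (is.finite(J_prev) && abs(J_prev - J) < params$eps) {
      converged <- TRUE
      break
    }
    J_prev <- J
  }
  ord <- order(centers)
  structure(list(centers = centers[ord],
                 memberships = U[, ord, drop = FALSE],
                 objective_trace = trace,
                 iterations = length(trace),
                 converged = converged),
            class = "fcm_result")
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("<fcm_result> %d objects, %d clusters, %d iterations (%s)\n",
              nrow(x$memberships), length(x$centers), x$iterations,
              if (x$converged) "converged" else "iteration cap"))
  cat("centers:", paste(sprintf("%.3f", x$centers), collapse = ", "), "\n")
  invisible(x)
}

#' Pixel-level fuzzy C-means baseline
#'
#' Clusters the foreground pixel intensities directly (no superpixels) and
#' assigns each pixel the class of its maximal membership; this is the
#' plain-FCM comparator in the evaluation harness. Pixels below
#' `background_floor` are labelled 0.
#'
#' @param img a [gray_image] (or matrix).
#' @param params an [fcm_params].
#' @param background_floor intensity below which a pixel is background;
#'   `NULL` clusters every pixel.
#' @return List with `class_map` (integer matrix: 0 = background, 1..c by
#'   ascending center intensity) and `fcm` (the [fcm_cluster] result).
#' @export
fcm_cluster_pixels <- function(img, params = fcm_params(), background_floor = 32) {
  img <- .as_gray_image(img)
  mask <- if (is.null(background_floor)) {
    matrix(TRUE, img$M, img$N)
  } else {
    img$pixels >= background_floor
  }
  if (!any(mask)) .stopf("no foreground pixels above background_floor")
  res <- fcm_cluster(img$pixels[mask], params)
  cls <- max.col(res$memberships, ties.method = "first")
  class_map <- matrix(0L, img$M, img$N)
  class_map[mask] <- cls
  list(class_map = class_map, fcm = res)
}
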