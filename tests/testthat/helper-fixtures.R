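# Shared fixtures built in code.

# Small phantom used by fast unit tests.
small_phantom <- function(size = 64, noise = 0, bias = 0, gs = 1L) {
  make_phantom(phantom_spec(size = c(size, size), noise_pct = noise,
                            bias_pct = bias, geometry_seed = gs,
                            noise_seed = gs + 100L))
}

# Hand-built superpixel map: a horizontal chain of equally sized regions on
# a 4-row strip, with per-region mean intensities as given.
chain_map <- function(means, cols_per_region = 4L) {
  k <- length(means)
  labels <- matrix(rep(seq_len(k), each = 4L * cols_per_region), nrow = 4L)
  px <- matrix(rep(means, each = 4L * cols_per_region), nrow = 4L)
  superpixel_map(labels, px)
}

# Minimal fcm_result stand-in for labeling tests.
mock_fcm <- function(U, centers = seq_len(ncol(U))) {
  structure(list(centers = centers, memberships = U,
                 objective_trace = numeric(0), iterations = 0L,
                 converged = TRUE),
            class = "fcm_result")
}

# Edge-replicated mask shift: out[i, j] = m[i - dr, j - dc].
shift_mask <- function(m, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(m)) - dr, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) - dc, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Closed-form fuzzy C-means objective for p = 2 with memberships optimal
# for the given centers: J(V) = sum_k 1 / sum_i (1 / d_ik^2).
fcm_objective_p2 <- function(features, centers) {
  sum(vapply(features, function(y) {
    w <- 1 / (y - centers)^2
    1 / sum(w)
  }, numeric(1)))
}

# Nested grid search over center pairs (c = 2) refining around the best
# pair; independent oracle for the final FCM objective.
fcm_grid_oracle_p2 <- function(features, levels = 6L, n_grid = 41L) {
  lo <- min(features); hi <- max(features)
  span <- hi - lo
  best <- c(lo, hi); best_j <- Inf
  for (lv in seq_len(levels)) {
    g1 <- seq(max(lo, best[1] - span), min(hi, best[1] + span), length.out = n_grid)
    g2 <- seq(max(lo, best[2] - span), min(hi, best[2] + span), length.out = n_grid)
    for (v1 in g1) for (v2 in g2) {
      if (v1 >= v2) next
      j <- fcm_objective_p2(features, c(v1, v2))
      if (j < best_j) { best_j <- j; best <- c(v1, v2) }
    }
    span <- span / (n_grid - 1) * 2
  }
  list(centers = best, objective = best_j)
}
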