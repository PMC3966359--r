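# Internal numerical helpers shared across modules.

# Shift a matrix by (dr, dc) with replicated edges: out[i, j] = m[i - dr, j - dc].
.shift <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Central-difference gradient; gx is the derivative along rows, gy along columns.
.grad <- function(m) {
  list(
    gx = (.shift(m, -1L, 0L) - .shift(m, 1L, 0L)) / 2,
    gy = (.shift(m, 0L, -1L) - .shift(m, 0L, 1L)) / 2
  )
}

.grad_mag <- function(m) {
  g <- .grad(m)
  sqrt(g$gx^2 + g$gy^2)
}

# One-dimensional Gaussian smoothing operator as an n x n band matrix with
# edge renormalisation; smoothing a matrix is then two matrix products.
.gauss_band <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  i <- rep(seq_len(n), each = 2L * r + 1L)
  j <- i + rep(seq(-r, r), times = n)
  w <- rep(k, times = n)
  ok <- j >= 1L & j <= n
  B <- matrix(0, n, n)
  B[cbind(i[ok], j[ok])] <- w[ok]
  B / rowSums(B)
}

.gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  Br <- .gauss_band(nrow(m), sigma)
  Bc <- .gauss_band(ncol(m), sigma)
  Br %*% m %*% t(Bc)
}

# Euclidean distance of every pixel to the nearest TRUE pixel of `target`.
# Returns +Inf everywhere when `target` is empty.
.dist_to <- function(target) {
  if (!any(target)) {
    return(matrix(Inf, nrow(target), ncol(target)))
  }
  if (all(target)) {
    return(matrix(0, nrow(target), ncol(target)))
  }
  m <- matrix(as.numeric(!target), nrow(target), ncol(target))
  as.matrix(EBImage::distmap(m, metric = "euclidean"))
}

# 4-connected component labelling of a logical mask.
.label_components <- function(mask) {
  if (!any(mask)) {
    return(matrix(0L, nrow(mask), ncol(mask)))
  }
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
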