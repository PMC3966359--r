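#' Parameters for turbopixel superpixel evolution
#'
#' Controls the seeded narrow-band level-set evolution that partitions an
#' image into compact superpixels. The evolution speed at each boundary
#' point is the product `S_I * S_B` of an image-driven term and a
#' proximity term that freezes fronts where regions meet.
#'
#' @param n_seeds number of seeds `L`; default (`NULL`) is
#'   `round(M * N / 256)`, i.e. superpixels of roughly 16 x 16 pixels.
#' @param alpha curvature weight in the reaction term `(1 - alpha * kappa)`.
#' @param beta weight of the doublet term `N . grad(phi)` attracting the
#'   boundary to image edges.
#' @param gamma regularisation constant in the affinity exponent
#'   `E = |grad I| / (G_sigma * |grad I| + gamma)`, on the unit-normalized
#'   gradient scale.
#' @param nu decay constant of the local affinity `phi = exp(-E / nu)`.
#' @param sigma Gaussian scale (pixels) used to smooth the gradient
#'   magnitude inside `E`.
#' @param dt evolution time step.
#' @param band_width half-width (pixels) of the narrow band around the
#'   front within which the embedding is updated.
#' @param max_iters iteration cap.
#' @param tol stop when the fraction of pixels newly assigned per iteration
#'   (averaged over a short window) falls below this value.
#' @param reinit_every reinitialise the embedding as an exact signed
#'   Euclidean distance from the assigned mask every this many iterations.
#' @param sb_width ramp width (pixels) of the proximity speed `S_B`.
#' @return An object of class `turbopixel_params`.
#' @export
turbopixel_params <- function(n_seeds = NULL, alpha = 0.3, beta = 1.0,
                              gamma = 2.5, nu = 0.3, sigma = 1.5, dt = 0.5,
                              band_width = 4, max_iters = 500L, tol = 1e-4,
                              reinit_every = 10L, sb_width = 2) {
  if (!is.null(n_seeds) && n_seeds < 1L) .stopf("n_seeds must be >= 1")
  if (alpha < 0 || beta < 0) .stopf("alpha and beta must be >= 0")
  if (gamma <= 0 || nu <= 0 || sigma <= 0) {
    .stopf("gamma, nu, sigma must all be > 0")
  }
  if (dt <= 0 || band_width < 1 || max_iters < 1L || tol < 0) {
    .stopf("invalid dt, band_width, max_iters or tol")
  }
  structure(list(n_seeds = if (is.null(n_seeds)) NULL else as.integer(n_seeds),
                 alpha = alpha, beta = beta, gamma = gamma, nu = nu,
                 sigma = sigma, dt = dt, band_width = band_width,
                 max_iters = as.integer(max_iters), tol = tol,
                 reinit_every = as.integer(reinit_every), sb_width = sb_width),
            class = "turbopixel_params")
}

#' Place superpixel seeds on a gradient-avoiding lattice
#'
#' Seeds are laid out on a near-uniform lattice and each is moved, within a
#' 3 x 3 window, to the local minimum of the Gaussian-smoothed image
#' gradient magnitude so that no seed starts on or next to an edge (the
#' smoothing spreads edge energy onto one-pixel-wide ridges whose centre
#' the raw central-difference gradient misses). The lattice site wins ties,
#' so a constant image is not perturbed; remaining ties break in row-major
#' order. A perturbation that would collide with an earlier seed is
#' discarded.
#'
#' @param img a [gray_image] (or matrix).
#' @param L number of seeds.
#' @param sigma Gaussian scale (pixels) for the edge-energy smoothing.
#' @return An `L` x 2 integer matrix of (row, col) seed coordinates, with
#'   the smoothed edge-energy field attached as attribute `"field"`.
#' @export
place_seeds <- function(img, L, sigma = 1.5) {
  img <- .as_gray_image(img)
  M <- img$M; N <- img$N
  L <- as.integer(L)
  if (L < 1L) .stopf("L must be >= 1")
  if (L > M * N) .stopf("L = %d exceeds the number of available lattice sites", L)
  n_r <- max(1L, as.integer(round(sqrt(L * M / N))))
  n_c <- as.integer(ceiling(L / n_r))
  while (n_r * n_c < L) n_r <- n_r + 1L
  rows <- pmin(pmax(as.integer(round((seq_len(n_r) - 0.5) * M / n_r)), 1L), M)
  cols <- pmin(pmax(as.integer(round((seq_len(n_c) - 0.5) * N / n_c)), 1L), N)
  sites <- cbind(row = rep(rows, each = n_c), col = rep(cols, times = n_r))
  if (nrow(sites) > L) {
    # Surplus lattice sites: keep the L sites closest to the image centre,
    # preserving row-major order among the kept ones.
    d <- (sites[, 1] - (M + 1) / 2)^2 + (sites[, 2] - (N + 1) / 2)^2
    keep <- sort(order(d, seq_len(nrow(sites)))[seq_len(L)])
    sites <- sites[keep, , drop = FALSE]
  }
  g <- .gaussian_smooth(.grad_mag(img$pixels), sigma)
  out <- matrix(0L, L, 2L, dimnames = list(NULL, c("row", "col")))
  taken <- matrix(FALSE, M, N)
  for (k in seq_len(L)) {
    r0 <- sites[k, 1]; c0 <- sites[k, 2]
    rr <- max(1L, r0 - 1L):min(M, r0 + 1L)
    cc <- max(1L, c0 - 1L):min(N, c0 + 1L)
    cand <- cbind(rep(rr, each = length(cc)), rep(cc, times = length(rr)))  # row-major
    # Lattice site first so a zero-gradient (tied) window leaves the seed in
    # place; remaining ties break in row-major order.
    cand <- rbind(c(r0, c0), cand[!(cand[, 1] == r0 & cand[, 2] == c0), , drop = FALSE])
    best <- cand[which.min(g[cand]), ]
    if (taken[best[1], best[2]]) best <- c(r0, c0)
    out[k, ] <- best
    taken[best[1], best[2]] <- TRUE
  }
  attr(out, "field") <- g
  out
}

#' Local affinity field
#'
#' Computes `phi(x, y) = exp(-E / nu)` with
#' `E = |grad I| / (G_sigma * |grad I| + gamma)`, where `G_sigma * |grad I|`
#' is the Gaussian-smoothed gradient magnitude and the gradient magnitude is
#' first normalized to \[0, 1\]. The affinity is 1 wherever the gradient
#' vanishes and drops near edges, slowing the evolving fronts there.
#'
#' @param img a [gray_image] (or matrix).
#' @param params a [turbopixel_params].
#' @return A matrix with values in (0, 1\].
#' @export
local_affinity <- function(img, params = turbopixel_params()) {
  img <- .as_gray_image(img)
  g <- .grad_mag(img$pixels)
  mx <- max(g)
  if (mx > 0) g <- g / mx
  sm <- .gaussian_smooth(g, params$sigma)
  exp(-(g / (sm + params$gamma)) / params$nu)
}

# Image-driven speed S_I = (1 - alpha * kappa) * phi - beta * (N . grad phi).
# The embedding is stored inside-positive (assigned <=> psi >= 0); the
# curvature/normal formulas assume an outside-positive embedding, so they
# are evaluated on -psi. `phi_grad` may be precomputed.
#' Image-driven evolution speed
#'
#' Combines a curvature-regularised reaction term with a doublet term that
#' attracts the front to edges of the affinity field. On a flat front in a
#' constant-affinity region the speed equals the affinity; on a circular
#' front of radius `r` it is `1 - alpha / r`.
#'
#' @param state list with element `psi`, the signed-distance-like embedding
#'   (positive on assigned pixels).
#' @param phi affinity field from [local_affinity].
#' @param params a [turbopixel_params].
#' @param phi_grad optional precomputed gradient of `phi` (list `gx`, `gy`).
#' @return A matrix of speeds (unclamped).
#' @export
speed_si <- function(state, phi, params = turbopixel_params(), phi_grad = NULL) {
  eps <- 1e-8
  po <- -state$psi
  gx <- (.shift(po, -1L, 0L) - .shift(po, 1L, 0L)) / 2
  gy <- (.shift(po, 0L, -1L) - .shift(po, 0L, 1L)) / 2
  gxx <- .shift(po, -1L, 0L) - 2 * po + .shift(po, 1L, 0L)
  gyy <- .shift(po, 0L, -1L) - 2 * po + .shift(po, 0L, 1L)
  gxy <- (.shift(po, -1L, -1L) + .shift(po, 1L, 1L) -
          .shift(po, -1L, 1L) - .shift(po, 1L, -1L)) / 4
  den <- gx^2 + gy^2
  kappa <- (gxx * gy^2 - 2 * gx * gy * gxy + gyy * gx^2) / (den^1.5 + eps)
  nmag <- sqrt(den) + eps
  if (is.null(phi_grad)) phi_grad <- .grad(phi)
  (1 - params$alpha * kappa) * phi -
    params$beta * ((gx / nmag) * phi_grad$gx + (gy / nmag) * phi_grad$gy)
}

#' Proximity speed freezing fronts between regions
#'
#' For every pixel, computes the distance `d1` to the nearest region and
#' `d2` to the nearest *other* region and returns the ramp
#' `min((d2 - d1) / sb_width, 1)`: 0 on pixels equidistant between two
#' distinct growing regions (the homotopic skeleton) and 1 far from any
#' competing region. With a single region the speed is 1 everywhere.
#'
#' @param state list with element `labels`, the current integer region map
#'   (0 = unassigned).
#' @param sb_width ramp width in pixels.
#' @return A matrix with values in \[0, 1\].
#' @export
speed_sb <- function(state, sb_width = 2) {
  labels <- state$labels
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) <= 1L) return(matrix(1, nrow(labels), ncol(labels)))
  d1 <- matrix(Inf, nrow(labels), ncol(labels))
  d2 <- d1
  for (i in ids) {
    di <- .dist_to(labels == i)
    closer <- di < d1
    d2 <- pmin(d2, ifelse(closer, d1, di))
    d1 <- pmin(d1, di)
  }
  pmin(pmax((d2 - d1) / sb_width, 0), 1)
}

#' Partition an image into superpixels by level-set evolution
#'
#' Grows `L` seeded regions with the narrow-band update
#' `psi <- psi + S_I * S_B * |grad psi| * dt` (embedding stored positive on
#' assigned pixels), inheriting region labels along 4-connectivity. A pixel
#' whose assigned 4-neighbours carry two or more distinct labels becomes a
#' frozen skeleton pixel, so regions can touch but never merge. Evolution
#' stops when the newly-assigned fraction falls below `tol` or at
#' `max_iters`; remaining unassigned pixels (the thin inter-region skeleton
#' and any stalled area) are then attached to the adjacent region with the
#' nearest mean intensity, so the result is a full partition.
#'
#' @param img a [gray_image] (or matrix).
#' @param params a [turbopixel_params].
#' @param seed unused placeholder for interface stability; the evolution is
#'   fully deterministic.
#' @return A [superpixel_map] with `K <= L` regions.
#' @export
evolve_turbopixels <- function(img, params = turbopixel_params(), seed = NULL) {
  img <- .as_gray_image(img)
  px <- img$pixels
  M <- img$M; N <- img$N; n_px <- M * N
  L <- if (is.null(params$n_seeds)) max(1L, as.integer(round(n_px / 256))) else params$n_seeds

  seeds <- place_seeds(img, L, params$sigma)
  labels <- matrix(0L, M, N)
  labels[seeds] <- seq_len(nrow(seeds))
  assigned <- labels > 0L
  skeleton <- matrix(FALSE, M, N)

  phi <- local_affinity(img, params)
  phig <- .grad(phi)
  psi <- NULL
  sb <- matrix(1, M, N)
  win <- 2L * params$reinit_every
  new_counts <- integer(0)
  it <- 0L
  converged <- FALSE

  while (it < params$max_iters) {
    it <- it + 1L
    if ((it - 1L) %% params$reinit_every == 0L) {
      if (all(assigned | skeleton)) { converged <- TRUE; break }
      psi <- .dist_to(!assigned) - .dist_to(assigned) + 0.5
      psi[skeleton] <- -0.5
      sb <- speed_sb(list(labels = labels), params$sb_width)
    }
    band <- !assigned & !skeleton & psi > -params$band_width
    if (!any(band)) { converged <- TRUE; break }

    pg <- .grad(psi)
    gm <- sqrt(pg$gx^2 + pg$gy^2)
    si <- speed_si(list(psi = psi), phi, params, phig)
    sp <- pmin(pmax(si, 0), 1) * sb
    psi[band] <- psi[band] + sp[band] * gm[band] * params$dt

    cand <- which(band & psi >= 0)
    n_new <- 0L
    if (length(cand)) {
      nb <- cbind(.shift(labels, 1L, 0L)[cand], .shift(labels, -1L, 0L)[cand],
                  .shift(labels, 0L, 1L)[cand], .shift(labels, 0L, -1L)[cand])
      mx <- pmax(nb[, 1], nb[, 2], nb[, 3], nb[, 4])
      conflict <- rowSums(nb > 0L & nb != mx) > 0L
      grow <- mx > 0L & !conflict
      if (any(grow)) {
        labels[cand[grow]] <- mx[grow]
        assigned[cand[grow]] <- TRUE
      }
      if (any(conflict)) {
        skeleton[cand[conflict]] <- TRUE
        psi[cand[conflict]] <- -0.5
      }
      orphan <- mx == 0L
      if (any(orphan)) psi[cand[orphan]] <- -0.05  # retry once a neighbour is assigned
      n_new <- sum(grow)
    }
    new_counts <- c(new_counts, n_new)
    if (length(new_counts) > win) new_counts <- new_counts[-1L]
    if (all(assigned | skeleton)) { converged <- TRUE; break }
    if (length(new_counts) == win && sum(new_counts) < params$tol * n_px * win) break
  }
  if (!converged && it >= params$max_iters && any(labels == 0L)) {
    warning("turbopixel evolution did not converge within max_iters; ",
            "remaining pixels assigned by nearest-mean adjacency", call. = FALSE)
  }

  labels <- .assign_remaining(labels, px)
  sp <- superpixel_map(labels, px)
  attr(sp, "iterations") <- it
  attr(sp, "seeds") <- seeds
  sp
}

# Attach every unlabeled pixel to the 4-adjacent region whose mean intensity
# is nearest the pixel's own value; sweeps repeat until the partition covers
# the image. Region means are held fixed at their pre-cleanup values.
.assign_remaining <- function(labels, px) {
  if (!any(labels == 0L)) return(labels)
  means <- rep(NA_real_, max(labels))
  tab <- tapply(px[labels > 0L], labels[labels > 0L], mean)
  means[as.integer(names(tab))] <- tab
  repeat {
    un <- which(labels == 0L)
    if (!length(un)) break
    nb <- cbind(.shift(labels, 1L, 0L)[un], .shift(labels, -1L, 0L)[un],
                .shift(labels, 0L, 1L)[un], .shift(labels, 0L, -1L)[un])
    dmat <- matrix(Inf, length(un), 4L)
    pos <- nb > 0L
    dmat[pos] <- abs(px[un][row(nb)[pos]] - means[nb[pos]])
    has <- rowSums(pos) > 0L
    if (!any(has)) .stopf("unassigned pixels are disconnected from every region")
    dh <- dmat[has, , drop = FALSE]
    # Equal-distance ties alternate by pixel parity so that a bisector line
    # between equally matching regions splits evenly instead of draining to
    # one side; either choice is 4-adjacent, so connectivity is preserved.
    idx <- un[has]
    parity <- ((idx - 1L) %% nrow(labels) + (idx - 1L) %/% nrow(labels)) %% 2L
    pick_f <- max.col(-dh, ties.method = "first")
    pick_l <- max.col(-dh, ties.method = "last")
    pick <- ifelse(parity == 0L, pick_f, pick_l)
    labels[idx] <- nb[has, , drop = FALSE][cbind(seq_along(idx), pick)]
  }
  labels
}

#' Superpixel map with region statistics and adjacency
#'
#' Wraps an integer region label field (ids relabelled to a contiguous
#' `1..K`; 0 is reserved for off-mask pixels) together with per-region
#' statistics and the 4-connected region adjacency relation.
#'
#' @param labels integer matrix of region ids (0 allowed for off-mask).
#' @param pixels intensity matrix of the same shape.
#' @return An object of class `superpixel_map`: list with `labels`, `K`,
#'   `stats` (data frame: `id`, `n_px`, `mean`, `var`, bounding box) and
#'   `adjacency` (two-column matrix of region-id pairs, `i < j`).
#' @export
superpixel_map <- function(labels, pixels) {
  labels <- as.matrix(labels)
  pixels <- if (inherits(pixels, "gray_image")) pixels$pixels else as.matrix(pixels)
  if (!identical(dim(labels), dim(pixels))) .stopf("labels and pixels must have the same shape")
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) .stopf("label map contains no regions")
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  lab <- labels
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  K <- length(ids)

  f <- factor(lab[lab > 0L], levels = seq_len(K))
  v <- pixels[lab > 0L]
  n_px <- as.integer(table(f))
  mu <- as.numeric(tapply(v, f, mean))
  va <- as.numeric(tapply(v, f, stats::var))
  va[is.na(va)] <- 0
  ri <- row(lab)[lab > 0L]; ci <- col(lab)[lab > 0L]
  stats_df <- data.frame(
    id = seq_len(K), n_px = n_px, mean = mu, var = va,
    row_min = as.integer(tapply(ri, f, min)), row_max = as.integer(tapply(ri, f, max)),
    col_min = as.integer(tapply(ci, f, min)), col_max = as.integer(tapply(ci, f, max))
  )

  structure(list(labels = lab, K = K, stats = stats_df,
                 adjacency = .region_adjacency(lab)),
            class = "superpixel_map")
}

# 4-connected adjacency pairs (i < j) between positive region ids.
.region_adjacency <- function(lab) {
  h <- cbind(as.vector(lab[-nrow(lab), ]), as.vector(lab[-1L, ]))
  v <- cbind(as.vector(lab[, -ncol(lab)]), as.vector(lab[, -1L]))
  pr <- rbind(h, v)
  pr <- pr[pr[, 1] > 0L & pr[, 2] > 0L & pr[, 1] != pr[, 2], , drop = FALSE]
  if (!nrow(pr)) return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  pr <- cbind(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
  pr <- unique(pr)
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  dimnames(pr) <- list(NULL, c("i", "j"))
  pr
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("<superpixel_map> %d x %d, %d regions (mean size %.1f px)\n",
              nrow(x$labels), ncol(x$labels), x$K, mean(x$stats$n_px)))
  invisible(x)
}

#' Neighbouring regions of a region
#'
#' @param sp a [superpixel_map].
#' @param id region id.
#' @return Sorted integer vector of 4-adjacent region ids.
#' @export
region_neighbors <- function(sp, id) {
  a <- sp$adjacency
  sort(unique(c(a[a[, 1] == id, 2], a[a[, 2] == id, 1])))
}

#' Check the partition conditions of a superpixel map
#'
#' Verifies that the regions are non-empty, pairwise disjoint (structural in
#' the label-map representation), 4-connected, and that together with the
#' off-mask label they cover the image grid.
#'
#' @param sp a [superpixel_map].
#' @param require_cover if `TRUE`, no pixel may carry label 0.
#' @return `TRUE` invisibly, or an error describing the violated condition.
#' @export
validate_partition <- function(sp, require_cover = TRUE) {
  lab <- sp$labels
  if (require_cover && any(lab == 0L)) .stopf("partition does not cover the image")
  ids <- sort(unique(lab[lab > 0L]))
  if (!identical(ids, seq_len(sp$K))) .stopf("region ids are not contiguous 1..K")
  if (any(sp$stats$n_px < 1L)) .stopf("empty region present")
  for (i in ids) {
    cc <- .label_components(lab == i)
    if (max(cc) != 1L) .stopf("region %d is not 4-connected", i)
  }
  invisible(TRUE)
}
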