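#' Parameters for deep segmentation
#'
#' Deep segmentation re-examines the highest-variance superpixels (those
#' most likely to straddle a tissue boundary) and splits them by an
#' automatic intensity threshold. Connected components whose area fraction
#' of the parent region exceeds the scale parameter `t` become regions of
#' their own; smaller components are treated as noise and re-absorbed.
#'
#' @param variance_fraction fraction in \[0, 1\] of superpixels (ranked by
#'   intensity variance, descending, ties by lower region id) selected for
#'   re-segmentation; 0 disables deep segmentation.
#' @param t scale parameter in (0, 1): minimum area fraction, relative to
#'   the parent superpixel, for a split component to be kept.
#' @param min_region_px regions smaller than this are never split.
#' @param max_rounds splitting repeats on recomputed statistics until no
#'   region changes or this many rounds have run; boundary superpixels that
#'   straddle three tissues need more than one binary split.
#' @return An object of class `deepseg_params`.
#' @export
deepseg_params <- function(variance_fraction = 0.2, t = 0.05,
                           min_region_px = 9L, max_rounds = 4L) {
  if (variance_fraction < 0 || variance_fraction > 1) {
    .stopf("variance_fraction must lie in [0, 1]")
  }
  if (t <= 0 || t >= 1) .stopf("t must lie in (0, 1)")
  if (min_region_px < 1L || max_rounds < 1L) .stopf("invalid min_region_px or max_rounds")
  structure(list(variance_fraction = variance_fraction, t = t,
                 min_region_px = as.integer(min_region_px),
                 max_rounds = as.integer(max_rounds)),
            class = "deepseg_params")
}

#' Otsu's automatic threshold
#'
#' Exhaustively maximises the between-class variance over a 256-bin
#' histogram of the values; returns the bin boundary threshold (values
#' strictly above it form the upper class), or `NA` when the values are
#' constant.
#'
#' @param values numeric vector of intensities.
#' @param n_bins number of histogram bins.
#' @return Threshold on the intensity scale, or `NA_real_`.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- values[is.finite(values)]
  if (!length(v)) return(NA_real_)
  rng <- range(v)
  if (rng[2] <= rng[1]) return(NA_real_)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE),
                nbins = n_bins)
  mids <- (br[-1L] + br[-(n_bins + 1L)]) / 2
  w <- cumsum(h)
  s <- cumsum(h * mids)
  w0 <- w[-n_bins]; w1 <- w[n_bins] - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- s[-n_bins] / w0
  mu1 <- (s[n_bins] - s[-n_bins]) / w1
  bc <- rep(-Inf, n_bins - 1L)
  bc[valid] <- (w0 * w1 * (mu0 - mu1)^2)[valid]
  k <- which.max(bc)
  if (!is.finite(bc[k])) return(NA_real_)
  br[k + 1L]
}

#' Select split candidates by intensity variance
#'
#' @param sp a [superpixel_map].
#' @param params a [deepseg_params].
#' @return Integer vector of the top `ceiling(variance_fraction * K)`
#'   region ids ranked by variance (descending; ties by lower id).
#' @export
select_candidates <- function(sp, params = deepseg_params()) {
  n_sel <- ceiling(params$variance_fraction * sp$K)
  if (n_sel < 1L) return(integer(0))
  ord <- order(-sp$stats$var, sp$stats$id)
  sp$stats$id[ord][seq_len(n_sel)]
}

#' Split one superpixel by automatic thresholding
#'
#' Computes an Otsu threshold over the region's pixels, cuts the region into
#' above/below 4-connected components, keeps every component whose pixel
#' fraction of the original region exceeds `t`, and re-absorbs each smaller
#' component into the adjacent kept component with the nearest mean
#' intensity (ties to the lower component). If no split survives (constant
#' region, region below `min_region_px`, or a single kept component) the
#' map is returned unchanged.
#'
#' @param img a [gray_image] (or matrix).
#' @param sp a [superpixel_map].
#' @param region_id id of the region to split.
#' @param params a [deepseg_params].
#' @return An updated [superpixel_map]; the region count never decreases.
#' @export
split_superpixel <- function(img, sp, region_id, params = deepseg_params()) {
  img <- .as_gray_image(img)
  if (!region_id %in% sp$stats$id) .stopf("region %d does not exist", region_id)
  new_lab <- .split_region_labels(sp$labels, img$pixels, region_id, params, sp$K)
  if (is.null(new_lab)) return(sp)
  superpixel_map(new_lab, img$pixels)
}

# Core of the split: returns an updated full label matrix with new region
# ids appended after `max_id`, or NULL when the region does not split.
.split_region_labels <- function(labels, px, region_id, params, max_id) {
  in_reg <- labels == region_id
  n0 <- sum(in_reg)
  if (n0 < params$min_region_px) return(NULL)
  th <- otsu_threshold(px[in_reg])
  if (is.na(th)) return(NULL)

  # Work inside the bounding box only.
  ri <- range(row(labels)[in_reg]); ci <- range(col(labels)[in_reg])
  sub <- in_reg[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
  spx <- px[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
  cc_hi <- .label_components(sub & spx > th)
  cc_lo <- .label_components(sub & spx <= th)
  n_hi <- max(cc_hi)
  comp <- matrix(0L, nrow(sub), ncol(sub))
  comp[cc_hi > 0L] <- cc_hi[cc_hi > 0L]
  comp[cc_lo > 0L] <- cc_lo[cc_lo > 0L] + n_hi
  n_comp <- max(comp)
  if (n_comp < 2L) return(NULL)
  sizes <- tabulate(comp[comp > 0L], nbins = n_comp)
  kept <- which(sizes / n0 > params$t)
  if (length(kept) < 2L) return(NULL)

  means <- as.numeric(tapply(spx[comp > 0L], factor(comp[comp > 0L], levels = seq_len(n_comp)), mean))
  # Re-absorb sub-t components into an adjacent kept component with nearest
  # mean intensity, iterating so chains of small components drain into the
  # kept ones; the region is connected, so this terminates.
  assign_to <- integer(n_comp)
  assign_to[kept] <- kept
  pending <- setdiff(which(sizes > 0L), kept)
  while (length(pending)) {
    progressed <- FALSE
    for (cid in pending) {
      m <- comp == cid
      nb_ids <- unique(c(.shift(comp, 1L, 0L)[m], .shift(comp, -1L, 0L)[m],
                         .shift(comp, 0L, 1L)[m], .shift(comp, 0L, -1L)[m]))
      nb_ids <- nb_ids[nb_ids > 0L & nb_ids != cid]
      targets <- unique(assign_to[nb_ids])
      targets <- targets[targets > 0L]
      if (length(targets)) {
        d <- abs(means[cid] - means[targets])
        assign_to[cid] <- min(targets[d == min(d)])
        progressed <- TRUE
      }
    }
    pending <- which(sizes > 0L & assign_to == 0L)
    if (!progressed && length(pending)) {
      # No kept component reachable (should not happen in a connected
      # region); keep the largest pending component as its own region.
      big <- pending[which.max(sizes[pending])]
      assign_to[big] <- big
      kept <- c(kept, big)
      pending <- setdiff(pending, big)
    }
  }

  final <- assign_to[comp[comp > 0L]]
  kept_sorted <- sort(unique(final))
  new_ids <- c(region_id, max_id + seq_len(length(kept_sorted) - 1L))
  id_map <- integer(n_comp)
  id_map[kept_sorted] <- new_ids
  out <- labels
  sub_out <- out[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
  sub_out[comp > 0L] <- id_map[final]
  out[ri[1]:ri[2], ci[1]:ci[2]] <- sub_out
  out
}

#' Deep-segment high-variance superpixels
#'
#' Applies [split_superpixel] to every candidate returned by
#' [select_candidates], then recomputes statistics and adjacency and (by
#' default) repeats on the refreshed ranking until no region splits or
#' `max_rounds` is reached. The region count satisfies `K_out >= K_in` and
#' all partition conditions are preserved.
#'
#' @param img a [gray_image] (or matrix).
#' @param sp a [superpixel_map].
#' @param params a [deepseg_params].
#' @return An updated [superpixel_map].
#' @export
deep_segment <- function(img, sp, params = deepseg_params()) {
  img <- .as_gray_image(img)
  if (params$variance_fraction == 0) return(sp)
  for (round in seq_len(params$max_rounds)) {
    cands <- select_candidates(sp, params)
    lab <- sp$labels
    max_id <- sp$K
    changed <- FALSE
    for (id in cands) {
      new_lab <- .split_region_labels(lab, img$pixels, id, params, max_id)
      if (!is.null(new_lab)) {
        lab <- new_lab
        max_id <- max(lab)
        changed <- TRUE
      }
    }
    if (!changed) break
    sp <- superpixel_map(lab, img$pixels)
  }
  sp
}
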