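#' Parameters for superpixel labeling
#'
#' After clustering, a superpixel is labelled directly only when its
#' maximal membership is confident; the rest (the "fuzzy blocks") are
#' resolved by broadcasting labels from adjacent superpixels whose mean
#' intensity is similar under a Butterworth similarity.
#'
#' @param eta intensity tolerance (gray units) of the Butterworth
#'   similarity: two regions differing by exactly `eta` have similarity 0.5.
#' @param n even positive Butterworth order; larger values make the
#'   similarity fall off more steeply beyond `eta`.
#' @param T_c membership confidence threshold in (0, 1); regions whose
#'   maximal membership does not exceed it become fuzzy blocks. Use 0 to
#'   disable (pure argmax labeling).
#' @param T_s similarity confidence threshold in (0, 1); 0.5 means "adopt a
#'   neighbour's class when the means differ by less than `eta`".
#' @param max_broadcast_iters broadcast sweep cap; surviving fuzzy blocks
#'   then fall back to their argmax membership.
#' @return An object of class `labeling_params`.
#' @export
labeling_params <- function(eta = 10, n = 4L, T_c = 0.7, T_s = 0.5,
                            max_broadcast_iters = 10L) {
  if (eta <= 0) .stopf("eta must be > 0")
  n <- as.integer(n)
  if (n < 2L || n %% 2L != 0L) .stopf("n must be an even integer >= 2")
  if (T_c < 0 || T_c >= 1 || T_s <= 0 || T_s >= 1) {
    .stopf("T_c must lie in [0, 1) and T_s in (0, 1)")
  }
  if (max_broadcast_iters < 1L) .stopf("max_broadcast_iters must be >= 1")
  structure(list(eta = eta, n = n, T_c = T_c, T_s = T_s,
                 max_broadcast_iters = as.integer(max_broadcast_iters)),
            class = "labeling_params")
}

#' Butterworth similarity of two mean intensities
#'
#' `S = 1 / (1 + (|mu - mu_i| / eta)^n)`: 1 at equality, exactly 0.5 at a
#' difference of `eta` (the half-power point), strictly decreasing in the
#' difference, and steeper for larger even order `n`.
#'
#' @param mu,mu_i mean intensities (vectorised).
#' @param params a [labeling_params] supplying `eta` and `n`.
#' @return Similarity values in (0, 1\].
#' @export
butterworth_similarity <- function(mu, mu_i, params = labeling_params()) {
  1 / (1 + (abs(mu - mu_i) / params$eta)^params$n)
}

#' Confident initial labels and the fuzzy-block set
#'
#' Region `i` receives class `argmax U_i` when `max U_i > T_c` (argmax ties
#' break to the lower class index); otherwise it joins the fuzzy set `F`
#' (class `NA`). Regions outside `fg_ids` (background superpixels excluded
#' from clustering) are fixed at class 0.
#'
#' @param sp a [superpixel_map].
#' @param fcm an [fcm_result] whose rows correspond to `fg_ids`.
#' @param params a [labeling_params].
#' @param fg_ids region ids that were clustered; defaults to all regions.
#' @return List with `region_class` (integer vector over ids `1..K`; `NA`
#'   marks a fuzzy block) and `provenance` (character vector).
#' @export
initial_labels <- function(sp, fcm, params = labeling_params(),
                           fg_ids = sp$stats$id) {
  if (nrow(fcm$memberships) != length(fg_ids)) {
    .stopf("one membership row per clustered region required")
  }
  region_class <- rep(0L, sp$K)
  provenance <- rep("background", sp$K)
  mx <- apply(fcm$memberships, 1L, max)
  am <- max.col(fcm$memberships, ties.method = "first")
  conf <- mx > params$T_c
  region_class[fg_ids] <- ifelse(conf, am, NA_integer_)
  provenance[fg_ids] <- ifelse(conf, "confident", "fuzzy")
  list(region_class = region_class, provenance = provenance)
}

#' Resolve fuzzy blocks by Butterworth broadcast
#'
#' Iterates over the fuzzy set: in each sweep every fuzzy region compares
#' its mean intensity with all *currently labelled* tissue neighbours
#' (labels frozen at sweep start, regions visited in ascending id order)
#' and adopts the class of its most similar neighbour when that similarity
#' exceeds `T_s` (ties to the lower neighbour id). Sweeps repeat until the
#' fuzzy set empties or `max_broadcast_iters` is reached; survivors fall
#' back to their argmax membership, so no fuzzy block remains. Confident
#' regions are never relabelled.
#'
#' @param draft output of [initial_labels].
#' @param sp a [superpixel_map].
#' @param fcm the [fcm_result] used for the draft.
#' @param params a [labeling_params].
#' @param fg_ids region ids that were clustered.
#' @return List with `region_class` (no `NA` left) and `provenance`
#'   (`"confident"`, `"broadcast-<k>"` or `"fallback"`).
#' @export
broadcast_labels <- function(draft, sp, fcm, params = labeling_params(),
                             fg_ids = sp$stats$id) {
  region_class <- draft$region_class
  provenance <- draft$provenance
  mu <- sp$stats$mean
  for (iter in seq_len(params$max_broadcast_iters)) {
    fuzzy <- which(is.na(region_class))
    if (!length(fuzzy)) break
    frozen <- region_class
    for (j in sort(fuzzy)) {
      nb <- region_neighbors(sp, j)
      nb <- nb[!is.na(frozen[nb]) & frozen[nb] > 0L]
      if (!length(nb)) next
      s <- butterworth_similarity(mu[j], mu[nb], params)
      k <- which.max(s)  # nb sorted ascending, so ties go to the lower id
      if (s[k] > params$T_s) {
        region_class[j] <- frozen[nb[k]]
        provenance[j] <- sprintf("broadcast-%d", iter)
      }
    }
    if (identical(region_class, frozen)) break  # no change can ever occur again
  }
  fuzzy <- which(is.na(region_class))
  if (length(fuzzy)) {
    rows <- match(fuzzy, fg_ids)
    region_class[fuzzy] <- max.col(fcm$memberships[rows, , drop = FALSE],
                                   ties.method = "first")
    provenance[fuzzy] <- "fallback"
  }
  list(region_class = region_class, provenance = provenance)
}

#' Merge same-class adjacent regions into the final segmentation
#'
#' Maps every region to its class, producing the per-pixel class map, and
#' merges 4-adjacent same-class superpixels into single connected
#' components. The operation is idempotent.
#'
#' @param labeled list with `region_class` and `provenance` (from
#'   [broadcast_labels], or any full labelling).
#' @param sp a [superpixel_map].
#' @param class_names names for class codes `0..length(class_names) - 1`.
#' @return An object of class `tissue_segmentation`: list with `class_map`
#'   (integer matrix of class codes), `merged_labels` (components of the
#'   class map), `region_class`, `provenance` and `class_names`.
#' @export
merge_regions <- function(labeled, sp,
                          class_names = c("background", "csf", "gray", "white")) {
  region_class <- labeled$region_class
  if (anyNA(region_class)) .stopf("all regions must be classified before merging")
  class_map <- matrix(0L, nrow(sp$labels), ncol(sp$labels))
  fg <- sp$labels > 0L
  class_map[fg] <- region_class[sp$labels[fg]]
  merged <- matrix(0L, nrow(class_map), ncol(class_map))
  offset <- 0L
  for (cl in sort(unique(class_map[class_map > 0L]))) {
    cc <- .label_components(class_map == cl)
    merged[cc > 0L] <- cc[cc > 0L] + offset
    offset <- offset + max(cc)
  }
  structure(list(class_map = class_map, merged_labels = merged,
                 region_class = region_class, provenance = labeled$provenance,
                 class_names = class_names),
            class = "tissue_segmentation")
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  tab <- table(factor(x$class_map, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  cat(sprintf("<tissue_segmentation> %d x %d, %d merged components\n",
              nrow(x$class_map), ncol(x$class_map), max(x$merged_labels)))
  print(tab)
  invisible(x)
}

#' Write the per-region provenance sidecar
#'
#' Records, for each superpixel, its final class and the stage that
#' resolved it (confident, broadcast iteration, fallback, background) as a
#' JSON file next to a serialized segmentation.
#'
#' @param seg a `tissue_segmentation`.
#' @param path output `.json` path.
#' @export
write_provenance <- function(seg, path) {
  rec <- data.frame(region = seq_along(seg$region_class),
                    class = seg$class_names[seg$region_class + 1L],
                    resolved_by = seg$provenance)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
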