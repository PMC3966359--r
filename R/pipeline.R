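#' Assemble a full pipeline configuration
#'
#' Collects the parameters of every stage, applying the package defaults
#' and overriding them with any values supplied. Each argument is a named
#' list matching the corresponding constructor's arguments (see
#' [turbopixel_params], [deepseg_params], [fcm_params], [labeling_params]).
#'
#' @param turbopixel,deepseg,fcm,labeling named lists of overrides.
#' @param background_floor superpixels with mean intensity below this value
#'   are labelled background and excluded from tissue clustering.
#' @return An object of class `msfcm_config`.
#' @examples
#' cfg <- msfcm_config(fcm = list(fuzziness = 2.2), labeling = list(eta = 8))
#' cfg$labeling$eta
#' @export
msfcm_config <- function(turbopixel = list(), deepseg = list(), fcm = list(),
                         labeling = list(), background_floor = 32) {
  structure(list(
    turbopixel = do.call(turbopixel_params, turbopixel),
    deepseg = do.call(deepseg_params, deepseg),
    fcm = do.call(fcm_params, fcm),
    labeling = do.call(labeling_params, labeling),
    background_floor = background_floor
  ), class = "msfcm_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain any subset of the sections `turbopixel`, `deepseg`,
#' `fcm`, `labeling` and the scalar `background_floor`, with keys matching
#' the parameter constructors; missing values take the package defaults.
#'
#' @param path YAML file path.
#' @return An `msfcm_config`.
#' @export
read_msfcm_config <- function(path) {
  raw <- yaml::read_yaml(path)
  msfcm_config(
    turbopixel = raw$turbopixel %||% list(),
    deepseg = raw$deepseg %||% list(),
    fcm = raw$fcm %||% list(),
    labeling = raw$labeling %||% list(),
    background_floor = raw$background_floor %||% 32
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multistage superpixel fuzzy C-means segmentation
#'
#' Runs the full pipeline on a grayscale image: (1) turbopixel
#' over-segmentation into compact superpixels, (2) deep segmentation of
#' high-variance superpixels by automatic thresholding, (3) fuzzy C-means
#' clustering of superpixel mean intensities into three tissue classes,
#' (4) confidence-thresholded labeling with iterative Butterworth-similarity
#' broadcast over the region adjacency structure, and (5) merging of
#' adjacent same-class regions. Superpixels whose mean intensity falls
#' below `config$background_floor` are labelled background (class 0) and
#' excluded from clustering. With identical configuration and seed the
#' output is bit-identical.
#'
#' @param img a [gray_image] (or intensity matrix).
#' @param config an [msfcm_config].
#' @param seed integer seed forwarded to the clustering stage.
#' @return An object of class `msfcm_result`: list with `segmentation`
#'   (a `tissue_segmentation`; class codes 0 background, 1 CSF, 2 gray
#'   matter, 3 white matter), `superpixels` (after deep segmentation),
#'   `rough` (before), `fcm`, `fg_ids` and `config`.
#' @examples
#' p <- make_phantom(phantom_spec(size = c(64, 64)))
#' res <- msfcm_segment(p$image)
#' mean(res$segmentation$class_map == p$truth)
#' @export
msfcm_segment <- function(img, config = msfcm_config(), seed = 1L) {
  img <- .as_gray_image(img)
  config$fcm$seed <- as.integer(seed)

  rough <- evolve_turbopixels(img, config$turbopixel)
  sp <- deep_segment(img, rough, config$deepseg)

  fg_ids <- sp$stats$id[sp$stats$mean >= config$background_floor]
  if (length(unique(sp$stats$mean[fg_ids])) < config$fcm$n_clusters) {
    .stopf("fewer than %d distinct foreground superpixel means; cannot cluster",
           config$fcm$n_clusters)
  }
  fcm_res <- fcm_cluster(sp$stats$mean[fg_ids], config$fcm)

  draft <- initial_labels(sp, fcm_res, config$labeling, fg_ids)
  labeled <- broadcast_labels(draft, sp, fcm_res, config$labeling, fg_ids)
  seg <- merge_regions(labeled, sp)

  structure(list(segmentation = seg, superpixels = sp, rough = rough,
                 fcm = fcm_res, fg_ids = fg_ids, config = config),
            class = "msfcm_result")
}

#' @export
print.msfcm_result <- function(x, ...) {
  cat(sprintf("<msfcm_result> %d rough -> %d deep superpixels, FCM centers %s\n",
              x$rough$K, x$superpixels$K,
              paste(sprintf("%.1f", x$fcm$centers), collapse = "/")))
  print(x$segmentation)
  invisible(x)
}
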