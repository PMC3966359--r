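#' Jaccard similarity of two masks
#'
#' `J(S1, S2) = |S1 n S2| / |S1 u S2|` between a predicted class mask and
#' the corresponding ground-truth mask. Two empty masks are defined to have
#' similarity 1 (the ratio is otherwise undefined at 0/0).
#'
#' @param pred_mask,truth_mask logical matrices over the same pixel grid.
#' @return Jaccard similarity in \[0, 1\].
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, ] <- TRUE
#' b <- matrix(FALSE, 4, 4); b[2:3, ] <- TRUE
#' jaccard(a, b)  # 4 / 12
#' @export
jaccard <- function(pred_mask, truth_mask) {
  if (!identical(dim(pred_mask), dim(truth_mask))) {
    .stopf("masks must share the same grid")
  }
  u <- sum(pred_mask | truth_mask)
  if (u == 0L) return(1)
  sum(pred_mask & truth_mask) / u
}

#' Per-class Jaccard scores of a segmentation
#'
#' Scores the three tissue classes against ground truth; background (class
#' 0) is not scored.
#'
#' @param class_map integer matrix of predicted class codes.
#' @param truth integer matrix of ground-truth codes on the same grid.
#' @param classes named vector of class codes to score.
#' @return Named numeric vector of Jaccard similarities.
#' @export
evaluate_segmentation <- function(class_map, truth,
                                  classes = c(csf = 1L, gry = 2L, wht = 3L)) {
  vapply(classes, function(cl) jaccard(class_map == cl, truth == cl), numeric(1))
}

#' Run the MSFCM-versus-FCM comparison over a phantom grid
#'
#' Segments every phantom with both the multistage pipeline and the
#' pixel-level FCM baseline, scores each against its ground truth, and
#' aggregates per-condition means. A segmentation failure on an image is
#' recorded as `NA` for that image and method, never silently dropped.
#'
#' @param grid list of phantom pairs from [make_grid] or [make_phantom].
#' @param config an [msfcm_config] for the multistage method.
#' @param baseline an [fcm_params] for the pixel baseline; its background
#'   floor is taken from `config`.
#' @param seed seed forwarded to both methods.
#' @return An object of class `eval_report`: list with `per_image` (one row
#'   per image, method and class) and `summary` (mean Jaccard per method,
#'   class, noise and bias level).
#' @export
evaluate_methods <- function(grid, config = msfcm_config(),
                             baseline = fcm_params(), seed = 1L) {
  if (!length(grid)) .stopf("phantom grid is empty")
  rows <- list()
  for (i in seq_along(grid)) {
    pair <- grid[[i]]
    spec <- pair$spec
    js_ms <- tryCatch(
      evaluate_segmentation(msfcm_segment(pair$image, config, seed)$segmentation$class_map,
                            pair$truth),
      error = function(e) c(csf = NA_real_, gry = NA_real_, wht = NA_real_)
    )
    js_px <- tryCatch(
      evaluate_segmentation(fcm_cluster_pixels(pair$image, baseline,
                                               config$background_floor)$class_map,
                            pair$truth),
      error = function(e) c(csf = NA_real_, gry = NA_real_, wht = NA_real_)
    )
    for (m in c("msfcm", "fcm")) {
      js <- if (m == "msfcm") js_ms else js_px
      rows[[length(rows) + 1L]] <- data.frame(
        image = i, geometry_seed = spec$geometry_seed,
        noise_pct = spec$noise_pct, bias_pct = spec$bias_pct,
        method = m, class = names(js), js = as.numeric(js)
      )
    }
  }
  per_image <- do.call(rbind, rows)
  summary <- stats::aggregate(js ~ method + class + noise_pct + bias_pct,
                              data = per_image, FUN = mean, na.action = stats::na.pass)
  structure(list(per_image = per_image, summary = summary), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d image evaluations\n",
              length(unique(x$per_image$image))))
  print(x$summary)
  invisible(x)
}

#' Reshape an evaluation report into a method-by-level table
#'
#' Rows are method-class combinations, columns the levels of the chosen
#' degradation axis (mean Jaccard, averaged over the other axis) — the
#' layout of a noise-sweep or bias-sweep accuracy table.
#'
#' @param report an `eval_report`.
#' @param axis `"noise"` or `"bias"`.
#' @return A data frame.
#' @export
eval_table <- function(report, axis = c("noise", "bias")) {
  axis <- match.arg(axis)
  key <- paste0(substr(axis, 1, 5), "_pct")
  agg <- stats::aggregate(stats::as.formula(paste("js ~ method + class +", key)),
                          data = report$per_image, FUN = mean,
                          na.action = stats::na.pass)
  wide <- stats::reshape(agg, idvar = c("method", "class"), timevar = key,
                         direction = "wide")
  names(wide) <- sub("^js\\.", paste0(axis, "_"), names(wide))
  rownames(wide) <- NULL
  wide[order(wide$method, wide$class), ]
}

#' Write an evaluation report to CSV
#'
#' @param report an `eval_report`.
#' @param path output `.csv` path.
#' @param axis degradation axis defining the column layout.
#' @export
write_eval_report <- function(report, path, axis = c("noise", "bias")) {
  utils::write.csv(eval_table(report, axis), path, row.names = FALSE)
  invisible(path)
}

#' Degradation slope of accuracy along a noise or bias axis
#'
#' Fits, per method, the least-squares slope of mean Jaccard similarity
#' against the level of the chosen axis for one tissue class (averaging
#' over the other axis). A method that degrades more slowly has a smaller
#' slope magnitude.
#'
#' @param report an `eval_report`.
#' @param class `"csf"`, `"gry"` or `"wht"`.
#' @param axis `"noise"` or `"bias"`.
#' @return Data frame with columns `method` and `slope` (Jaccard units per
#'   percent level).
#' @export
degradation_curve <- function(report, class = c("wht", "gry", "csf"),
                              axis = c("noise", "bias")) {
  class <- match.arg(class)
  axis <- match.arg(axis)
  key <- paste0(substr(axis, 1, 5), "_pct")
  d <- report$per_image[report$per_image$class == class, ]
  agg <- stats::aggregate(stats::as.formula(paste("js ~ method +", key)),
                          data = d, FUN = mean, na.action = stats::na.pass)
  out <- lapply(split(agg, agg$method), function(g) {
    if (length(unique(g[[key]])) < 2L) {
      .stopf("need at least two %s levels for a degradation slope", axis)
    }
    data.frame(method = g$method[1],
               slope = unname(stats::coef(stats::lm(g$js ~ g[[key]]))[2]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
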