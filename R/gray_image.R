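#' Grayscale image container
#'
#' A `gray_image` holds a 2-D intensity field on a fixed \[0, 255\] scale.
#' All pipeline stages (superpixel evolution, deep segmentation, clustering,
#' labeling) consume this representation, so intensity thresholds such as the
#' Butterworth tolerance `eta` always live on one common 8-bit-like scale.
#' Pixel `[i, j]` is row `i` (top to bottom), column `j` (left to right);
#' there is no physical spacing.
#'
#' @param pixels numeric matrix of intensities.
#' @param normalize if `TRUE`, or if values fall outside \[0, 255\], the
#'   intensities are rescaled linearly (min-max) onto \[0, 255\]. A constant
#'   matrix maps to all zeros.
#' @return An object of class `gray_image` with elements `pixels`, `M`
#'   (rows) and `N` (columns).
#' @examples
#' img <- gray_image(matrix(runif(64, 0, 255), 8, 8))
#' dim(img$pixels)
#' @export
gray_image <- function(pixels, normalize = FALSE) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) .stopf("pixel values must be numeric")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) .stopf("image must be at least 1 x 1")
  if (!all(is.finite(pixels))) .stopf("all intensities must be finite")
  rng <- range(pixels)
  if (normalize || rng[1] < 0 || rng[2] > 255) {
    if (rng[2] > rng[1]) {
      pixels <- (pixels - rng[1]) / (rng[2] - rng[1]) * 255
    } else {
      pixels <- pixels * 0
    }
  }
  structure(list(pixels = pixels, M = nrow(pixels), N = ncol(pixels)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, intensity range [%.1f, %.1f]\n",
              x$M, x$N, min(x$pixels), max(x$pixels)))
  invisible(x)
}

.as_gray_image <- function(x) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x)
}

#' Read a grayscale image
#'
#' Reads PNG, TIFF or NIfTI-1 input into a [gray_image]. Raster formats are
#' scaled by bit depth so an 8-bit file keeps its stored values (a pixel
#' stored as 7 reads as 7) and a 16-bit file is rescaled linearly so 65535
#' maps to 255. NIfTI volumes have no defined intensity scale and are
#' min-max normalized to \[0, 255\]; they are treated slice-wise, with
#' `slice_index` selecting an axial (third-dimension) slice.
#'
#' @param path path to a `.png`, `.tif`/`.tiff`, `.nii` or `.nii.gz` file.
#' @param slice_index 1-based axial slice for 3-D NIfTI input; required when
#'   the volume has more than one slice.
#' @return A [gray_image].
#' @export
read_gray_image <- function(path, slice_index = NULL) {
  if (!file.exists(path) || dir.exists(path)) .stopf("cannot read '%s': no such file", path)
  ext <- tolower(sub(".*?(\\.[a-z0-9.]+)$", "\\1", basename(path)))
  if (ext %in% c(".png", ".tif", ".tiff")) {
    m <- if (ext == ".png") png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]  # first channel of RGB(A) input
    return(gray_image(m * 255))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 3L) {
      if (is.null(slice_index)) {
        if (dim(arr)[3] != 1L) .stopf("3-D NIfTI input requires slice_index")
        slice_index <- 1L
      }
      if (slice_index < 1L || slice_index > dim(arr)[3]) {
        .stopf("slice_index %d out of range [1, %d]", slice_index, dim(arr)[3])
      }
      arr <- arr[, , slice_index]
    } else if (length(dim(arr)) != 2L) {
      .stopf("unsupported NIfTI dimensionality: %s", paste(dim(arr), collapse = "x"))
    }
    return(gray_image(arr, normalize = TRUE))
  }
  .stopf("unsupported image format: '%s'", ext)
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img a [gray_image].
#' @param path output `.png` path.
#' @export
write_gray_image <- function(img, path) {
  img <- .as_gray_image(img)
  if (dir.exists(path)) .stopf("'%s' is a directory", path)
  png::writePNG(pmin(pmax(img$pixels, 0), 255) / 255, path)
  invisible(path)
}

#' Read and write integer label maps
#'
#' Label maps pair a [gray_image] with a same-shape field of non-negative
#' integer labels; label 0 is reserved for background. 2-D maps are stored
#' as 8-bit grayscale PNG (labels must not exceed 255), volumes as integer
#' NIfTI. Writing then reading a label map reproduces it exactly.
#'
#' @param labels integer matrix of non-negative labels.
#' @param path output path ending in `.png`, `.nii` or `.nii.gz`.
#' @return `read_label_map` returns an integer matrix.
#' @export
write_label_map <- function(labels, path) {
  labels <- as.matrix(labels)
  if (any(labels < 0) || any(labels != round(labels))) {
    .stopf("labels must be non-negative integers")
  }
  if (dir.exists(path)) .stopf("'%s' is a directory", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(labels) > 255) .stopf("PNG label maps support at most 255 labels")
    png::writePNG(labels / 255, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- array(as.integer(labels), dim = c(nrow(labels), ncol(labels), 1L))
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int32"), path)
  } else {
    .stopf("unsupported label map format for '%s'", path)
  }
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  if (!file.exists(path) || dir.exists(path)) .stopf("cannot read '%s': no such file", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    return(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) arr <- arr[, , 1L]
    return(matrix(as.integer(round(arr)), nrow(arr), ncol(arr)))
  }
  .stopf("unsupported label map format for '%s'", path)
}
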