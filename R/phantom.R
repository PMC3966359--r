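#' Specification of a synthetic brain phantom
#'
#' Describes a BrainWeb-style 2-D head phantom: three tissue classes
#' (cerebrospinal fluid, gray matter, white matter) over background, with
#' additive Gaussian noise quoted as a percentage of the brightest tissue
#' mean and a smooth multiplicative bias field quoted as a percentage
#' amplitude. The study grid uses noise levels 0/3/5/7/9% and bias levels
#' 0/20/40%, but any non-negative level is accepted.
#'
#' @param size `c(M, N)` image size in pixels (at least 48 x 48).
#' @param tissue_means intensities of CSF, gray matter and white matter on
#'   the \[0, 255\] scale; must be strictly increasing (white matter is the
#'   brightest tissue on T1-like contrast).
#' @param noise_pct additive Gaussian noise standard deviation as a percent
#'   of the brightest tissue mean.
#' @param bias_pct amplitude of the multiplicative bias field in percent:
#'   the field is `1 + bias_pct/100 * g(x, y)` with `g` a smooth low-order
#'   surface spanning \[-0.5, 0.5\].
#' @param geometry_seed seed controlling anatomy (boundary harmonics,
#'   ventricles, deep gray nuclei, bias-field orientation).
#' @param noise_seed seed controlling the noise realisation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(128L, 128L),
                         tissue_means = c(csf = 64, gray = 128, white = 192),
                         noise_pct = 0, bias_pct = 0,
                         geometry_seed = 1L, noise_seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 48L)) {
    .stopf("phantom size must be at least 48 x 48 to fit all three tissues")
  }
  tissue_means <- as.numeric(tissue_means)
  if (length(tissue_means) != 3L || any(diff(tissue_means) <= 0)) {
    .stopf("tissue_means must be three strictly increasing intensities (CSF < gray < white)")
  }
  if (noise_pct < 0 || bias_pct < 0) .stopf("noise_pct and bias_pct must be >= 0")
  structure(list(size = size, tissue_means = stats::setNames(tissue_means, c("csf", "gray", "white")),
                 noise_pct = noise_pct, bias_pct = bias_pct,
                 geometry_seed = as.integer(geometry_seed),
                 noise_seed = as.integer(noise_seed)),
            class = "phantom_spec")
}

# Sum of cosine harmonics used for boundary perturbation.
.harmonics <- function(theta, amps, freqs, phases) {
  out <- 0
  for (k in seq_along(amps)) out <- out + amps[k] * cos(freqs[k] * theta + phases[k])
  out
}

#' Generate a synthetic brain phantom with ground truth
#'
#' Builds a nested-blob head phantom: background (label 0), an outer CSF rim
#' (1), a gray-matter ribbon with cortical-fold perturbations (2) and inner
#' white matter (3) containing CSF ventricles and deep gray nuclei. The
#' clean image is piecewise constant at the tissue means; a multiplicative
#' bias field and additive Gaussian noise are applied afterwards and the
#' result is clipped to \[0, 255\]. Identical seeds give bit-identical
#' output.
#'
#' Differences from the real BrainWeb simulator: noise is Gaussian
#' everywhere (BrainWeb uses Rayleigh background noise) and tissue interiors
#' are perfectly homogeneous (no partial-volume mixing).
#'
#' @param spec a [phantom_spec].
#' @return An object of class `phantom_pair`: list with `image`
#'   ([gray_image]), `truth` (integer matrix, 0 = background, 1 = CSF,
#'   2 = gray matter, 3 = white matter) and `spec`.
#' @examples
#' p <- make_phantom(phantom_spec(size = c(64, 64)))
#' table(p$truth)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  M <- spec$size[1]; N <- spec$size[2]
  R <- 0.44 * min(M, N)

  geo <- .with_seed(spec$geometry_seed, {
    list(
      centre = c((M + 1) / 2 + stats::runif(1, -0.02, 0.02) * M,
                 (N + 1) / 2 + stats::runif(1, -0.02, 0.02) * N),
      outer_amp = stats::runif(2, 0.02, 0.05), outer_ph = stats::runif(2, 0, 2 * pi),
      gm_amp = stats::runif(1, 0.02, 0.04), gm_ph = stats::runif(1, 0, 2 * pi),
      fold_amp = stats::runif(2, 0.04, 0.08), fold_freq = sample(5:9, 2),
      fold_ph = stats::runif(2, 0, 2 * pi),
      vent_dy = stats::runif(1, 0.10, 0.14), vent_a = stats::runif(1, 0.16, 0.20),
      vent_b = stats::runif(1, 0.07, 0.09), vent_tilt = stats::runif(1, -0.25, 0.25),
      nuc_dx = stats::runif(1, 0.16, 0.22), nuc_r = stats::runif(1, 0.07, 0.10),
      bias_coef = { v <- stats::rnorm(4); v / sqrt(sum(v^2)) }
    )
  })

  row <- matrix(seq_len(M), M, N)
  col <- matrix(seq_len(N), M, N, byrow = TRUE)
  dx <- row - geo$centre[1]
  dy <- col - geo$centre[2]
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)

  r_out <- R * (1 + .harmonics(theta, geo$outer_amp, c(1, 2), geo$outer_ph))
  r_gm <- 0.86 * r_out * (1 + geo$gm_amp * cos(2 * theta + geo$gm_ph))
  r_wm <- 0.62 * r_out * (1 + .harmonics(theta, geo$fold_amp, geo$fold_freq, geo$fold_ph))

  truth <- matrix(0L, M, N)
  truth[rho <= r_out] <- 1L
  truth[rho <= r_gm] <- 2L
  truth[rho <= r_wm] <- 3L

  # Lateral ventricles: two tilted CSF ellipses inside white matter.
  for (s in c(-1, 1)) {
    ex <- dx / R
    ey <- dy / R - s * geo$vent_dy
    u <- cos(geo$vent_tilt) * ex - s * sin(geo$vent_tilt) * ey
    v <- s * sin(geo$vent_tilt) * ex + cos(geo$vent_tilt) * ey
    vent <- (u / geo$vent_a)^2 + (v / geo$vent_b)^2 <= 1
    truth[vent & truth == 3L] <- 1L
  }
  # Deep gray nuclei: round gray-matter blobs below the ventricles.
  for (s in c(-1, 1)) {
    nuc <- ((dx / R - geo$nuc_dx)^2 + (dy / R - s * 0.5 * geo$vent_dy)^2) <= geo$nuc_r^2
    truth[nuc & truth == 3L] <- 2L
  }
  if (length(setdiff(0:3, unique(as.integer(truth)))) > 0L) {
    .stopf("phantom size too small: not all tissue classes present")
  }

  img <- matrix(c(0, spec$tissue_means)[truth + 1L], M, N)

  if (spec$bias_pct > 0) {
    u <- 2 * (row - 1) / (M - 1) - 1
    v <- 2 * (col - 1) / (N - 1) - 1
    b <- geo$bias_coef
    raw <- b[1] * u + b[2] * v + b[3] * u * v + b[4] * (u^2 - v^2)
    # Normalize the surface over the head support so tissue actually spans
    # the advertised [-0.5, 0.5] amplitude; background extremes are clipped.
    rs <- range(raw[truth > 0L])
    g <- pmin(pmax((raw - rs[1]) / (rs[2] - rs[1]) - 0.5, -0.5), 0.5)
    img <- img * (1 + spec$bias_pct / 100 * g)
  }
  if (spec$noise_pct > 0) {
    sigma <- spec$noise_pct / 100 * max(spec$tissue_means)
    img <- img + .with_seed(spec$noise_seed, matrix(stats::rnorm(M * N, sd = sigma), M, N))
  }
  img <- pmin(pmax(img, 0), 255)

  structure(list(image = gray_image(img), truth = truth, spec = spec),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("<phantom_pair> %d x %d, noise %.0f%%, bias %.0f%%, seeds (geometry %d, noise %d)\n",
              x$spec$size[1], x$spec$size[2], x$spec$noise_pct, x$spec$bias_pct,
              x$spec$geometry_seed, x$spec$noise_seed))
  invisible(x)
}

#' Generate a grid of phantoms over noise and bias conditions
#'
#' Produces `n_images` anatomies (geometry seeds `base$geometry_seed + 0, 1,
#' ...`), each rendered under every combination of the given noise and bias
#' levels. Geometry is shared across conditions so that comparisons along
#' the noise or bias axis isolate the degradation effect; noise realisations
#' are distinct per condition.
#'
#' @param base a [phantom_spec] providing size, tissue means and base seeds.
#' @param noise_levels,bias_levels non-empty numeric vectors of levels (%).
#' @param n_images number of anatomies per condition.
#' @return A list of [make_phantom] pairs of length
#'   `length(noise_levels) * length(bias_levels) * n_images`.
#' @export
make_grid <- function(base, noise_levels = c(0, 3, 5, 7, 9),
                      bias_levels = c(0, 20, 40), n_images = 1L) {
  stopifnot(inherits(base, "phantom_spec"))
  if (length(noise_levels) < 1L || length(bias_levels) < 1L) {
    .stopf("noise_levels and bias_levels must be non-empty")
  }
  if (n_images < 1L) .stopf("n_images must be >= 1")
  out <- list()
  cond <- 0L
  for (noise in noise_levels) {
    for (bias in bias_levels) {
      cond <- cond + 1L
      for (g in seq_len(n_images)) {
        sp <- phantom_spec(size = base$size, tissue_means = base$tissue_means,
                           noise_pct = noise, bias_pct = bias,
                           geometry_seed = base$geometry_seed + g - 1L,
                           noise_seed = base$noise_seed + 1000L * cond + g)
        out[[length(out) + 1L]] <- make_phantom(sp)
      }
    }
  }
  out
}
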