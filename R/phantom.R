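#' Generate a T2-like brain phantom with ground-truth labels
#'
#' Nested-ellipse planes emulating the histogram structure of an axial
#' T2-weighted brain slice: an outer gray-matter ring, an inner white-matter
#' mass, and bright cerebrospinal fluid as a central ventricular body plus
#' two peripheral pockets, on a near-zero background. Each voxel is its
#' class mode plus additive Gaussian noise, rounded and clipped to
#' `[0, 255]`. Fully determined by `seed`.
#'
#' Default modes (GM 65, WM 110, CSF 180) sit near the centers of the
#' anatomical T2 ranges of [region_ranges()] so that the published 45-85 /
#' 86-140 / 141-255 bounds are exercised without being straddled.
#'
#' @param shape Integer vector `c(planes, rows, cols)`.
#' @param modes Named class means: `background`, `GM`, `WM`, `CSF`.
#' @param noise_sigma Gaussian noise standard deviation in gray levels.
#' @param seed Integer RNG seed.
#' @param ranges [region_ranges()] the tissue modes must respect.
#' @return A list with elements `volume` (a [gray_volume()]), `labels`
#'   (ground-truth `label_map`: 0 background, then regions in range order),
#'   and `spec` (the generating parameters).
#' @examples
#' ph <- generate_phantom(shape = c(1, 64, 64), noise_sigma = 0, seed = 7)
#' region_volumes(ph$labels)
#' @export
generate_phantom <- function(shape = c(1, 256, 256),
                             modes = c(background = 5, GM = 65, WM = 110, CSF = 180),
                             noise_sigma = 5, seed = 1,
                             ranges = region_ranges()) {
  stopifnot(length(shape) == 3L, all(shape >= 1L), shape[2] >= 8L, shape[3] >= 8L,
            noise_sigma >= 0)
  ranges <- validate_ranges(ranges)
  for (i in seq_len(nrow(ranges))) {
    m <- if (ranges$region[i] %in% names(modes)) modes[[ranges$region[i]]] else NULL
    if (is.null(m) || m < ranges$low[i] || m > ranges$high[i]) {
      stop(sprintf("mode for %s must lie in [%d, %d]",
                   ranges$region[i], ranges$low[i], ranges$high[i]), call. = FALSE)
    }
  }
  if (modes[["background"]] >= ranges$low[1]) {
    stop("background mode must lie below the first region range", call. = FALSE)
  }

  n <- shape[2]; m <- shape[3]
  yy <- matrix(rep((seq_len(n) - (n + 1) / 2) / (n / 2), m), n, m)
  xx <- matrix(rep((seq_len(m) - (m + 1) / 2) / (m / 2), each = n), n, m)
  inside <- function(cy, cx, ry, rx) ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1

  lab2d <- matrix(0L, n, m)
  lab2d[inside(0, 0, 0.92, 0.88)] <- 1L                       # GM ring (outer)
  lab2d[inside(0, 0, 0.92 * 0.78, 0.88 * 0.78)] <- 2L         # WM mass
  csf <- inside(0, 0, 0.36, 0.50) |                           # ventricular body
    inside(-0.45, 0, 0.15, 0.15) | inside(0.45, 0, 0.15, 0.15) # peripheral pockets
  lab2d[csf] <- 3L

  mode_lut <- c(modes[["background"]],
                vapply(ranges$region, function(r) modes[[r]], numeric(1)))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  vol <- array(0L, dim = shape)
  labels <- array(0L, dim = shape)
  for (z in seq_len(shape[1])) {
    clean <- mode_lut[lab2d + 1L]
    noisy <- if (noise_sigma > 0) {
      clean + stats::rnorm(length(clean), 0, noise_sigma)
    } else clean
    vol[z, , ] <- pmin(pmax(round(noisy), 0), 255)
    labels[z, , ] <- lab2d
  }
  list(
    volume = gray_volume(vol, source = sprintf("phantom(seed=%d)", seed)),
    labels = structure(labels, class = c("label_map", "array"),
                       regions = ranges$region),
    spec = list(shape = shape, modes = as.list(modes),
                noise_sigma = noise_sigma, seed = seed)
  )
}

# Piecewise visible-spectrum approximation: wavelength (nm) -> base RGB in
# [0,1], with intensity fall-off at the spectrum edges and display gamma.
wavelength_to_rgb <- function(w, gamma = 0.8) {
  r <- g <- b <- numeric(length(w))
  i <- w >= 380 & w < 440; r[i] <- -(w[i] - 440) / 60; b[i] <- 1
  i <- w >= 440 & w < 490; g[i] <- (w[i] - 440) / 50; b[i] <- 1
  i <- w >= 490 & w < 510; g[i] <- 1; b[i] <- -(w[i] - 510) / 20
  i <- w >= 510 & w < 580; r[i] <- (w[i] - 510) / 70; g[i] <- 1
  i <- w >= 580 & w < 645; r[i] <- 1; g[i] <- -(w[i] - 645) / 65
  i <- w >= 645 & w <= 780; r[i] <- 1
  att <- rep(1, length(w))
  i <- w >= 380 & w < 420; att[i] <- 0.3 + 0.7 * (w[i] - 380) / 40
  i <- w > 700 & w <= 780; att[i] <- 0.3 + 0.7 * (780 - w[i]) / 80
  cbind(R = (att * r)^gamma, G = (att * g)^gamma, B = (att * b)^gamma)
}

#' Generate the built-in 400-700 nm spectrum palette image
#'
#' A horizontal wavelength ramp from 400 nm (violet) to 700 nm (red),
#' luminance-graded so the columns' YIQ lumas ascend across the full 8-bit
#' range: column `i` targets luma `255 i / (n + 1)`, takes its hue angle in
#' CIELAB from the standard piecewise visible-spectrum approximation, and
#' carries the largest chroma whose reconstructed color stays within half a
#' gray level of the luma target. That chroma cap is what lets the
#' colorization preserve the original luminance to within a gray level or
#' two; fully saturated spectral colors would not.
#'
#' @param n_colors Number of distinct columns (2-256); default 200.
#' @param height Image height in rows.
#' @return A [color_image()] of `height x n_colors` with exactly `n_colors`
#'   unique columns, lumas strictly increasing left to right.
#' @export
generate_spectrum <- function(n_colors = 200L, height = 32L) {
  n_colors <- as.integer(n_colors)
  if (n_colors < 2L || n_colors > 256L) {
    stop("`n_colors` must lie in [2, 256]", call. = FALSE)
  }
  wl <- seq(400, 700, length.out = n_colors)
  base <- wavelength_to_rgb(wl)
  base_lab <- rgb_to_lab(pmin(base, 1) * 255)
  theta <- atan2(base_lab[, 3], base_lab[, 2])
  target <- 255 * seq_len(n_colors) / (n_colors + 1)
  l_star <- rgb_to_lab(cbind(target, target, target))[, 1]

  rgb <- matrix(0L, n_colors, 3L)
  remaining <- seq_len(n_colors)
  for (chroma in seq(60, 0, by = -0.5)) {
    if (length(remaining) == 0L) break
    cand <- lab_to_rgb(cbind(l_star[remaining],
                             chroma * cos(theta[remaining]),
                             chroma * sin(theta[remaining])))
    ok <- abs(luma(cand) - target[remaining]) <= 0.5
    rgb[remaining[ok], ] <- cand[ok, , drop = FALSE]
    remaining <- remaining[!ok]
  }
  img <- array(0L, dim = c(height, n_colors, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(rep(rgb[, ch], each = height), height)
  color_image(img)
}
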