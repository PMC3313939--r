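#' YIQ luma of RGB pixels
#'
#' The NTSC YIQ luminance component, `0.299 R + 0.587 G + 0.114 B`, returned
#' as a real number on the 0-255 scale (not rounded). This is the luminance
#' used on both sides of the palette match during colorization: for a gray
#' pixel `(g, g, g)` the luma is exactly `g`.
#'
#' @param rgb A length-3 vector or an `n x 3` matrix of channels in `[0, 255]`.
#' @return A numeric vector of luma values.
#' @examples
#' luma(c(255, 0, 0))  # 76.245
#' @export
luma <- function(rgb) {
  rgb <- as_rgb_matrix(rgb)
  drop(rgb %*% c(0.299, 0.587, 0.114))
}

as_rgb_matrix <- function(rgb) {
  if (is.null(dim(rgb))) {
    if (length(rgb) != 3L) stop("an RGB triple has 3 channels", call. = FALSE)
    rgb <- matrix(rgb, 1L, 3L)
  }
  if (ncol(rgb) != 3L) stop("RGB matrix must have 3 columns", call. = FALSE)
  if (any(!is.finite(rgb)) || any(rgb < 0 | rgb > 255)) {
    stop("RGB channels must lie in [0, 255]", call. = FALSE)
  }
  rgb
}

# IEC 61966-2-1 sRGB primaries under D65. The reference white is taken as
# the image of (1,1,1) through the same matrix, which makes the gray axis
# map to a* = b* = 0 exactly.
srgb_to_xyz_matrix <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
xyz_to_srgb_matrix <- solve(srgb_to_xyz_matrix)
d65_white <- rowSums(srgb_to_xyz_matrix)

srgb_linearize <- function(s) ifelse(s <= 0.04045, s / 12.92,
                                     ((s + 0.055) / 1.055)^2.4)
srgb_delinearize <- function(l) ifelse(l <= 0.0031308, 12.92 * l,
                                       1.055 * l^(1 / 2.4) - 0.055)
lab_f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                            t / (3 * (6 / 29)^2) + 4 / 29)
lab_finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))

#' Convert RGB to CIELAB
#'
#' The standard pipeline: sRGB inverse-gamma linearization, linear RGB to
#' tri-stimulus XYZ under the D65 white point, then XYZ to CIELAB.
#' Achromatic inputs `(g, g, g)` map to the `a* = b* = 0` axis exactly.
#'
#' @param rgb A length-3 vector or `n x 3` matrix, channels in `[0, 255]`.
#' @return An `n x 3` matrix with columns `L`, `a`, `b` (`L` in `[0, 100]`).
#' @export
rgb_to_lab <- function(rgb) {
  rgb <- as_rgb_matrix(rgb)
  lin <- srgb_linearize(rgb / 255)
  xyz <- lin %*% t(srgb_to_xyz_matrix)
  fxyz <- lab_f(sweep(xyz, 2, d65_white, "/"))
  cbind(L = 116 * fxyz[, 2] - 16,
        a = 500 * (fxyz[, 1] - fxyz[, 2]),
        b = 200 * (fxyz[, 2] - fxyz[, 3]))
}

#' Convert CIELAB to RGB
#'
#' Inverse of [rgb_to_lab()]. Out-of-gamut results are clipped to
#' `[0, 255]` per channel, then rounded, so the function always returns a
#' displayable color.
#'
#' @param lab A length-3 vector `(L, a, b)` or `n x 3` matrix.
#' @return An `n x 3` integer matrix with columns `R`, `G`, `B`.
#' @export
lab_to_rgb <- function(lab) {
  if (is.null(dim(lab))) lab <- matrix(lab, 1L, 3L)
  if (ncol(lab) != 3L) stop("Lab matrix must have 3 columns", call. = FALSE)
  if (any(!is.finite(lab))) stop("Lab components must be finite", call. = FALSE)
  fy <- (lab[, 1] + 16) / 116
  fxyz <- cbind(fy + lab[, 2] / 500, fy, fy - lab[, 3] / 200)
  xyz <- sweep(lab_finv(fxyz), 2, d65_white, "*")
  lin <- pmin(pmax(xyz %*% t(xyz_to_srgb_matrix), 0), 1)  # gamut clip
  out <- round(srgb_delinearize(lin) * 255)
  storage.mode(out) <- "integer"
  colnames(out) <- c("R", "G", "B")
  out
}
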