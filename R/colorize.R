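#' Colorization configuration
#'
#' @param criterion_c1 Maximum luma distance (0-255 scale) for a palette
#'   match to count as successful; default 3.4, chosen so a ~200-color
#'   luma-spanning palette partitions the luma axis into at least the ~38
#'   perceivable bands needed to tell brain soft tissues apart.
#' @param fallback What to do when no palette entry lies within
#'   `criterion_c1`: `"nearest"` (default) uses the nearest entry anyway;
#'   `"error"` aborts.
#' @param palette_size Default target palette size for [build_palette()].
#' @return A list of class `colorization_config`.
#' @export
colorization_config <- function(criterion_c1 = 3.4,
                                fallback = c("nearest", "error"),
                                palette_size = 200L) {
  if (!is.numeric(criterion_c1) || criterion_c1 <= 0) {
    stop("`criterion_c1` must be positive", call. = FALSE)
  }
  structure(list(criterion_c1 = criterion_c1,
                 fallback = match.arg(fallback),
                 palette_size = as.integer(palette_size)),
            class = "colorization_config")
}

#' Build a chromaticity palette from a color-spectrum image
#'
#' Collects the unique RGB colors of the spectrum image; when more than
#' `target_size` are present, keeps a luma-stratified subsample of exactly
#' `target_size` entries (evenly spaced through the luma-sorted sequence).
#' Each entry carries its YIQ luma, its CIELAB coordinates, and the source
#' RGB, sorted ascending by luma.
#'
#' @param spectrum A [color_image()] (e.g. from [generate_spectrum()]) or an
#'   `n x 3` RGB matrix.
#' @param target_size Maximum palette size; default 200.
#' @return A tibble of class `chroma_palette` with columns `luma`, `L`,
#'   `a`, `b`, `R`, `G`, `B`.
#' @examples
#' pal <- build_palette(generate_spectrum(50))
#' nrow(pal)
#' @export
build_palette <- function(spectrum, target_size = 200L) {
  px <- if (inherits(spectrum, "color_image")) pixel_matrix(spectrum)
        else as_rgb_matrix(spectrum)
  px <- unique(px)
  if (nrow(px) < 2L) {
    stop("spectrum has fewer than 2 unique colors", call. = FALSE)
  }
  lum <- luma(px)
  ord <- order(lum, px[, 1], px[, 2], px[, 3])
  px <- px[ord, , drop = FALSE]
  lum <- lum[ord]
  if (nrow(px) > target_size) {
    pick <- round(seq(1L, nrow(px), length.out = target_size))
    px <- px[pick, , drop = FALSE]
    lum <- lum[pick]
  }
  lab <- rgb_to_lab(px)
  out <- tibble::tibble(luma = lum, L = lab[, 1], a = lab[, 2], b = lab[, 3],
                        R = px[, 1], G = px[, 2], B = px[, 3])
  class(out) <- c("chroma_palette", class(out))
  out
}

#' Match a luminance value to its nearest palette entry
#'
#' Finds the entry minimizing the Euclidean distance `D = |l - luma|`. The
#' match is "successful" when `D <= criterion_c1`; otherwise the configured
#' fallback applies. Ties break to the lower-luma entry.
#'
#' @param l A luma value in `[0, 255]`.
#' @param palette A [build_palette()] tibble.
#' @param cfg A [colorization_config()].
#' @return The matched palette row (one-row tibble) with an extra column
#'   `distance`.
#' @export
match_luminance <- function(l, palette, cfg = colorization_config()) {
  if (nrow(palette) == 0L) stop("empty palette", call. = FALSE)
  d <- abs(l - palette$luma)
  i <- which.min(d)  # first minimum = lower luma on ties (sorted palette)
  if (d[i] > cfg$criterion_c1 && cfg$fallback == "error") {
    stop(sprintf("no palette entry within C1 = %.3g of luma %.3g",
                 cfg$criterion_c1, l), call. = FALSE)
  }
  dplyr::mutate(palette[i, ], distance = d[i])
}

# One 256-entry RGB lookup table: for each gray level g, keep the gray
# pixel's own CIELAB lightness and adopt the matched entry's (a*, b*).
colorize_lut <- function(palette, cfg) {
  g <- 0:255
  gray_lab <- rgb_to_lab(cbind(g, g, g))
  idx <- vapply(g, function(gi) {
    d <- abs(gi - palette$luma)
    i <- which.min(d)
    if (d[i] > cfg$criterion_c1 && cfg$fallback == "error") {
      stop(sprintf("no palette entry within C1 = %.3g of luma %d",
                   cfg$criterion_c1, gi), call. = FALSE)
    }
    i
  }, integer(1))
  lab_to_rgb(cbind(gray_lab[, 1], palette$a[idx], palette$b[idx]))
}

#' Colorize one gray plane by luminance matching
#'
#' Each pixel of gray value `g` keeps its own luminance (the CIELAB
#' lightness of `(g, g, g)`) and receives the chromaticity `(a*, b*)` of the
#' palette entry whose YIQ luma is nearest `g`. The output color is a pure
#' function of `g` given the palette, so the implementation uses a 256-entry
#' lookup table that equals the per-pixel definition exactly.
#'
#' @param plane An integer matrix in `[0, 255]`, or a [gray_volume()]
#'   (first plane used).
#' @param palette A [build_palette()] tibble.
#' @param cfg A [colorization_config()].
#' @return A [color_image()] with the same luminance structure as the input.
#' @export
colorize_plane <- function(plane, palette, cfg = colorization_config()) {
  if (inherits(plane, "gray_volume")) plane <- get_plane(plane, 1L)
  storage.mode(plane) <- "integer"
  if (any(plane < 0L | plane > 255L)) stop("gray values must lie in [0, 255]", call. = FALSE)
  lut <- colorize_lut(palette, cfg)
  color_image(array(lut[as.vector(plane) + 1L, ], dim = c(dim(plane), 3L)))
}

#' Colorize every plane of a gray volume
#'
#' @param v A [gray_volume()].
#' @inheritParams colorize_plane
#' @return A list of [color_image()], one per plane; deterministic.
#' @export
colorize_volume <- function(v, palette, cfg = colorization_config()) {
  stopifnot(inherits(v, "gray_volume"))
  lut <- colorize_lut(palette, cfg)
  lapply(seq_len(n_planes(v)), function(z) {
    plane <- get_plane(v, z)
    color_image(array(lut[as.vector(plane) + 1L, ], dim = c(dim(plane), 3L)))
  })
}
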