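#' Construct a gray volume
#'
#' The package's internal container for grayscale image data: an integer
#' array of 8-bit intensities indexed `[plane, row, col]`. A 2D image is a
#' volume with a single plane. All readers normalize to this type, so every
#' downstream stage (histogram analysis, centroid selection, clustering,
#' colorization) works on one representation.
#'
#' @param x A matrix (single plane) or 3D array `[plane, row, col]` of
#'   intensities in `[0, 255]`.
#' @param source Optional provenance string (file path).
#' @param bit_depth Original bit depth of the source data (8 or 16).
#' @return An integer array of class `gray_volume` with dimensions
#'   `c(planes, rows, cols)`.
#' @examples
#' v <- gray_volume(matrix(0:255, 16, 16))
#' dim(v)
#' @export
gray_volume <- function(x, source = NULL, bit_depth = 8L) {
  if (is.matrix(x)) {
    x <- array(x, dim = c(1L, nrow(x), ncol(x)))
  }
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("`x` must be a matrix or a 3D array [plane, row, col]", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("intensities must be finite", call. = FALSE)
  if (any(x < 0 | x > 255)) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  if (any(x != round(x))) {
    stop("intensities must be integers; normalize the source first", call. = FALSE)
  }
  if (dim(x)[2] < 2L || dim(x)[3] < 2L) {
    stop("plane dimensions must be at least 2 x 2", call. = FALSE)
  }
  out <- array(as.integer(x), dim = dim(x))
  class(out) <- c("gray_volume", "array")
  attr(out, "source") <- source
  attr(out, "bit_depth") <- as.integer(bit_depth)
  out
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<gray_volume> %d plane(s) of %d x %d, intensities %d..%d\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

#' Number of planes in a gray volume
#' @param v A `gray_volume`.
#' @return Integer plane count.
#' @export
n_planes <- function(v) dim(v)[1]

#' Extract one plane of a gray volume as a matrix
#' @param v A `gray_volume`.
#' @param z Plane index (1-based).
#' @return An integer matrix `[row, col]`.
#' @export
get_plane <- function(v, z = 1L) {
  if (z < 1L || z > dim(v)[1]) stop("plane index out of range", call. = FALSE)
  matrix(v[z, , ], dim(v)[2], dim(v)[3])
}

#' Construct a color image
#'
#' An RGB raster with integer channels in `[0, 255]`, stored as an array
#' `[row, col, channel]`.
#'
#' @param x A 3D array `[row, col, 3]` with values in `[0, 255]`.
#' @return An integer array of class `color_image`.
#' @export
color_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop("`x` must be an array [row, col, 3]", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0 | x > 255) || any(x != round(x))) {
    stop("channels must be integers in [0, 255]", call. = FALSE)
  }
  out <- array(as.integer(x), dim = dim(x))
  class(out) <- c("color_image", "array")
  out
}

#' @export
print.color_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<color_image> %d x %d RGB\n", d[1], d[2]))
  invisible(x)
}

# Internal: flatten a color image to an n x 3 integer matrix of pixels.
pixel_matrix <- function(img) {
  d <- dim(img)
  matrix(as.integer(img), d[1] * d[2], 3L)
}
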