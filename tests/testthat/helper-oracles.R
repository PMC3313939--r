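# Independent oracle implementations, deliberately written as naive loops
# so they share no code path with the package functions they check.

# Brute-force nearest-centroid labeling of one plane (ties -> lowest index).
oracle_assign_plane <- function(plane, centroids, background_low = NULL) {
  out <- matrix(0L, nrow(plane), ncol(plane))
  for (i in seq_len(nrow(plane))) {
    for (j in seq_len(ncol(plane))) {
      g <- plane[i, j]
      if (!is.null(background_low) && g < background_low) next
      best <- 1L
      for (r in seq_along(centroids)) {
        if (abs(g - centroids[r]) < abs(g - centroids[best])) best <- r
      }
      out[i, j] <- best
    }
  }
  out
}

# Peak scan by explicit plateau-run enumeration over a 256-bin count vector.
oracle_find_peaks <- function(counts) {
  gray <- integer(0); cnt <- integer(0)
  i <- 1L
  while (i <= 256L) {
    j <- i
    while (j < 256L && counts[j + 1L] == counts[i]) j <- j + 1L
    left_smaller <- i > 1L && counts[i - 1L] < counts[i]
    right_smaller <- j < 256L && counts[j + 1L] < counts[i]
    if (left_smaller && right_smaller) {
      mid <- i + (j - i) %/% 2L      # lower median of the run
      gray <- c(gray, mid - 1L)      # bin index -> gray level
      cnt <- c(cnt, counts[i])
    }
    i <- j + 1L
  }
  tibble::tibble(gray = gray, count = cnt)
}

# Hand-rolled sRGB (D65) -> CIELAB, independent of grDevices::convertColor.
oracle_rgb_to_lab <- function(rgb) {
  s <- rgb / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  wp <- as.vector(M %*% c(1, 1, 1))  # D65 white from the same primaries
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[1] / wp[1]); fy <- f(xyz[2] / wp[2]); fz <- f(xyz[3] / wp[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Linear-scan nearest palette entry by |l - luma|, first (lowest-luma) wins.
oracle_match_index <- function(l, lumas) {
  best <- 1L
  for (i in seq_along(lumas)) if (abs(l - lumas[i]) < abs(l - lumas[best])) best <- i
  best
}

# Scalar per-pixel colorization straight from the definition: keep the gray
# pixel's own L*, adopt the matched entry's (a*, b*).
oracle_colorize_plane <- function(plane, palette, cfg = colorization_config()) {
  out <- array(0L, dim = c(dim(plane), 3L))
  for (i in seq_len(nrow(plane))) {
    for (j in seq_len(ncol(plane))) {
      g <- plane[i, j]
      entry <- match_luminance(g, palette, cfg)
      L <- rgb_to_lab(c(g, g, g))[1, 1]
      out[i, j, ] <- lab_to_rgb(c(L, entry$a, entry$b))
    }
  }
  out
}

# Small helper: peak tibble literal.
peaks_tbl <- function(gray, count) tibble::tibble(gray = gray, count = count)

# Histogram tibble from an explicit 256-count vector.
hist_tbl <- function(counts) tibble::tibble(gray = 0:255, count = as.integer(counts))

# Counts vector with given (gray, count) pairs, zero elsewhere.
counts_at <- function(gray, count) {
  h <- integer(256)
  h[gray + 1L] <- count
  h
}
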