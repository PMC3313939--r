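#' Anatomical intensity ranges for T2 brain tissue
#'
#' The gray-level windows inside which each tissue's histogram peak is
#' sought. Defaults are the T2-weighted brain windows: gray matter 45-85,
#' white matter 86-140, cerebrospinal fluid 141-255. Ranges must be
#' non-overlapping and ascending; the lower bound of the first range doubles
#' as the default background cutoff for [assign_hard()].
#'
#' @param gm,wm,csf Length-2 integer vectors `c(low, high)`.
#' @return A tibble with columns `region`, `low`, `high`.
#' @examples
#' region_ranges()
#' @export
region_ranges <- function(gm = c(45, 85), wm = c(86, 140), csf = c(141, 255)) {
  rr <- tibble::tibble(
    region = c("GM", "WM", "CSF"),
    low = c(gm[1], wm[1], csf[1]),
    high = c(gm[2], wm[2], csf[2])
  )
  validate_ranges(rr)
}

validate_ranges <- function(rr) {
  stopifnot(is.data.frame(rr), all(c("region", "low", "high") %in% names(rr)))
  if (any(rr$low > rr$high) || any(rr$low < 0) || any(rr$high > 255)) {
    stop("each range needs 0 <= low <= high <= 255", call. = FALSE)
  }
  if (nrow(rr) > 1L && any(rr$low[-1] <= rr$high[-nrow(rr)])) {
    stop("ranges must be non-overlapping and ascending", call. = FALSE)
  }
  rr
}

#' Gray-level histogram of one image plane
#'
#' Exact counts over the full 8-bit range; the counts always sum to the
#' plane's pixel count.
#'
#' @param plane An integer matrix with values in `[0, 255]`, or a
#'   [gray_volume()] (with `z` selecting the plane).
#' @param z Plane index when `plane` is a volume.
#' @return A tibble with columns `gray` (0-255) and `count`.
#' @export
compute_histogram <- function(plane, z = 1L) {
  if (inherits(plane, "gray_volume")) plane <- get_plane(plane, z)
  if (length(plane) == 0L) stop("plane is empty", call. = FALSE)
  tibble::tibble(gray = 0:255, count = tabulate(as.integer(plane) + 1L, 256L))
}

#' Histogram peaks (strict local maxima with plateau handling)
#'
#' A gray level `g` is a peak when `h(g-1) < h(g) > h(g+1)`. A plateau of
#' equal counts flanked on both sides by smaller counts contributes a single
#' peak at its midpoint (lower median). Gray levels 0 and 255 are never
#' peaks, so the (typically huge) background bin can never masquerade as a
#' tissue mode.
#'
#' @param h A histogram tibble from [compute_histogram()].
#' @return A tibble with columns `gray` and `count`, ascending in `gray`.
#' @export
find_peaks <- function(h) {
  counts <- histogram_counts(h)
  r <- rle(counts)
  n_runs <- length(r$values)
  if (n_runs < 3L) return(tibble::tibble(gray = integer(), count = integer()))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- 2:(n_runs - 1L)
  is_peak <- r$values[idx] > r$values[idx - 1L] & r$values[idx] > r$values[idx + 1L]
  keep <- idx[is_peak]
  # plateau midpoint, lower median; -1 converts bin index to gray level
  gray <- starts[keep] + (r$lengths[keep] - 1L) %/% 2L - 1L
  tibble::tibble(gray = gray, count = r$values[keep])
}

histogram_counts <- function(h) {
  if (is.data.frame(h)) {
    stopifnot(all(c("gray", "count") %in% names(h)))
    counts <- integer(256)
    counts[h$gray + 1L] <- as.integer(h$count)
    counts
  } else {
    stopifnot(length(h) == 256L)
    as.integer(h)
  }
}

#' Drop minor histogram peaks
#'
#' Removes peaks whose count falls below `fraction` of the highest peak
#' count (default 5\%), discarding noise spikes before the merge step.
#' Idempotent.
#'
#' @param peaks A peak tibble from [find_peaks()].
#' @param fraction Pruning fraction in `(0, 1)`; default `0.05`.
#' @return The surviving peaks, same columns.
#' @export
prune_peaks <- function(peaks, fraction = 0.05) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (nrow(peaks) == 0L) return(peaks)
  peaks[peaks$count >= fraction * max(peaks$count), , drop = FALSE]
}

#' Merge peaks closer than a minimum separation
#'
#' Scans peaks in ascending gray order; whenever the next peak lies closer
#' than `min_separation` gray levels to the last kept peak, only the
#' higher-count of the two survives (ties keep the lower gray level), and
#' scanning restarts from the survivor. The result is pairwise separated by
#' at least `min_separation`, which makes the operation idempotent.
#'
#' @param peaks A peak tibble, ascending in `gray`.
#' @param min_separation Minimum gray-level distance between kept peaks;
#'   default 10.
#' @return The merged peak tibble.
#' @export
merge_peaks <- function(peaks, min_separation = 10) {
  if (!is.numeric(min_separation) || min_separation < 1) {
    stop("`min_separation` must be >= 1", call. = FALSE)
  }
  n <- nrow(peaks)
  if (n <= 1L) return(peaks)
  keep <- 1L
  for (i in 2:n) {
    last <- keep[length(keep)]
    if (peaks$gray[i] - peaks$gray[last] < min_separation) {
      if (peaks$count[i] > peaks$count[last]) keep[length(keep)] <- i
      # tie or lower: the incumbent (lower gray) stays
    } else {
      keep <- c(keep, i)
    }
  }
  peaks[keep, , drop = FALSE]
}

#' Pick one centroid per anatomical range
#'
#' For each region the centroid is the gray level of the highest-count
#' surviving peak inside `[low, high]`. Degenerate inputs fall back
#' gracefully: with no peak in the range, the argmax of the raw histogram
#' inside the range is used (`source = "raw-argmax"`); with no counts at all
#' in the range, the range midpoint is used and a warning raised
#' (`source = "midpoint"`). Count ties break to the lower gray level.
#'
#' @param peaks Peak tibble (after pruning/merging).
#' @param ranges A [region_ranges()] tibble.
#' @param h The raw histogram of the same plane (for the fallback).
#' @return A tibble with columns `region`, `centroid`, `source`.
#' @export
select_centroids <- function(peaks, ranges = region_ranges(), h = NULL) {
  ranges <- validate_ranges(ranges)
  counts <- if (is.null(h)) NULL else histogram_counts(h)
  purrr::pmap_dfr(ranges, function(region, low, high) {
    in_range <- peaks[peaks$gray >= low & peaks$gray <= high, , drop = FALSE]
    if (nrow(in_range) > 0L) {
      best <- in_range$gray[which.max(in_range$count)]  # first max = lower gray
      return(tibble::tibble(region = region, centroid = best, source = "peak"))
    }
    if (!is.null(counts)) {
      levels <- low:high
      cr <- counts[levels + 1L]
      if (sum(cr) > 0L) {
        return(tibble::tibble(region = region,
                              centroid = levels[which.max(cr)],
                              source = "raw-argmax"))
      }
    }
    warning(sprintf("no counts in region %s [%d, %d]; using range midpoint",
                    region, low, high), call. = FALSE)
    tibble::tibble(region = region, centroid = (low + high) %/% 2L,
                   source = "midpoint")
  })
}

#' Automatic centroid selection for a whole volume
#'
#' Runs the full per-plane pipeline in a single pass with no iteration:
#' histogram, peak detection, 5\% pruning, distance merging, and per-range
#' centroid selection. With `global = TRUE` the plane histograms are pooled
#' before peak analysis and the same centroids are applied to every plane.
#'
#' @param v A [gray_volume()].
#' @param ranges A [region_ranges()] tibble.
#' @param prune_fraction Passed to [prune_peaks()].
#' @param min_separation Passed to [merge_peaks()].
#' @param global Pool all plane histograms into one centroid set?
#' @return A tibble with columns `plane`, `region`, `centroid`, `source`,
#'   of class `centroid_set`; one row per plane and region, region order
#'   following `ranges`.
#' @examples
#' ph <- generate_phantom(shape = c(1, 64, 64), noise_sigma = 0)
#' auto_centroids(ph$volume)
#' @export
auto_centroids <- function(v, ranges = region_ranges(), prune_fraction = 0.05,
                           min_separation = 10, global = FALSE) {
  stopifnot(inherits(v, "gray_volume"))
  plane_centroids <- function(h, z) {
    find_peaks(h) |>
      prune_peaks(prune_fraction) |>
      merge_peaks(min_separation) |>
      select_centroids(ranges, h) |>
      dplyr::mutate(plane = z, .before = 1)
  }
  if (global) {
    pooled <- compute_histogram(v, 1L)
    for (z in seq_len(n_planes(v))[-1]) {
      pooled$count <- pooled$count + compute_histogram(v, z)$count
    }
    one <- plane_centroids(pooled, 1L)
    out <- purrr::map_dfr(seq_len(n_planes(v)),
                          function(z) dplyr::mutate(one, plane = z))
  } else {
    out <- purrr::map_dfr(seq_len(n_planes(v)),
                          function(z) plane_centroids(compute_histogram(v, z), z))
  }
  class(out) <- c("centroid_set", class(out))
  out
}
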