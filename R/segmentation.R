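#' Hard nearest-centroid segmentation
#'
#' Single-phase clustering: every voxel is assigned to the region whose
#' centroid (for that voxel's plane) is nearest in absolute gray-level
#' distance. Centroids are never updated by the pass. Ties break to the
#' lowest region index. Voxels darker than `background_low` get label 0
#' (background); pass `background_low = NULL` to classify every voxel.
#'
#' @param v A [gray_volume()].
#' @param centroids A `centroid_set` tibble from [auto_centroids()], or a
#'   numeric vector of centroids applied to every plane.
#' @param background_low Gray level below which voxels are background
#'   (default 45, the GM lower bound), or `NULL` to disable.
#' @return An integer array of class `label_map`, same shape as `v`, with
#'   values `0` (background) to `k`; region names kept in the `regions`
#'   attribute.
#' @export
assign_hard <- function(v, centroids, background_low = 45) {
  stopifnot(inherits(v, "gray_volume"))
  cen <- centroid_matrix(centroids, n_planes(v))
  labels <- array(0L, dim = dim(v))
  for (z in seq_len(n_planes(v))) {
    plane <- v[z, , ]
    d <- abs(outer(as.vector(plane), cen$values[z, ], "-"))
    lab <- max.col(-d, ties.method = "first")
    if (!is.null(background_low)) lab[as.vector(plane) < background_low] <- 0L
    labels[z, , ] <- lab
  }
  structure(labels, class = c("label_map", "array"), regions = cen$regions)
}

# Normalize centroid input to a planes x k matrix plus region names.
centroid_matrix <- function(centroids, nz) {
  if (inherits(centroids, "data.frame")) {
    stopifnot(all(c("plane", "region", "centroid") %in% names(centroids)))
    regions <- unique(centroids$region)
    m <- matrix(NA_real_, nz, length(regions))
    for (j in seq_along(regions)) {
      rows <- centroids[centroids$region == regions[j], ]
      rows <- rows[rows$plane >= 1L & rows$plane <= nz, ]
      m[rows$plane, j] <- rows$centroid
    }
    if (any(is.na(m))) stop("missing centroids for some planes", call. = FALSE)
    list(values = m, regions = regions)
  } else {
    if (!is.numeric(centroids) || length(centroids) < 1L) {
      stop("`centroids` must be a centroid_set tibble or numeric vector",
           call. = FALSE)
    }
    list(values = matrix(centroids, nz, length(centroids), byrow = TRUE),
         regions = names(centroids) %||% paste0("R", seq_along(centroids)))
  }
}

#' Soft (graded membership) segmentation
#'
#' Inverse-square-distance memberships: for voxel value `g` and region
#' centroid `c_r`, `u_r = (d_r + eps)^-2 / sum_s (d_s + eps)^-2` with
#' `d_r = |g - c_r|` and `eps = 1e-6`. Memberships are nonnegative and sum
#' to 1 per voxel; a voxel exactly on a centroid receives membership ~1 for
#' that region. The argmax over regions reproduces [assign_hard()] (without
#' background) wherever distances are not exactly tied.
#'
#' @inheritParams assign_hard
#' @return A numeric array of class `membership_map` with dimensions
#'   `c(planes, rows, cols, k)`; region names in the `regions` attribute.
#' @export
assign_soft <- function(v, centroids) {
  stopifnot(inherits(v, "gray_volume"))
  eps <- 1e-6
  cen <- centroid_matrix(centroids, n_planes(v))
  k <- ncol(cen$values)
  memb <- array(0, dim = c(dim(v), k))
  for (z in seq_len(n_planes(v))) {
    d <- abs(outer(as.vector(v[z, , ]), cen$values[z, ], "-"))
    w <- 1 / (d + eps)^2
    w <- w / rowSums(w)
    memb[z, , , ] <- w
  }
  structure(memb, class = c("membership_map", "array"), regions = cen$regions)
}

#' Extract one region's intensities from a segmented volume
#'
#' Hard mode keeps the original intensity of voxels carrying the region's
#' label and zeroes everything else; soft mode scales each voxel's intensity
#' by its membership in the region (rounded), so more opaque pixels are the
#' ones more strongly classified into the region.
#'
#' @param v The source [gray_volume()].
#' @param m A `label_map` (hard mode) or `membership_map` (soft mode).
#' @param region Region name or index.
#' @param mode `"hard"` or `"soft"`; inferred from `m` when omitted.
#' @return A [gray_volume()] of the extracted region.
#' @export
extract_region <- function(v, m, region, mode = NULL) {
  stopifnot(inherits(v, "gray_volume"))
  regions <- attr(m, "regions")
  idx <- if (is.character(region)) match(region, regions) else as.integer(region)
  if (is.na(idx) || idx < 1L || idx > length(regions)) {
    stop("unknown region: ", region, call. = FALSE)
  }
  if (is.null(mode)) mode <- if (inherits(m, "label_map")) "hard" else "soft"
  mode <- match.arg(mode, c("hard", "soft"))
  if (mode == "hard") {
    stopifnot(inherits(m, "label_map"))
    out <- unclass(v) * (unclass(m) == idx)
  } else {
    stopifnot(inherits(m, "membership_map"))
    out <- round(unclass(v) * array(m[, , , idx], dim = dim(v)))
  }
  gray_volume(out, source = attr(v, "source"))
}

#' Default segmentation rendering colors
#'
#' GM purple, WM dark pink, CSF yellow, background black. Exact RGB values
#' are configuration, not science; these defaults follow the conventional
#' display of the three tissue classes.
#'
#' @return A named list of RGB triples, including `background`.
#' @export
default_color_table <- function() {
  list(background = c(0, 0, 0),
       GM = c(128, 0, 128),     # purple
       WM = c(219, 112, 147),   # dark pink
       CSF = c(255, 255, 0))    # yellow
}

#' Render a hard label map to color images
#'
#' @param labels A `label_map`.
#' @param color_table Named list mapping each region name (and
#'   `"background"`) to an RGB triple; defaults to [default_color_table()].
#' @return A list of [color_image()], one per plane.
#' @export
render_hard <- function(labels, color_table = NULL) {
  stopifnot(inherits(labels, "label_map"))
  regions <- attr(labels, "regions")
  color_table <- color_table %||% default_color_table()
  present <- sort(unique(as.vector(labels)))
  needed <- c(if (0L %in% present) "background", regions[present[present > 0L]])
  missing <- setdiff(needed, names(color_table))
  if (length(missing) > 0L || any(present > length(regions))) {
    bad <- if (any(present > length(regions))) present[present > length(regions)] else missing
    stop("no color for label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  lut <- rbind(color_table$background %||% c(0, 0, 0),
               do.call(rbind, lapply(regions, function(r) {
                 color_table[[r]] %||% c(0, 0, 0)  # checked above if present
               })))
  lapply(seq_len(dim(labels)[1]), function(z) {
    lab <- matrix(labels[z, , ], dim(labels)[2], dim(labels)[3])
    color_image(array(lut[lab + 1L, ], dim = c(dim(lab), 3L)))
  })
}

#' Per-region voxel counts of a label map
#'
#' @param labels A `label_map`.
#' @return A tibble with columns `region` (including `"background"`) and
#'   `voxels`; counts over all regions partition the volume.
#' @export
region_volumes <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  regions <- attr(labels, "regions")
  counts <- tabulate(as.vector(labels) + 1L, nbins = length(regions) + 1L)
  tibble::tibble(region = c("background", regions), voxels = counts)
}

#' Voxel count of a single region
#'
#' @param labels A `label_map`.
#' @param region Region name or index (0 or `"background"` for background).
#' @return Integer voxel count.
#' @export
region_volume <- function(labels, region) {
  stopifnot(inherits(labels, "label_map"))
  regions <- attr(labels, "regions")
  if (is.character(region)) {
    if (region == "background") {
      idx <- 0L
    } else {
      idx <- match(region, regions)
      if (is.na(idx)) stop("unknown region: ", region, call. = FALSE)
    }
  } else {
    idx <- as.integer(region)
    if (idx < 0L || idx > length(regions)) {
      stop("unknown region index: ", region, call. = FALSE)
    }
  }
  sum(labels == idx)
}
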