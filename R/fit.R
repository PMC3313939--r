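#' Segment a gray volume end to end
#'
#' The whole single-phase pipeline: per-plane histogram peak analysis,
#' automatic centroid selection inside the anatomical ranges, and
#' nearest-centroid voxel classification (plus optional soft memberships).
#' Centroids are selected once and never updated by the voxel pass.
#'
#' @param v A [gray_volume()].
#' @param ranges A [region_ranges()] tibble.
#' @param prune_fraction,min_separation Peak pipeline parameters; see
#'   [prune_peaks()] and [merge_peaks()].
#' @param background_low Background cutoff for [assign_hard()]; `NULL`
#'   disables the background class.
#' @param soft Also compute soft memberships?
#' @param global_centroids Pool plane histograms into one centroid set?
#' @return An object of class `chromaseg_fit`: a list with `volume`,
#'   `centroids`, `labels`, `memberships` (or `NULL`), `ranges`, `params`.
#' @examples
#' ph <- generate_phantom(shape = c(1, 64, 64), seed = 3)
#' fit <- segment_volume(ph$volume)
#' tidy(fit)
#' @export
segment_volume <- function(v, ranges = region_ranges(), prune_fraction = 0.05,
                           min_separation = 10, background_low = 45,
                           soft = FALSE, global_centroids = FALSE) {
  stopifnot(inherits(v, "gray_volume"))
  cen <- auto_centroids(v, ranges, prune_fraction, min_separation,
                        global = global_centroids)
  labels <- assign_hard(v, cen, background_low)
  memb <- if (soft) assign_soft(v, cen) else NULL
  structure(
    list(volume = v, centroids = cen, labels = labels, memberships = memb,
         ranges = ranges,
         params = list(prune_fraction = prune_fraction,
                       min_separation = min_separation,
                       background_low = background_low,
                       global_centroids = global_centroids)),
    class = "chromaseg_fit")
}

#' @export
print.chromaseg_fit <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<chromaseg_fit> %d plane(s) of %d x %d, %d regions\n",
              d[1], d[2], d[3], nrow(x$ranges)))
  print(glance(x))
  invisible(x)
}

#' Tidy a segmentation fit
#'
#' One row per plane and region: the selected centroid, how it was chosen,
#' and the region's voxel count and within-plane fraction.
#'
#' @param x A `chromaseg_fit`.
#' @param ... Unused.
#' @return A tibble with columns `plane`, `region`, `centroid`, `source`,
#'   `voxels`, `fraction`.
#' @export
tidy.chromaseg_fit <- function(x, ...) {
  d <- dim(x$labels)
  per_plane <- purrr::map_dfr(seq_len(d[1]), function(z) {
    counts <- tabulate(as.vector(x$labels[z, , ]) + 1L,
                       nbins = nrow(x$ranges) + 1L)
    tibble::tibble(plane = z, region = x$ranges$region,
                   voxels = counts[-1L], fraction = counts[-1L] / (d[2] * d[3]))
  })
  dplyr::left_join(x$centroids, per_plane, by = c("plane", "region"))
}

#' One-row summary of a segmentation fit
#'
#' @param x A `chromaseg_fit`.
#' @param ... Unused.
#' @return A one-row tibble: planes, plane dims, number of regions,
#'   background fraction, and total foreground voxels.
#' @export
glance.chromaseg_fit <- function(x, ...) {
  d <- dim(x$labels)
  bg <- sum(x$labels == 0L)
  tibble::tibble(n_planes = d[1], n_rows = d[2], n_cols = d[3],
                 k = nrow(x$ranges),
                 background_fraction = bg / length(x$labels),
                 foreground_voxels = length(x$labels) - bg)
}

#' Plot a segmentation fit
#'
#' `type = "labels"` renders one plane with the region color table
#' (GM purple, WM dark pink, CSF yellow by default); `type = "histogram"`
#' shows that plane's gray-level histogram with the selected centroids.
#'
#' @param object A `chromaseg_fit`.
#' @param plane Plane index to display.
#' @param type `"labels"` or `"histogram"`.
#' @param color_table Optional named color table (see [render_hard()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chromaseg_fit <- function(object, plane = 1L,
                                   type = c("labels", "histogram"),
                                   color_table = NULL, ...) {
  type <- match.arg(type)
  if (type == "histogram") {
    h <- compute_histogram(object$volume, plane)
    cen <- dplyr::filter(object$centroids, .data$plane == !!plane)
    return(
      ggplot2::ggplot(h, ggplot2::aes(x = .data$gray, y = .data$count)) +
        ggplot2::geom_col(width = 1, fill = "grey40") +
        ggplot2::geom_vline(data = cen,
                            ggplot2::aes(xintercept = .data$centroid,
                                         color = .data$region),
                            linewidth = 0.8) +
        ggplot2::labs(x = "gray level", y = "count", color = "centroid",
                      title = sprintf("Plane %d histogram and centroids", plane)) +
        ggplot2::theme_minimal()
    )
  }
  ct <- color_table %||% default_color_table()
  img <- render_hard(object$labels, ct)[[plane]]
  df <- tidyr::expand_grid(row = seq_len(dim(img)[1]), col = seq_len(dim(img)[2]))
  df$fill <- grDevices::rgb(img[cbind(df$row, df$col, 1L)],
                            img[cbind(df$row, df$col, 2L)],
                            img[cbind(df$row, df$col, 3L)], maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(title = sprintf("Hard segmentation, plane %d", plane)) +
    ggplot2::theme_void()
}

#' Plot a chromaticity palette as a strip
#'
#' @param object A [build_palette()] tibble.
#' @param ... Unused.
#' @return A ggplot object: one tile per entry in luma order.
#' @export
autoplot.chroma_palette <- function(object, ...) {
  df <- dplyr::mutate(object, idx = dplyr::row_number(),
                      fill = grDevices::rgb(.data$R, .data$G, .data$B,
                                            maxColorValue = 255))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = 1, fill = .data$fill)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(x = "palette index (ascending luma)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
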