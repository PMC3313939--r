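#' Read a grayscale image or volume
#'
#' Reads 8- or 16-bit grayscale PNG or TIFF images (single files, multi-page
#' TIFFs, or stacks given as several files / a directory of files) and
#' NIfTI-1 volumes, normalizing everything to the internal 8-bit
#' [gray_volume()]. Sources with more than 8 bits of depth are linearly
#' min-max rescaled to `[0, 255]` over the whole volume (not per slice) so
#' inter-slice intensity relations survive, then rounded half-up. Stack
#' order is file-name order for directories and the given order for explicit
#' file vectors; NIfTI planes follow the axial index.
#'
#' DICOM series are not supported; convert to NIfTI or PNG/TIFF first.
#'
#' @param path Path to a file, a directory of slice files, or a character
#'   vector of slice files (stack order as given).
#' @param format_hint Optional: one of `"png"`, `"tiff"`, `"nifti"`.
#'   Normally inferred from the extension.
#' @return A [gray_volume()].
#' @export
read_gray <- function(path, format_hint = NULL) {
  if (length(path) > 1L) {
    planes <- lapply(path, read_gray_file, format_hint = format_hint)
    return(stack_planes(planes, source = path[1]))
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (length(files) == 0L) stop("empty series directory: ", path, call. = FALSE)
    if (any(grepl("\\.dcm$", files, ignore.case = TRUE))) {
      stop("DICOM series are not supported; convert to NIfTI or PNG/TIFF first",
           call. = FALSE)
    }
    planes <- lapply(files, read_gray_file, format_hint = format_hint)
    return(stack_planes(planes, source = path))
  }
  read_gray_file(path, format_hint)
}

infer_format <- function(path, format_hint = NULL) {
  if (!is.null(format_hint)) return(match.arg(format_hint, c("png", "tiff", "nifti")))
  low <- tolower(path)
  if (grepl("\\.png$", low)) return("png")
  if (grepl("\\.(tif|tiff)$", low)) return("tiff")
  if (grepl("\\.(nii|nii\\.gz|hdr|img)$", low)) return("nifti")
  if (grepl("\\.dcm$", low)) {
    stop("DICOM files are not supported; convert to NIfTI or PNG/TIFF first",
         call. = FALSE)
  }
  stop("cannot infer image format from path: ", path, call. = FALSE)
}

read_gray_file <- function(path, format_hint = NULL) {
  fmt <- infer_format(path, format_hint)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(fmt,
    png = read_gray_png(path),
    tiff = read_gray_tiff(path),
    nifti = read_gray_nifti(path)
  )
}

# png::readPNG normalizes to [0,1] and drops the bit depth. Values exactly
# on the k/255 grid are treated as 8-bit and recovered verbatim; anything
# else is taken as high-depth data and min-max rescaled per the io contract.
read_gray_png <- function(path) {
  x <- tryCatch(png::readPNG(path), error = function(e) {
    stop("unreadable PNG: ", path, " (", conditionMessage(e), ")", call. = FALSE)
  })
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L) {
      stop("RGB input to read_gray(): convert to grayscale or use read_color()",
           call. = FALSE)
    }
    x <- x[, , 1]  # gray + alpha: keep gray
  }
  u <- x * 255
  if (max(abs(u - round(u))) < 1e-6) {
    gray_volume(round(u), source = path, bit_depth = 8L)
  } else {
    raw <- round(x * 65535)
    gray_volume(rescale_minmax(raw), source = path, bit_depth = 16L)
  }
}

read_gray_tiff <- function(path) {
  x <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                error = function(e) {
    stop("unreadable TIFF: ", path, " (", conditionMessage(e), ")", call. = FALSE)
  })
  if (!is.list(x)) x <- list(x)
  x <- lapply(x, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] >= 3L) {
        stop("RGB input to read_gray(): convert to grayscale or use read_color()",
             call. = FALSE)
      }
      p <- p[, , 1]
    }
    p
  })
  arr <- array(0, dim = c(length(x), nrow(x[[1]]), ncol(x[[1]])))
  for (z in seq_along(x)) arr[z, , ] <- x[[z]]
  if (max(arr) > 255) {
    gray_volume(rescale_minmax(arr), source = path, bit_depth = 16L)
  } else {
    gray_volume(arr, source = path, bit_depth = 8L)
  }
}

read_gray_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    stop("unreadable NIfTI: ", path, " (", conditionMessage(e), ")", call. = FALSE)
  })
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  if (length(dim(arr)) != 3L) stop("only 3D NIfTI volumes are supported", call. = FALSE)
  arr <- aperm(arr, c(3L, 2L, 1L))  # axial index first, then row, col
  if (min(arr) < 0 || max(arr) > 255 || any(arr != round(arr))) {
    arr <- rescale_minmax(arr)
    depth <- 16L
  } else {
    depth <- 8L
  }
  gray_volume(arr, source = path, bit_depth = depth)
}

# Linear min-max rescale to [0,255], rounded half-up; constant input maps to 0.
rescale_minmax <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(array(0, dim = dim(x) %||% length(x)))
  floor((x - rng[1]) / (rng[2] - rng[1]) * 255 + 0.5)
}

stack_planes <- function(planes, source) {
  dims <- vapply(planes, function(p) dim(p)[2:3], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("slice dimensions differ across the stack", call. = FALSE)
  }
  arr <- array(0L, dim = c(length(planes), dims[1, 1], dims[2, 1]))
  for (z in seq_along(planes)) arr[z, , ] <- planes[[z]][1, , ]
  gray_volume(arr, source = source,
              bit_depth = max(vapply(planes, attr, integer(1), "bit_depth")))
}

#' Read a color (RGB) image
#'
#' Grayscale input is promoted to RGB triples `(g, g, g)`.
#'
#' @param path Path to a PNG or TIFF file.
#' @return A [color_image()].
#' @export
read_color <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- infer_format(path)
  if (fmt == "nifti") stop("read_color() supports PNG and TIFF only", call. = FALSE)
  x <- tryCatch(
    if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path),
    error = function(e) {
      stop("unreadable image: ", path, " (", conditionMessage(e), ")", call. = FALSE)
    })
  if (length(dim(x)) == 2L) {
    x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  } else if (dim(x)[3] == 2L) {
    x <- array(rep(x[, , 1], 3L), dim = c(dim(x)[1:2], 3L))
  } else if (dim(x)[3] == 4L) {
    x <- x[, , 1:3]
  }
  color_image(round(x * 255))
}

#' Write a color image as PNG
#' @param image A [color_image()].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_color <- function(image, path) {
  stopifnot(inherits(image, "color_image"))
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' Write a gray volume as one PNG per plane (or a single PNG for one plane)
#' @param v A [gray_volume()].
#' @param path Output path: a `.png` file for single-plane volumes, otherwise
#'   a directory (created if needed) receiving `plane_###.png` files.
#' @return Invisibly, the written file path(s).
#' @export
write_gray <- function(v, path) {
  stopifnot(inherits(v, "gray_volume"))
  if (n_planes(v) == 1L && grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(get_plane(v, 1L) / 255, target = path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(path, sprintf("plane_%03d.png", seq_len(n_planes(v))))
  for (z in seq_len(n_planes(v))) {
    png::writePNG(get_plane(v, z) / 255, target = files[z])
  }
  invisible(files)
}

#' Write a label map: rendered PNG per plane plus a CSV of region volumes
#'
#' @param labels A `label_map` from [assign_hard()].
#' @param path Output directory (created if needed).
#' @param color_table Optional named color table passed to [render_hard()].
#' @return Invisibly, the CSV path.
#' @export
write_labels <- function(labels, path, color_table = NULL) {
  stopifnot(inherits(labels, "label_map"))
  if (length(labels) == 0L) stop("empty label map", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  imgs <- render_hard(labels, color_table)
  for (z in seq_along(imgs)) {
    write_color(imgs[[z]], file.path(path, sprintf("labels_%03d.png", z)))
  }
  vols <- region_volumes(labels)
  csv <- file.path(path, "region_volumes.csv")
  utils::write.csv(vols, csv, row.names = FALSE)
  invisible(csv)
}

#' Write a report record as JSON
#'
#' Round-trips through [read_report()].
#'
#' @param report A list or data frame (e.g. a centroid table).
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#' @param path JSON path.
#' @return The parsed record (data frames simplified).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
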