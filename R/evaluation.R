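#' Volume-based Jaccard coefficient between two region volumes
#'
#' The volume-difference ratio `Jc = |v1 - v2| / (v1 + v2)` between two
#' voxel counts of the same anatomical region extracted by two methods.
#' It is 0 for identical volumes, approaches 1 as one volume dominates, is
#' symmetric in its arguments, and is invariant to scaling both volumes.
#' Note this compares volumes only, not spatial overlap; it is the
#' coefficient conventionally reported next to per-region voxel counts.
#'
#' @param v1,v2 Nonnegative voxel counts, not both zero.
#' @return A one-row tibble of class `jaccard_result` with columns `v1`,
#'   `v2`, `coefficient`.
#' @examples
#' jaccard_volume(7921, 7466)
#' @export
jaccard_volume <- function(v1, v2) {
  if (!is.numeric(v1) || !is.numeric(v2) || v1 < 0 || v2 < 0) {
    stop("volumes must be nonnegative numbers", call. = FALSE)
  }
  if (v1 + v2 == 0) {
    stop("Jaccard coefficient is undefined for two empty volumes", call. = FALSE)
  }
  out <- tibble::tibble(v1 = v1, v2 = v2,
                        coefficient = abs(v1 - v2) / (v1 + v2))
  class(out) <- c("jaccard_result", class(out))
  out
}

#' @export
print.jaccard_result <- function(x, ...) {
  cat(sprintf("Jc(%s, %s) = %.8f\n",
              format(x$v1, big.mark = ","), format(x$v2, big.mark = ","),
              x$coefficient))
  invisible(x)
}

#' Region-wise Jaccard comparison of two segmentations
#'
#' Computes [jaccard_volume()] per shared region between two volume tables
#' (e.g. one method's counts against a reference method's).
#'
#' @param volumes_a,volumes_b Region volume tables: tibbles with columns
#'   `region` and `voxels` (as from [region_volumes()]), or named numeric
#'   vectors. Region keys must agree.
#' @return A tibble with columns `region`, `v1`, `v2`, `coefficient`.
#' @examples
#' compare_methods(c(GM = 7921, WM = 10567, CSF = 1546),
#'                 c(GM = 7466, WM = 11928, CSF = 1391))
#' @export
compare_methods <- function(volumes_a, volumes_b) {
  a <- as_volume_table(volumes_a)
  b <- as_volume_table(volumes_b)
  if (!setequal(a$region, b$region)) {
    stop("region keys differ: ", paste(setdiff(union(a$region, b$region),
                                               intersect(a$region, b$region)),
                                       collapse = ", "), call. = FALSE)
  }
  dplyr::inner_join(a, b, by = "region", suffix = c("_a", "_b")) |>
    dplyr::rowwise() |>
    dplyr::mutate(coefficient = jaccard_volume(voxels_a, voxels_b)$coefficient) |>
    dplyr::ungroup() |>
    dplyr::rename(v1 = "voxels_a", v2 = "voxels_b")
}

as_volume_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("region", "voxels") %in% names(x)))
    tibble::as_tibble(x[, c("region", "voxels")])
  } else if (is.numeric(x) && !is.null(names(x))) {
    tibble::tibble(region = names(x), voxels = unname(x))
  } else {
    stop("volumes must be a region/voxels table or a named numeric vector",
         call. = FALSE)
  }
}
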