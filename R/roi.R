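#' Morphological erosion with a radius-1 spherical kernel
#'
#' Erodes a binary ROI mask with the set of voxels at Euclidean distance at
#' most one voxel — the 6-neighbour cross plus centre — applied
#' `iterations` times (default 3, the standard partial-volume guard before
#' ROI statistics). The 26-neighbourhood (radius sqrt(3)) is available for
#' comparison.
#'
#' @param mask 3-D logical array.
#' @param iterations number of erosion passes, default 3.
#' @param neighborhood 6 (radius-1 ball, default) or 26 (full cube).
#' @return eroded logical array, always a subset of the input.
#' @export
erode_mask <- function(mask, iterations = 3L, neighborhood = c(6L, 26L)) {
  neighborhood <- match.arg(as.character(neighborhood[1]), c("6", "26"))
  mask <- as.array(mask)
  stopifnot(length(dim(mask)) == 3L)
  storage.mode(mask) <- "logical"
  for (it in seq_len(iterations)) {
    if (!any(mask)) break
    out <- mask
    for (axis in 1:3) for (dir in c(-1L, 1L))
      out <- out & shift_array(mask, axis, dir, fill = FALSE)
    if (neighborhood == "26") {
      # remaining 20 offsets: all nonzero {-1,0,1}^3 beyond the 6 faces
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        nz <- sum(c(dx, dy, dz) != 0)
        if (nz < 2) next
        sh <- mask
        if (dx != 0) sh <- shift_array(sh, 1, dx, FALSE)
        if (dy != 0) sh <- shift_array(sh, 2, dy, FALSE)
        if (dz != 0) sh <- shift_array(sh, 3, dz, FALSE)
        out <- out & sh
      }
    }
    mask <- out
  }
  mask
}

#' Two-sided percentile trimming
#'
#' Keeps values between the `lo`th and `hi`th percentiles (inclusive),
#' percentiles computed by linear interpolation between order statistics
#' (type-7 quantiles) on the supplied values themselves. This is the
#' outlier-removal step applied to each ROI's voxel values after erosion.
#'
#' @param values nonempty numeric vector.
#' @param lo,hi lower/upper percentiles, defaults 1 and 99.
#' @return the surviving values, in input order.
#' @export
trim_outliers <- function(values, lo = 1, hi = 99) {
  if (!length(values)) stop("cannot trim an empty vector")
  stopifnot(lo >= 0, hi <= 100, lo < hi)
  q <- stats::quantile(values, c(lo, hi) / 100, names = FALSE, type = 7)
  values[values >= q[1] & values <= q[2]]
}

#' ROI summary statistics after erosion and trimming
#'
#' The per-ROI preprocessing used in the cohort analysis: erode the ROI mask
#' (partial-volume guard), remove voxel values outside the 1st/99th
#' percentiles of the eroded set, then report mean and standard deviation.
#' Order is fixed: erode, then trim, then summarize.
#'
#' @param chi a [susceptibility_volume()] or 3-D array.
#' @param mask logical ROI mask.
#' @param roi name used in reporting and error messages.
#' @param erode_iterations erosion passes (0 disables), default 3.
#' @param trim length-2 percentile bounds, default `c(1, 99)`; `NULL`
#'   disables trimming.
#' @return a one-row data.frame: `roi`, `mean`, `sd`, `n_voxels` (original),
#'   `n_eroded`, `n_used`.
#' @export
summarize_roi <- function(chi, mask, roi = "roi", erode_iterations = 3L,
                          trim = c(1, 99)) {
  vals <- vol_values(chi)
  mask <- as.array(mask)
  if (!identical(dim(mask), dim(vals)))
    stop("ROI mask shape does not match the volume")
  n0 <- sum(mask)
  em <- if (erode_iterations > 0) erode_mask(mask, erode_iterations) else mask
  n1 <- sum(em)
  if (n1 == 0L)
    stop("ROI '", roi, "' vanished under erosion (", n0,
         " voxels before); reduce erode_iterations")
  v <- vals[em]
  if (!is.null(trim)) v <- trim_outliers(v, trim[1], trim[2])
  data.frame(roi = roi, mean = mean(v),
             sd = if (length(v) > 1) stats::sd(v) else 0, n_voxels = n0,
             n_eroded = n1, n_used = length(v), stringsAsFactors = FALSE)
}

#' ROI statistics for every region of a label map
#'
#' @param chi a [susceptibility_volume()].
#' @param labels a [label_map()].
#' @param erode_iterations,trim passed to [summarize_roi()].
#' @return data.frame with one row per ROI in legend order.
#' @export
roi_statistics <- function(chi, labels, erode_iterations = 3L,
                           trim = c(1, 99)) {
  stopifnot(inherits(labels, "label_map"))
  out <- lapply(names(labels$legend), function(id)
    summarize_roi(chi, labels$labels == as.integer(id),
                  roi = labels$legend[[id]],
                  erode_iterations = erode_iterations, trim = trim))
  do.call(rbind, out)
}
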