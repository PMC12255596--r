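#' Voxelwise accuracy test of a reconstructed ROI
#'
#' Treats the voxels within one ROI as independent samples from an
#' ROI-specific distribution and runs an unpaired Welch t test between the
#' referenced reconstruction voxels and the referenced ground-truth voxels.
#' The ROI is "accurate" when the two means are not significantly different
#' at the given level (p >= alpha). Reference scalars shift the means only;
#' variances are computed on the raw voxel sets, so referencing an ROI to
#' its own mean gives a numerator of exactly zero and t = 0.
#'
#' @param recon_voxels,gt_voxels numeric voxel values from the same ROI of
#'   the reconstruction and ground truth (>= 2 each).
#' @param recon_ref,gt_ref scalar reference values subtracted from the
#'   respective means (default 0).
#' @param alpha significance level, default 0.05.
#' @return list: `accurate` (logical), plus the underlying `welch_result`
#'   fields `statistic`, `df`, `p.value`.
#' @export
accuracy_test <- function(recon_voxels, gt_voxels, recon_ref = 0,
                          gt_ref = 0, alpha = 0.05) {
  n <- length(recon_voxels); m <- length(gt_voxels)
  if (n < 2 || m < 2) stop("both voxel sets need at least 2 voxels")
  if (!is.finite(recon_ref) || !is.finite(gt_ref))
    stop("reference values must be finite")
  wt <- welch_from_moments(mean(recon_voxels) - recon_ref,
                           stats::var(recon_voxels), n,
                           mean(gt_voxels) - gt_ref,
                           stats::var(gt_voxels), m)
  list(accurate = wt$p.value >= alpha, statistic = wt$statistic,
       df = wt$df, p.value = wt$p.value)
}

#' Accuracy table across reconstructions, ROIs and referencing strategies
#'
#' For every combination of reconstruction, test ROI and referencing
#' strategy, classifies the ROI as accurately reconstructed (voxelwise Welch
#' t against the ground truth, both referenced with the strategy's scalar).
#' Data-driven reference masks are computed once: the relative-variance mask
#' from the spread across the supplied reconstructions, the R2* mask from
#' the supplied relaxation map; both masks are shared by all volumes.
#'
#' @param recons named list of [susceptibility_volume()]s on the ground
#'   truth grid.
#' @param gt ground-truth [susceptibility_volume()] with a brain mask.
#' @param labels [label_map()] of the test ROIs.
#' @param strategies named list of [reference_strategy()] objects, or a
#'   character vector of shorthand names: `"none"`, `"wholebrain"`,
#'   `"relvar"`, `"r2s"`, or any ROI name in the legend (anatomical).
#' @param r2s optional `r2s_map` (needed for the `"r2s"` strategy).
#' @param alpha significance level, default 0.05.
#' @return object of class `accuracy_table`: `accurate` (logical array
#'   recon x roi x strategy), `counts` (roi x strategy accurate-count
#'   matrix), `sums` (per-strategy totals), `alpha`.
#' @export
accuracy_table <- function(recons, gt, labels, strategies = c("none"),
                           r2s = NULL, alpha = 0.05) {
  stopifnot(inherits(gt, "susceptibility_volume"),
            inherits(labels, "label_map"))
  if (is.null(names(recons)))
    names(recons) <- paste0("recon", seq_along(recons))
  if (is.character(strategies)) {
    nm <- strategies
    strategies <- lapply(strategies, function(s) {
      switch(s,
        none = reference_strategy("none"),
        wholebrain = reference_strategy("whole_brain"),
        relvar = reference_strategy("relative_variance"),
        r2s = reference_strategy("r2s_threshold"),
        reference_strategy("anatomical", roi = s))
    })
    names(strategies) <- nm
  }
  brain <- gt$brain_mask
  if (is.null(brain)) stop("ground truth must carry a brain mask")
  rois <- unname(labels$legend)
  masks <- lapply(names(labels$legend),
                  function(id) labels$labels == as.integer(id))
  names(masks) <- rois
  # shared masks for the data-driven strategies
  region_masks <- lapply(strategies, function(st) {
    if (st$kind == "relative_variance")
      low_percentile_mask(relative_variance_map(recons), brain,
                          st$percentile)
    else if (st$kind == "r2s_threshold") {
      if (is.null(r2s)) stop("the r2s_threshold strategy requires an R2* map")
      r2s_reference_mask(r2s, brain, st$threshold_hz)
    } else NULL
  })
  acc <- array(NA, dim = c(length(recons), length(rois), length(strategies)),
               dimnames = list(names(recons), rois, names(strategies)))
  for (s in seq_along(strategies)) {
    st <- strategies[[s]]
    gt_ref <- reference_value(gt, st, labels, region_masks[[s]])
    for (r in seq_along(recons)) {
      rec <- recons[[r]]
      if (!identical(dim(rec$values), dim(gt$values)))
        stop("reconstruction '", names(recons)[r],
             "' is not on the ground-truth grid")
      rec_ref <- reference_value(rec, st, labels, region_masks[[s]])
      for (j in seq_along(rois)) {
        m <- masks[[j]]
        acc[r, j, s] <- accuracy_test(rec$values[m], gt$values[m],
                                      rec_ref, gt_ref, alpha)$accurate
      }
    }
  }
  counts <- apply(acc, c(2, 3), sum)
  structure(list(accurate = acc, counts = counts,
                 sums = colSums(counts), alpha = alpha),
            class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat("<accuracy_table> ", dim(x$accurate)[1], " reconstructions x ",
      dim(x$accurate)[2], " ROIs x ", dim(x$accurate)[3],
      " strategies (alpha = ", x$alpha, ")\n", sep = "")
  print(rbind(x$counts, Sum = x$sums))
  invisible(x)
}
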