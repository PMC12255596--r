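#' Referencing strategy descriptor
#'
#' The five ways of choosing a scalar reference susceptibility: none,
#' anatomical ROI mean/median, whole-brain mean, low relative-variance
#' voxels, and the R2*-threshold region.
#'
#' @param kind one of `"none"`, `"anatomical"`, `"whole_brain"`,
#'   `"relative_variance"`, `"r2s_threshold"`.
#' @param roi ROI name, required for `"anatomical"`.
#' @param percentile percentile in (0, 100] for `"relative_variance"`;
#'   default 3 (the lowest third percentile).
#' @param threshold_hz R2* cutoff in Hz for `"r2s_threshold"`; default 4.
#' @param stat `"mean"` or `"median"` summary within the reference voxels.
#' @return object of class `reference_strategy`.
#' @export
reference_strategy <- function(kind = c("none", "anatomical", "whole_brain",
                                        "relative_variance",
                                        "r2s_threshold"),
                               roi = NULL, percentile = 3,
                               threshold_hz = 4, stat = c("mean", "median")) {
  kind <- match.arg(kind)
  stat <- match.arg(stat)
  if (kind == "anatomical" && is.null(roi))
    stop("anatomical referencing requires an ROI name")
  if (percentile <= 0 || percentile > 100)
    stop("percentile must lie in (0, 100]")
  if (threshold_hz <= 0) stop("threshold_hz must be positive")
  structure(list(kind = kind, roi = roi, percentile = percentile,
                 threshold_hz = threshold_hz, stat = stat),
            class = "reference_strategy")
}

#' Reference value within a region
#'
#' The scalar that referencing subtracts: the mean (or median)
#' susceptibility over a reference mask. Voxels outside the brain mask never
#' contribute.
#'
#' @param chi a [susceptibility_volume()] (or bare 3-D array).
#' @param mask logical array selecting the reference region.
#' @param stat `"mean"` or `"median"`.
#' @return scalar reference susceptibility in ppm.
#' @export
region_reference_value <- function(chi, mask, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  vals <- vol_values(chi)
  mask <- as.array(mask)
  if (!identical(dim(mask), dim(vals)))
    stop("mask shape does not match the volume")
  if (inherits(chi, "susceptibility_volume") && !is.null(chi$brain_mask))
    mask <- mask & chi$brain_mask
  v <- vals[mask]
  if (!length(v)) stop("reference mask is empty (within the brain)")
  if (stat == "mean") mean(v) else stats::median(v)
}

#' Whole-brain reference value
#'
#' Mean susceptibility over the brain mask. Setting the whole-volume mean to
#' zero is the implicit referencing performed by direct dipole inversions
#' whose kernel DC term is zero.
#'
#' @param chi a [susceptibility_volume()] or 3-D array.
#' @param brain_mask logical array; defaults to the volume's own mask.
#' @return scalar ppm.
#' @export
whole_brain_reference <- function(chi, brain_mask = NULL) {
  vals <- vol_values(chi)
  if (is.null(brain_mask) && inherits(chi, "susceptibility_volume"))
    brain_mask <- chi$brain_mask
  if (is.null(brain_mask)) stop("a brain mask is required")
  if (!any(brain_mask)) stop("brain mask is empty")
  mean(vals[brain_mask])
}

#' Voxelwise relative variance across volumes
#'
#' Across-subject (or across-reconstruction) sample variance divided by the
#' across-subject mean in each voxel, all volumes already on one grid. Voxels
#' with low relative variance are candidates for a segmentation-free
#' reference region. Near-zero means give arbitrarily large ratios, so
#' downstream thresholding ranks voxels by the absolute ratio.
#'
#' @param chis list of at least two [susceptibility_volume()]s or arrays on
#'   a common lattice.
#' @return object of class `rv_map` with `values` (ratio, dimensionless) and
#'   `n_inputs`.
#' @export
relative_variance_map <- function(chis) {
  if (length(chis) < 2L) stop("at least 2 volumes are required")
  vals <- lapply(chis, vol_values)
  d <- dim(vals[[1]])
  if (!all(vapply(vals, function(v) identical(dim(v), d), logical(1))))
    stop("all volumes must share one lattice")
  n <- length(vals)
  s1 <- Reduce(`+`, vals)
  s2 <- Reduce(`+`, lapply(vals, function(v) v^2))
  m <- s1 / n
  v <- (s2 - n * m^2) / (n - 1)  # unbiased across-input variance
  structure(list(values = v / m, n_inputs = n), class = "rv_map")
}

#' Low-percentile reference mask
#'
#' Selects in-brain voxels whose absolute map value falls at or below the
#' given percentile of the in-brain absolute-value distribution (linear
#' interpolation between order statistics, the type-7 quantile convention).
#' With a relative-variance map and the default 3rd percentile this yields
#' the data-driven low-variance reference region.
#'
#' @param map an `rv_map` or 3-D array.
#' @param brain_mask logical array.
#' @param percentile percentile in (0, 100], default 3.
#' @return logical 3-D mask.
#' @export
low_percentile_mask <- function(map, brain_mask, percentile = 3) {
  vals <- abs(vol_values(map))
  brain_mask <- as.array(brain_mask)
  if (!identical(dim(brain_mask), dim(vals)))
    stop("brain mask shape does not match the map")
  if (!any(brain_mask)) stop("brain mask is empty")
  if (percentile <= 0 || percentile > 100)
    stop("percentile must lie in (0, 100]")
  vals[!is.finite(vals)] <- Inf  # undefined ratios can never be selected
  inb <- vals[brain_mask]
  thr <- stats::quantile(inb, percentile / 100, names = FALSE, type = 7)
  brain_mask & vals <= thr
}

#' R2* map from a multi-echo series (ARLO estimator)
#'
#' Closed-form mono-exponential R2* fit for equally spaced echoes by
#' auto-regression on linear operations: Simpson-rule integrals over
#' consecutive echo triplets are regressed on the corresponding signal
#' differences, combined by least squares with the noise-consistent
#' cross-term. Negative estimates (noise-driven signal growth) are clipped
#' to 0 Hz. See [fit_r2s_loglin()] for the log-linear cross-check estimator.
#'
#' @param echoes an [echo_series()] (>= 3 equally spaced echoes).
#' @return object of class `r2s_map` with `values` in Hz (>= 0).
#' @export
fit_r2s <- function(echoes) {
  stopifnot(inherits(echoes, "echo_series"))
  d <- dim(echoes$magnitudes)
  ne <- d[4]
  dt <- diff(echoes$echo_times)[1] / 1000  # ms -> s, so rates come out in Hz
  y <- matrix(echoes$magnitudes, ncol = ne)
  nt <- ne - 2L
  Sss <- Ssd <- Sdd <- numeric(nrow(y))
  for (j in seq_len(nt)) {
    s <- (dt / 3) * (y[, j] + 4 * y[, j + 1] + y[, j + 2])
    dd <- y[, j] - y[, j + 2]
    Sss <- Sss + s * s
    Ssd <- Ssd + s * dd
    Sdd <- Sdd + dd * dd
  }
  num <- Sss + (dt / 3) * Ssd
  den <- (dt / 3) * Sdd + Ssd
  t2s <- num / den
  r2s <- numeric(length(t2s))
  ok <- is.finite(t2s) & t2s > 0 & den != 0
  r2s[ok] <- 1 / t2s[ok]
  r2s[r2s < 0] <- 0
  structure(list(values = array(r2s, d[1:3])), class = "r2s_map")
}

#' Log-linear least-squares R2* fit
#'
#' Ordinary least squares of log magnitude on echo time, per voxel. Exact on
#' noiseless mono-exponential data; used as an independent cross-check of
#' the ARLO estimator. Voxels with any nonpositive echo return 0.
#'
#' @param echoes an [echo_series()].
#' @return object of class `r2s_map`, values in Hz (negative clipped to 0).
#' @export
fit_r2s_loglin <- function(echoes) {
  stopifnot(inherits(echoes, "echo_series"))
  d <- dim(echoes$magnitudes)
  te <- echoes$echo_times / 1000  # s
  y <- matrix(echoes$magnitudes, ncol = d[4])
  pos <- rowSums(y <= 0) == 0L
  r2s <- numeric(nrow(y))
  if (any(pos)) {
    ly <- log(y[pos, , drop = FALSE])
    tc <- te - mean(te)
    slope <- as.vector(ly %*% tc) / sum(tc^2)
    r2s[pos] <- pmax(-slope, 0)
  }
  structure(list(values = array(r2s, d[1:3])), class = "r2s_map")
}

#' R2*-threshold reference mask
#'
#' The segmentation-free reference region: in-brain voxels with R2* below a
#' cutoff (default 4 Hz). Low relaxation rates mark fluid-like, weakly
#' susceptible tissue such as CSF, including pockets outside the ventricles
#' that anatomical segmentations miss.
#'
#' @param r2s an `r2s_map` (from [fit_r2s()]) or 3-D array in Hz.
#' @param brain_mask logical array.
#' @param threshold_hz positive cutoff in Hz, default 4.
#' @return logical 3-D mask.
#' @export
r2s_reference_mask <- function(r2s, brain_mask, threshold_hz = 4) {
  if (threshold_hz <= 0) stop("threshold_hz must be positive")
  vals <- vol_values(r2s)
  brain_mask <- as.array(brain_mask)
  if (!identical(dim(brain_mask), dim(vals)))
    stop("brain mask shape does not match the R2* map")
  m <- brain_mask & vals < threshold_hz
  if (!any(m))
    stop("no in-brain voxels with R2* below ", threshold_hz,
         " Hz; raise threshold_hz")
  m
}

#' Subtract a scalar reference value
#'
#' Referencing is a pure shift: every value minus the reference scalar. The
#' distribution shape (and in particular the variance of any fixed voxel
#' set) is unchanged; only means move.
#'
#' @param x numeric vector, 3-D array, or [susceptibility_volume()].
#' @param ref_value finite scalar (ppm).
#' @return same type as `x`, shifted.
#' @export
apply_reference <- function(x, ref_value) {
  if (length(ref_value) != 1L || !is.finite(ref_value))
    stop("ref_value must be a single finite number")
  if (inherits(x, "susceptibility_volume")) {
    x$values <- x$values - ref_value
    x
  } else {
    x - ref_value
  }
}

#' Resolve a referencing strategy to a scalar
#'
#' Computes the reference value a [reference_strategy()] prescribes for one
#' volume, given whatever auxiliary inputs the strategy needs (label map for
#' anatomical regions, a precomputed mask for the data-driven regions).
#'
#' @param chi a [susceptibility_volume()].
#' @param strategy a [reference_strategy()].
#' @param labels [label_map()], required for anatomical strategies.
#' @param region_mask precomputed logical mask, required for
#'   `relative_variance` and `r2s_threshold` strategies (these masks are
#'   shared across volumes / derived from the subject's own R2* map, so the
#'   caller supplies them; see [low_percentile_mask()] and
#'   [r2s_reference_mask()]).
#' @return scalar ppm (0 for kind `"none"`).
#' @export
reference_value <- function(chi, strategy, labels = NULL,
                            region_mask = NULL) {
  stopifnot(inherits(strategy, "reference_strategy"))
  switch(strategy$kind,
    none = 0,
    whole_brain = whole_brain_reference(chi),
    anatomical = {
      if (is.null(labels)) stop("anatomical referencing requires a label map")
      region_reference_value(chi, roi_mask(labels, strategy$roi),
                             stat = strategy$stat)
    },
    relative_variance = ,
    r2s_threshold = {
      if (is.null(region_mask))
        stop("strategy '", strategy$kind, "' requires a precomputed region_mask")
      region_reference_value(chi, region_mask, stat = strategy$stat)
    })
}
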