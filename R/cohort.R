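#' Cohort sampling design
#'
#' Parameters of the generative model for per-subject ROI mean
#' susceptibilities in a multi-group study. For subject \eqn{s} of group
#' \eqn{g} with age \eqn{a_s}, the mean of ROI \eqn{j} is drawn as
#' \deqn{\mu_{g,j} + b_s + \beta (a_s - \bar a) + \epsilon_{s,j}}
#' with a shared per-subject offset \eqn{b_s \sim N(0, \tau^2)} (the
#' inter-subject global-susceptibility shift that referencing is designed to
#' remove), an age trend with slope \eqn{\beta}, and independent ROI noise
#' \eqn{\epsilon_{s,j} \sim N(0, \sigma_j^2)}. A designated reference ROI may
#' additionally carry a group-specific pathology shift — the mechanism by
#' which referencing biases group comparisons.
#'
#' @param group_sizes named integer vector of subjects per group; the default
#'   emulates a temporal-lobe-epilepsy study with 27 healthy controls and 19
#'   left / 17 right TLE patients.
#' @param roi_means numeric matrix (groups x ROIs, dimnames required) of
#'   underlying ROI means in ppm. Defaults to the phantom's nine regions with
#'   identical means in every group (a null design).
#' @param roi_sd named per-ROI between-subject standard deviation (ppm);
#'   a scalar is recycled. Default 0.01 ppm.
#' @param subject_offset_sd \eqn{\tau}, SD of the shared per-subject offset
#'   (ppm). Default 0.005 ppm.
#' @param reference_roi ROI whose mean receives `ref_pathology_shift`.
#' @param ref_pathology_shift named per-group shift (ppm) of the reference
#'   ROI mean; groups not named get 0. Unknown group names are an error.
#' @param age_range,age_slope uniform age range in years and the common
#'   susceptibility-age slope in ppm/year.
#' @param within_sd within-subject (voxelwise) SD reported per ROI (ppm).
#' @param roi_voxels nominal ROI voxel count reported per subject.
#' @param reference_rois ROIs whose per-subject means are also exported as
#'   `ref_<roi>` referencing columns.
#' @param wholebrain_sd SD (ppm) of the residual whole-brain mean around the
#'   subject offset; direct dipole inversions demean the map, so this is
#'   small.
#' @param seed default seed used by [simulate_cohort()].
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(group_sizes = c(HC = 27, LTLE = 19, RTLE = 17),
                          roi_means = NULL,
                          roi_sd = 0.01,
                          subject_offset_sd = 0.005,
                          reference_roi = "csf",
                          ref_pathology_shift = NULL,
                          age_range = c(16, 67),
                          age_slope = 0.001,
                          within_sd = 0.01,
                          roi_voxels = 120L,
                          reference_rois = NULL,
                          wholebrain_sd = 0.001,
                          seed = 1L) {
  if (is.null(names(group_sizes)) || any(group_sizes < 1))
    stop("group_sizes must be a named vector of positive counts")
  groups <- names(group_sizes)
  if (is.null(roi_means)) {
    spec <- default_roi_spec()
    mu <- vapply(spec, function(e) e$chi, numeric(1))
    names(mu) <- vapply(spec, function(e) e$name, character(1))
    roi_means <- matrix(rep(mu, each = length(groups)),
                        nrow = length(groups),
                        dimnames = list(groups, names(mu)))
  }
  if (is.null(dimnames(roi_means)) ||
      !setequal(rownames(roi_means), groups))
    stop("roi_means must have one named row per group")
  roi_means <- roi_means[groups, , drop = FALSE]
  rois <- colnames(roi_means)
  if (length(roi_sd) == 1L) roi_sd <- setNames(rep(roi_sd, length(rois)), rois)
  if (any(roi_sd < 0) || subject_offset_sd < 0 || wholebrain_sd < 0)
    stop("standard deviations must be nonnegative")
  if (!reference_roi %in% rois)
    stop("reference_roi '", reference_roi, "' is not a column of roi_means")
  shift <- setNames(rep(0, length(groups)), groups)
  if (!is.null(ref_pathology_shift)) {
    unknown <- setdiff(names(ref_pathology_shift), groups)
    if (length(unknown))
      stop("ref_pathology_shift names unknown group(s): ",
           paste(unknown, collapse = ", "))
    shift[names(ref_pathology_shift)] <- ref_pathology_shift
  }
  if (is.null(reference_rois))
    reference_rois <- intersect(c("csf", "corpus_callosum",
                                  "internal_capsule"), rois)
  if (length(within_sd) == 1L)
    within_sd <- setNames(rep(within_sd, length(rois)), rois)
  if (length(roi_voxels) == 1L)
    roi_voxels <- setNames(rep(as.integer(roi_voxels), length(rois)), rois)
  structure(list(group_sizes = group_sizes, roi_means = roi_means,
                 roi_sd = roi_sd[rois], subject_offset_sd = subject_offset_sd,
                 reference_roi = reference_roi, ref_pathology_shift = shift,
                 age_range = as.numeric(age_range), age_slope = age_slope,
                 within_sd = within_sd[rois], roi_voxels = roi_voxels[rois],
                 reference_rois = reference_rois,
                 wholebrain_sd = wholebrain_sd, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a cohort of per-subject ROI summaries
#'
#' Draws one subject table from a [cohort_design()]: ages uniform on the
#' design range, a shared per-subject susceptibility offset, independent ROI
#' noise, the reference-ROI pathology shift, and per-strategy reference
#' values. Deterministic given `(design, seed)`.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed; defaults to `design$seed`.
#' @return data.frame with columns `subject_id`, `group`, `age`,
#'   `<roi>_mean`, `<roi>_sd`, `<roi>_n` for every ROI, and referencing
#'   columns `ref_none`, `ref_wholebrain` and `ref_<roi>` for each entry of
#'   `design$reference_rois`. The design is attached as attribute `"design"`.
#' @export
simulate_cohort <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(as.integer(seed))
  groups <- names(design$group_sizes)
  rois <- colnames(design$roi_means)
  mid_age <- mean(design$age_range)
  N <- sum(design$group_sizes)
  grp <- rep(groups, design$group_sizes)
  idx <- unlist(lapply(design$group_sizes, seq_len), use.names = FALSE)
  age <- runif(N, design$age_range[1], design$age_range[2])
  b <- rnorm(N, 0, design$subject_offset_sd)
  trend <- design$age_slope * (age - mid_age)
  out <- data.frame(subject_id = sprintf("%s_%03d", grp, idx),
                    group = factor(grp, levels = groups), age = age,
                    stringsAsFactors = FALSE)
  for (roi in rois) {
    mu <- design$roi_means[grp, roi]
    if (roi == design$reference_roi)
      mu <- mu + design$ref_pathology_shift[grp]
    nv <- design$roi_voxels[[roi]]
    out[[paste0(roi, "_mean")]] <-
      mu + b + trend + rnorm(N, 0, design$roi_sd[[roi]])
    out[[paste0(roi, "_sd")]] <- design$within_sd[[roi]] *
      sqrt(rchisq(N, nv - 1) / (nv - 1))
    out[[paste0(roi, "_n")]] <- nv
  }
  out$ref_none <- 0
  out$ref_wholebrain <- b + trend + rnorm(N, 0, design$wholebrain_sd)
  for (roi in design$reference_rois)
    out[[paste0("ref_", roi)]] <- out[[paste0(roi, "_mean")]]
  rownames(out) <- NULL
  attr(out, "design") <- design
  out
}
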