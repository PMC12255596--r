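#' Susceptibility volume
#'
#' A 3-D scalar lattice of magnetic susceptibility values in parts per million
#' (ppm), together with the voxel size in mm and an optional brain mask.
#' Susceptibility maps reconstructed from MRI phase are relative: any scalar
#' offset is equally valid, which is why reference-region normalization
#' matters downstream.
#'
#' @param values 3-D numeric array of susceptibility in ppm.
#' @param voxel_size length-3 numeric, voxel edge lengths in mm.
#' @param brain_mask optional 3-D logical array of the same shape; voxels
#'   outside it never enter reference regions or ROI statistics.
#' @return An object of class `susceptibility_volume`: a list with elements
#'   `values`, `voxel_size`, `brain_mask`.
#' @export
susceptibility_volume <- function(values, voxel_size = c(1, 1, 1),
                                  brain_mask = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array, got ", length(dim(values)), " dims")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (mm)")
  if (!is.null(brain_mask)) {
    brain_mask <- as.array(brain_mask)
    if (!identical(dim(brain_mask), dim(values)))
      stop("brain_mask shape ", paste(dim(brain_mask), collapse = "x"),
           " does not match values shape ",
           paste(dim(values), collapse = "x"))
    storage.mode(brain_mask) <- "logical"
    if (any(!is.finite(values[brain_mask])))
      stop("non-finite susceptibility values inside the brain mask")
  }
  structure(list(values = values, voxel_size = voxel_size,
                 brain_mask = brain_mask),
            class = "susceptibility_volume")
}

#' @export
print.susceptibility_volume <- function(x, ...) {
  cat("<susceptibility_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size, 3), collapse = "x"), " mm\n",
      sep = "")
  if (!is.null(x$brain_mask))
    cat("  brain mask: ", sum(x$brain_mask), " voxels\n", sep = "")
  rng <- range(x$values)
  cat("  chi range [ppm]: ", signif(rng[1], 4), " .. ", signif(rng[2], 4),
      "\n", sep = "")
  invisible(x)
}

#' Field perturbation volume
#'
#' The relative field shift \eqn{\Delta B} (in ppm of B0) generated by a
#' susceptibility distribution through the dipole convolution.
#'
#' @param values 3-D numeric array, field shift in ppm.
#' @param voxel_size length-3 numeric, mm.
#' @return An object of class `field_volume`.
#' @export
field_volume <- function(values, voxel_size = c(1, 1, 1)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  structure(list(values = values, voxel_size = as.numeric(voxel_size)),
            class = "field_volume")
}

#' Integer label map with a legend
#'
#' Carrier for ROI segmentations: an integer lattice where 0 is background
#' and each nonzero id names a region via the legend.
#'
#' @param labels 3-D integer array; 0 is background.
#' @param legend named character vector or named list mapping id (as name)
#'   to ROI name, e.g. `c("1" = "csf", "2" = "thalamus")`.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, legend) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  storage.mode(labels) <- "integer"
  legend <- unlist(legend)
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0L]
  missing <- setdiff(as.character(ids), names(legend))
  if (length(missing))
    stop("labels present without a legend entry: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, legend = legend), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$labels), collapse = " x "), " voxels, ",
      length(x$legend), " regions\n", sep = "")
  for (id in names(x$legend))
    cat(sprintf("  %3s %-18s %d voxels\n", id, x$legend[[id]],
                sum(x$labels == as.integer(id))))
  invisible(x)
}

#' Extract a logical ROI mask from a label map
#'
#' @param map a `label_map`.
#' @param roi ROI name (looked up in the legend) or integer id.
#' @return 3-D logical array.
#' @export
roi_mask <- function(map, roi) {
  stopifnot(inherits(map, "label_map"))
  if (is.character(roi)) {
    hit <- names(map$legend)[map$legend == roi]
    if (!length(hit)) stop("ROI '", roi, "' not found in legend")
    id <- as.integer(hit[1])
  } else {
    id <- as.integer(roi)
  }
  map$labels == id
}

#' Multi-echo magnitude series
#'
#' 4-D magnitude data over echoes with their echo times, the input to R2*
#' relaxometry. The closed-form ARLO fit requires at least three equally
#' spaced echoes.
#'
#' @param magnitudes 4-D nonnegative array, last axis indexes echoes.
#' @param echo_times strictly increasing, equally spaced echo times in ms.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(magnitudes, echo_times) {
  magnitudes <- as.array(magnitudes)
  if (length(dim(magnitudes)) != 4L)
    stop("`magnitudes` must be a 4-D array (x, y, z, echo)")
  echo_times <- as.numeric(echo_times)
  ne <- length(echo_times)
  if (ne < 3L) stop("at least 3 echoes are required, got ", ne)
  if (dim(magnitudes)[4] != ne)
    stop("number of echoes (", dim(magnitudes)[4],
         ") does not match echo_times (", ne, ")")
  d <- diff(echo_times)
  if (any(d <= 0)) stop("echo_times must be strictly increasing")
  if (any(abs(d - d[1]) > 1e-6 * d[1]))
    stop("echo_times must be equally spaced (required by the ARLO fit)")
  if (any(magnitudes < 0)) stop("magnitudes must be nonnegative")
  structure(list(magnitudes = magnitudes, echo_times = echo_times),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  cat("<echo_series> ", paste(dim(x$magnitudes)[1:3], collapse = " x "),
      " voxels, ", length(x$echo_times), " echoes (",
      paste(signif(x$echo_times, 4), collapse = ", "), " ms)\n", sep = "")
  invisible(x)
}

# shared internal: pull the 3-D array out of a volume-or-array argument
vol_values <- function(x) {
  if (inherits(x, c("susceptibility_volume", "field_volume", "r2s_map",
                    "rv_map")))
    x$values
  else as.array(x)
}
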