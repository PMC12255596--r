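#' Default phantom ROI geometry
#'
#' Nine spherical test regions named after the deep grey-matter, white-matter
#' and CSF structures routinely compared in clinical susceptibility studies:
#' CSF, corpus callosum, internal capsule, amygdala, caudate, pallidum,
#' putamen, thalamus and hippocampus. Susceptibility values are
#' literature-plausible ppm offsets relative to CSF; R2* values (Hz) give the
#' CSF compartment fluid-like relaxation and iron-rich nuclei fast decay.
#'
#' @param lattice_shape length-3 integer lattice size the geometry is scaled
#'   against (defaults assume 48^3).
#' @return a list of geometry entries, each a list with `name`, `type`,
#'   `center`, `radius`, `chi` (ppm) and `r2s` (Hz).
#' @export
default_roi_spec <- function(lattice_shape = c(48, 48, 48)) {
  s <- lattice_shape / 48  # scale reference layout to requested lattice
  sph <- function(name, center, radius, chi, r2s)
    list(name = name, type = "sphere", center = center * s,
         radius = radius * min(s), chi = chi, r2s = r2s)
  list(
    sph("csf",              c(24, 24, 24), 4, 0.000,  1),
    sph("corpus_callosum",  c(24, 33, 24), 3, -0.030, 45),
    sph("internal_capsule", c(24, 15, 24), 3, -0.015, 40),
    sph("amygdala",         c(14, 24, 20), 3, 0.005,  25),
    sph("caudate",          c(34, 24, 20), 3, 0.055,  35),
    sph("pallidum",         c(14, 24, 28), 3, 0.130,  60),
    sph("putamen",          c(34, 24, 28), 3, 0.045,  40),
    sph("thalamus",         c(24, 24, 33), 3, 0.010,  30),
    sph("hippocampus",      c(24, 24, 15), 3, 0.005,  25)
  )
}

geometry_mask <- function(entry, lattice_shape) {
  d <- lattice_shape
  ix <- slice.index(array(0, d), 1)
  iy <- slice.index(array(0, d), 2)
  iz <- slice.index(array(0, d), 3)
  c0 <- entry$center
  m <- switch(entry$type,
    sphere = {
      r <- entry$radius
      (ix - c0[1])^2 + (iy - c0[2])^2 + (iz - c0[3])^2 <= r^2
    },
    ellipsoid = {
      ax <- entry$semiaxes
      ((ix - c0[1]) / ax[1])^2 + ((iy - c0[2]) / ax[2])^2 +
        ((iz - c0[3]) / ax[3])^2 <= 1
    },
    box = {
      h <- entry$halfwidths
      abs(ix - c0[1]) <= h[1] & abs(iy - c0[2]) <= h[2] &
        abs(iz - c0[3]) <= h[3]
    },
    stop("unknown geometry type '", entry$type, "'")
  )
  ext <- switch(entry$type,
                sphere = rep(entry$radius, 3),
                ellipsoid = entry$semiaxes,
                box = entry$halfwidths)
  if (any(c0 - ext < 1) || any(c0 + ext > d))
    stop("geometry '", entry$name, "' extends outside the lattice")
  m
}

#' Build a piecewise-constant susceptibility phantom
#'
#' Constructs a parametric phantom (disjoint spheres/ellipsoids/boxes inside
#' an ellipsoidal "brain") with exactly known per-ROI susceptibility, the
#' stand-in for a realistic ground-truth dataset in all simulation studies
#' here. Because the ROIs are piecewise constant, their true means are known
#' by construction.
#'
#' @param lattice_shape length-3 integer lattice size.
#' @param roi_spec list of geometry entries as in [default_roi_spec()].
#' @param voxel_size length-3 voxel size in mm.
#' @param background_chi susceptibility of brain tissue outside any ROI (ppm).
#' @param brain_semiaxes ellipsoid semiaxes of the brain mask in voxels
#'   (default 42/46/38 percent of the lattice extent).
#' @return list with `chi` (a [susceptibility_volume()] carrying the brain
#'   mask) and `labels` (a [label_map()] whose legend covers every ROI).
#' @export
build_phantom <- function(lattice_shape = c(48, 48, 48),
                          roi_spec = default_roi_spec(lattice_shape),
                          voxel_size = c(1, 1, 1),
                          background_chi = 0,
                          brain_semiaxes = NULL) {
  d <- as.integer(lattice_shape)
  stopifnot(length(d) == 3L, all(d >= 8))
  if (is.null(brain_semiaxes))
    brain_semiaxes <- c(0.42, 0.46, 0.38) * d
  center <- (d + 1) / 2
  brain <- geometry_mask(list(name = "brain", type = "ellipsoid",
                              center = center, semiaxes = brain_semiaxes), d)
  labels <- array(0L, d)
  chi <- array(0, d)
  chi[brain] <- background_chi
  legend <- character(0)
  for (i in seq_along(roi_spec)) {
    entry <- roi_spec[[i]]
    m <- geometry_mask(entry, d)
    if (!any(m)) stop("geometry '", entry$name, "' contains no voxels")
    if (any(labels[m] != 0L))
      stop("geometry '", entry$name, "' overlaps ROI '",
           legend[as.character(labels[m][labels[m] != 0L][1])], "'")
    if (any(!brain[m]))
      stop("geometry '", entry$name, "' extends outside the brain mask")
    labels[m] <- i
    chi[m] <- entry$chi
    legend[as.character(i)] <- entry$name
  }
  list(chi = susceptibility_volume(chi, voxel_size, brain_mask = brain),
       labels = label_map(labels, legend))
}

#' Map per-ROI relaxation rates onto a phantom label map
#'
#' @param labels a [label_map()].
#' @param roi_spec geometry list carrying `r2s` entries (Hz).
#' @param brain_mask logical array; tissue not covered by an ROI gets
#'   `background_hz`, voxels outside the brain get 0.
#' @param background_hz R2* of unlabeled brain tissue (Hz).
#' @return 3-D numeric array of R2* in Hz.
#' @export
phantom_r2s <- function(labels, roi_spec, brain_mask, background_hz = 20) {
  r2s <- array(0, dim(labels$labels))
  r2s[brain_mask] <- background_hz
  for (i in seq_along(roi_spec))
    r2s[labels$labels == i] <- roi_spec[[i]]$r2s
  r2s
}

#' Discrete dipole kernel
#'
#' The k-space dipole kernel \eqn{D(k) = 1/3 - k_{B0}^2/|k|^2} that links
#' susceptibility to field shift. Its zero at the k-space origin makes the
#' map's global mean (DC offset) unobservable, which is the root cause of the
#' referencing problem; the conical zero surface makes the inversion
#' ill-posed.
#'
#' @param lattice_shape length-3 integer lattice size.
#' @param voxel_size length-3 voxel size in mm.
#' @param b0_axis index (1-3) of the main-field axis; defaults to the third.
#' @return object of class `dipole_kernel` with `values` (all in
#'   \eqn{[-2/3, 1/3]}, exactly 0 at zero frequency) and `b0_axis`.
#' @export
dipole_kernel <- function(lattice_shape, voxel_size = c(1, 1, 1),
                          b0_axis = 3L) {
  d <- as.integer(lattice_shape)
  stopifnot(length(d) == 3L, all(d >= 1), all(voxel_size > 0))
  b0_axis <- as.integer(b0_axis)
  if (!b0_axis %in% 1:3) stop("b0_axis must be 1, 2 or 3")
  if (d[b0_axis] == 1L)
    stop("lattice is degenerate (size 1) along the B0 axis")
  f <- lapply(1:3, function(a) fft_freq(d[a], voxel_size[a]))
  K1 <- array(f[[1]], d)
  K2 <- array(rep(f[[2]], each = d[1]), d)
  K3 <- array(rep(f[[3]], each = d[1] * d[2]), d)
  k2 <- K1^2 + K2^2 + K3^2
  kb <- list(K1, K2, K3)[[b0_axis]]
  D <- 1 / 3 - kb^2 / k2
  D[k2 == 0] <- 0
  structure(list(values = D, b0_axis = b0_axis,
                 voxel_size = as.numeric(voxel_size)),
            class = "dipole_kernel")
}

#' Dipole forward model: susceptibility to field shift
#'
#' Computes the relative field perturbation as the spectral product of the
#' susceptibility distribution with the dipole kernel (circular convolution).
#' Because the kernel annihilates the zero-frequency component, the output
#' field always has zero lattice mean, regardless of any constant offset in
#' the input.
#'
#' @param chi a [susceptibility_volume()].
#' @param kernel a [dipole_kernel()] on the same lattice.
#' @return a [field_volume()] in ppm.
#' @export
forward_field <- function(chi, kernel) {
  stopifnot(inherits(chi, "susceptibility_volume"),
            inherits(kernel, "dipole_kernel"))
  if (!identical(dim(chi$values), dim(kernel$values)))
    stop("susceptibility and kernel lattice shapes differ")
  F <- fft(chi$values) * kernel$values
  field <- Re(fft(F, inverse = TRUE)) / prod(dim(chi$values))
  field_volume(field, chi$voxel_size)
}

#' Dipole inversion by thresholded k-space division or Tikhonov
#'
#' Direct single-step inversions of the dipole forward model, used as
#' reconstruction emulators with method-specific bias:
#' \describe{
#'   \item{tkd}{thresholded k-space division: divide the field spectrum by
#'     the kernel, replacing kernel values with magnitude below `delta` by
#'     `sign(D) * delta` (sign 0 treated as +).}
#'   \item{tikhonov}{direct Tikhonov-regularized inversion:
#'     \eqn{\hat\chi(k) = D \Delta B(k) / (D^2 + \lambda)}.}
#' }
#' Both leave the DC component at 0, so reconstructed maps have (close to)
#' zero lattice mean — the implicit whole-volume referencing of direct
#' inversions.
#'
#' @param field a [field_volume()].
#' @param kernel matching [dipole_kernel()].
#' @param method `"tkd"` or `"tikhonov"`.
#' @param delta TKD truncation threshold (> 0), default 0.2.
#' @param lambda Tikhonov regularization weight (> 0), default 0.05.
#' @param brain_mask optional logical array attached to the output.
#' @return a [susceptibility_volume()].
#' @export
reconstruct <- function(field, kernel, method = c("tkd", "tikhonov"),
                        delta = 0.2, lambda = 0.05, brain_mask = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(field, "field_volume"),
            inherits(kernel, "dipole_kernel"))
  if (!identical(dim(field$values), dim(kernel$values)))
    stop("field and kernel lattice shapes differ")
  D <- kernel$values
  F <- fft(field$values)
  spec <- if (method == "tkd") {
    if (delta <= 0)
      stop("tkd with delta = 0 is an undefined inverse at the kernel zeros")
    Dt <- ifelse(abs(D) < delta, ifelse(D < 0, -delta, delta), D)
    F / Dt
  } else {
    if (lambda <= 0)
      stop("tikhonov with lambda = 0 is an undefined inverse at the kernel zeros")
    D * F / (D^2 + lambda)
  }
  chi <- Re(fft(spec, inverse = TRUE)) / prod(dim(D))
  susceptibility_volume(chi, field$voxel_size, brain_mask = brain_mask)
}

#' Simulate a multi-echo gradient-echo magnitude series
#'
#' Mono-exponential decay `m0 * exp(-R2* * TE)` per voxel plus optional
#' Gaussian noise on the magnitude, clipped at zero. Gaussian (rather than
#' Rician) noise is a deliberate simplification appropriate at the
#' signal-to-noise ratios simulated here.
#'
#' @param m0 3-D array of echo-time-zero magnitudes (arbitrary units).
#' @param r2s_map 3-D array of R2* in Hz (nonnegative).
#' @param echo_times equally spaced echo times in ms.
#' @param noise_sd Gaussian noise standard deviation (same units as `m0`).
#' @param seed optional integer seed; the same seed gives a bit-identical
#'   series.
#' @return an [echo_series()].
#' @export
simulate_echoes <- function(m0, r2s_map, echo_times, noise_sd = 0,
                            seed = NULL) {
  m0 <- as.array(m0); r2s_map <- as.array(r2s_map)
  stopifnot(identical(dim(m0), dim(r2s_map)))
  if (any(r2s_map < 0)) stop("r2s_map must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ne <- length(echo_times)
  mag <- array(0, c(dim(m0), ne))
  for (e in seq_len(ne)) {
    s <- m0 * exp(-r2s_map * echo_times[e] / 1000)  # Hz * ms -> /1000
    if (noise_sd > 0) s <- s + rnorm(length(s), 0, noise_sd)
    mag[, , , e] <- pmax(s, 0)
  }
  echo_series(mag, echo_times)
}
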