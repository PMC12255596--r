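# Discrete FFT frequency coordinates (cycles per mm), unshifted ordering:
# 0, 1, ..., floor((n-1)/2), -floor(n/2), ..., -1, each over n*d.
fft_freq <- function(n, d = 1) {
  c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L)) / (n * d)
}

# Shift a 3-D logical/numeric array by one voxel along `axis` in direction
# `dir` (+1/-1), padding with `fill`. Used by the morphological erosion.
shift_array <- function(a, axis, dir, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (dir > 0) {
    idx_dst[[axis]] <- 2:d[axis]
    idx_src[[axis]] <- 1:(d[axis] - 1L)
  } else {
    idx_dst[[axis]] <- 1:(d[axis] - 1L)
    idx_src[[axis]] <- 2:d[axis]
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Gaussian smoothing of a 3-D lattice
#'
#' Periodic (FFT-based) Gaussian convolution, used to soften piecewise
#' constant phantoms before dipole inversion fixtures.
#'
#' @param values 3-D numeric array.
#' @param sigma_vox Gaussian standard deviation in voxels.
#' @return smoothed array of the same shape.
#' @export
smooth_volume <- function(values, sigma_vox = 1) {
  values <- as.array(values)
  d <- dim(values)
  stopifnot(length(d) == 3L, sigma_vox >= 0)
  if (sigma_vox == 0) return(values)
  g <- lapply(d, function(n) {
    f <- fft_freq(n)
    exp(-2 * pi^2 * sigma_vox^2 * f^2)  # FT of a unit-integral Gaussian
  })
  K <- outer(outer(g[[1]], g[[2]]), g[[3]])
  dim(K) <- d
  Re(fft(fft(values) * K, inverse = TRUE)) / prod(d)
}
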