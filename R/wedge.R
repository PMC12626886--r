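#' Missing-wedge model
#'
#' Single-tilt-axis acquisition geometry. The tilt axis is the volume's
#' second axis; a Fourier component is inside the missing wedge iff the
#' angle between its projection onto the (axis1, axis3) plane and the
#' axis3 direction falls outside `[tilt_min, tilt_max]`.
#'
#' @param tilt_min,tilt_max tilt range in degrees, `-90 < tilt_min <
#'   tilt_max < 90`. A range of `(-90, 90)` means full sampling (no wedge).
#' @return An object of class `"wedge_model"`.
#' @examples
#' w <- wedge_model(-60, 60)
#' @export
wedge_model <- function(tilt_min = -60, tilt_max = 60) {
  stopifnot(is.numeric(tilt_min), is.numeric(tilt_max))
  if (!(tilt_min > -90 && tilt_min < tilt_max && tilt_max < 90) &&
      !(tilt_min == -90 && tilt_max == 90)) {
    stop("wedge_model(): need -90 < tilt_min < tilt_max < 90 (or exactly (-90, 90) for no wedge)")
  }
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max), class = "wedge_model")
}

is_full_range <- function(w) w$tilt_min <= -90 && w$tilt_max >= 90

#' Binary wedge sampling mask in Fourier space
#'
#' Returns a logical/numeric array on the unshifted FFT grid of a cubic
#' volume of size `n`: 1 where a Fourier component is sampled, 0 inside the
#' missing wedge. The zero-frequency column along the tilt axis is always
#' sampled.
#'
#' @param n cubic grid size.
#' @param wedge a [wedge_model()].
#' @return `n x n x n` numeric array of 0/1.
#' @export
wedge_mask <- function(n, wedge) {
  stopifnot(inherits(wedge, "wedge_model"))
  if (is_full_range(wedge)) return(array(1, c(n, n, n)))
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  kx <- array(rep(k, times = n * n), c(n, n, n))
  kz <- array(rep(k, each = n * n), c(n, n, n))
  ang <- atan2(kx, kz) * 180 / pi
  # Fold to (-90, 90]: k and -k carry the same information (Hermitian grid).
  ang[ang > 90] <- ang[ang > 90] - 180
  ang[ang <= -90] <- ang[ang <= -90] + 180
  m <- !(ang > wedge$tilt_max | ang < wedge$tilt_min)
  array(as.numeric(m), c(n, n, n))
}

#' Apply a missing wedge to a volume
#'
#' Zeroes Fourier components inside the missing wedge and returns the
#' degraded real-space volume. Total Fourier power never increases.
#'
#' @param vol a cubic [density_volume()].
#' @param wedge a [wedge_model()].
#' @return Degraded [density_volume()].
#' @export
apply_wedge <- function(vol, wedge) {
  require_cubic(vol, "apply_wedge")
  if (is_full_range(wedge)) return(vol)
  n <- dim(vol$grid)[1]
  m <- wedge_mask(n, wedge)
  g <- Re(fft(fft(vol$grid) * m, inverse = TRUE)) / n^3
  density_volume(array(g, dim(vol$grid)), vol$voxel_size, vol$origin)
}

# Wedge sampling mask rotated by rotation matrix Q (applied to the mask
# geometry), returned on the unshifted FFT grid as continuous weights in
# [0, 1] (trilinear interpolation of the binary mask in centred order).
rotated_wedge_mask <- function(n, wedge, Q) {
  m <- wedge_mask(n, wedge)
  if (is_full_range(wedge)) return(m)
  ms <- fftshift3(m)
  g <- cpp_affine_sample(as.numeric(ms), dim(ms), t(Q), c(0, 0, 0))
  r <- ifftshift3(array(g, dim(ms)))
  r[r < 0] <- 0
  r[r > 1] <- 1
  r
}
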