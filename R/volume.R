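#' Density volume
#'
#' A 3D intensity grid with a physical voxel size (isotropic, Angstrom) and
#' an origin giving the physical position of the centre of voxel (1,1,1).
#' This is the common currency of subtomogram averaging, FSC resolution
#' estimation and EM-fit scoring.
#'
#' @param grid 3D numeric array.
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param origin physical position (Angstrom) of the centre of the first
#'   voxel. The default centres the grid on the physical origin.
#' @return An object of class `"density_volume"`.
#' @examples
#' v <- density_volume(array(rnorm(8^3), c(8, 8, 8)), voxel_size = 4)
#' dim(v$grid)
#' @export
density_volume <- function(grid, voxel_size = 1,
                           origin = -(dim(grid) - 1) / 2 * voxel_size) {
  grid <- as.array(grid)
  stopifnot(length(dim(grid)) == 3, is.numeric(voxel_size),
            voxel_size > 0, length(origin) == 3)
  if (!all(is.finite(grid))) stop("density_volume(): grid contains non-finite values")
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_volume> %d x %d x %d, voxel %.4g A, origin (%.4g, %.4g, %.4g) A\n",
              d[1], d[2], d[3], x$voxel_size, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

is_cubic <- function(vol) {
  d <- dim(vol$grid)
  d[1] == d[2] && d[2] == d[3]
}

require_cubic <- function(vol, what) {
  if (!is_cubic(vol)) stop(sprintf("%s requires a cubic grid, got %s",
                                   what, paste(dim(vol$grid), collapse = "x")))
  invisible(vol)
}

check_same_grid <- function(a, b, what) {
  if (!identical(dim(a$grid), dim(b$grid))) {
    stop(sprintf("%s: grid dimensions differ (%s vs %s)", what,
                 paste(dim(a$grid), collapse = "x"),
                 paste(dim(b$grid), collapse = "x")))
  }
  if (abs(a$voxel_size - b$voxel_size) > 1e-6 * a$voxel_size) {
    stop(sprintf("%s: voxel sizes differ", what))
  }
  invisible(NULL)
}

#' Apply a rigid transform to a volume
#'
#' Resamples `vol` so that a feature at physical position `x` moves to
#' `R x + t` (rotation about the grid's geometric centre). Trilinear
#' interpolation; samples falling outside the grid are zero.
#'
#' @param vol a [density_volume()].
#' @param p a [pose()]; `p$shift` is in Angstrom.
#' @param inverse apply the inverse transform instead.
#' @return A transformed [density_volume()].
#' @export
transform_volume <- function(vol, p, inverse = FALSE) {
  stopifnot(inherits(vol, "density_volume"), inherits(p, "pose"))
  t_vox <- p$shift / vol$voxel_size
  if (inverse) {
    A <- p$rotation
    b <- t_vox
  } else {
    A <- t(p$rotation)
    b <- -as.numeric(t(p$rotation) %*% t_vox)
  }
  g <- cpp_affine_sample(as.numeric(vol$grid), dim(vol$grid), A, b)
  density_volume(array(g, dim(vol$grid)), vol$voxel_size, vol$origin)
}

#' Rotate a volume about its centre
#'
#' @param vol a [density_volume()].
#' @param rotation 3x3 rotation matrix.
#' @return The rotated volume.
#' @export
rotate_volume <- function(vol, rotation) {
  transform_volume(vol, pose(rotation, c(0, 0, 0)))
}

#' Voxelwise Pearson correlation of two volumes
#'
#' @param a,b volumes on identical grids.
#' @return Correlation coefficient.
#' @export
volume_correlation <- function(a, b) {
  check_same_grid(a, b, "volume_correlation")
  stats::cor(as.numeric(a$grid), as.numeric(b$grid))
}

# Physical coordinates (Angstrom) of the grid centre-of-rotation.
volume_centre <- function(vol) {
  vol$origin + (dim(vol$grid) - 1) / 2 * vol$voxel_size
}

# Convert physical Angstrom coordinates (rows of a matrix) to 0-based voxel
# coordinates of `vol`.
phys_to_voxel <- function(vol, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  sweep(xyz, 2, vol$origin, "-") / vol$voxel_size
}

#' Gaussian low-pass filter a volume
#'
#' Soft Fourier-space Gaussian rolloff with half-amplitude near the cutoff;
#' used for the fixed per-iteration low-pass schedule of
#' [iterative_refine()].
#'
#' @param vol a [density_volume()].
#' @param cutoff resolution cutoff in Angstrom (features finer than this are
#'   suppressed). `Inf` returns the input unchanged.
#' @return Filtered volume.
#' @export
lowpass_volume <- function(vol, cutoff) {
  if (!is.finite(cutoff)) return(vol)
  stopifnot(cutoff > 0)
  d <- dim(vol$grid)
  f2 <- freq_radius_sq(d, vol$voxel_size)
  fc <- 1 / cutoff
  filt <- exp(-f2 / (2 * (fc / sqrt(2 * log(2)))^2))
  g <- Re(fft(fft(vol$grid) * filt, inverse = TRUE)) / prod(d)
  density_volume(array(g, d), vol$voxel_size, vol$origin)
}

# Squared spatial frequency (1/A^2) on the unshifted FFT grid.
freq_radius_sq <- function(d, voxel_size) {
  fr <- function(n) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
    if (n == 1) k <- 0
    k / (n * voxel_size)
  }
  fx <- fr(d[1]); fy <- fr(d[2]); fz <- fr(d[3])
  outer(outer(fx^2, fy^2, "+"), fz^2, "+")
}

# Per-axis FFT frequencies in 1/A (unshifted order).
fft_freqs <- function(n, voxel_size) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n == 1) k <- 0
  k / (n * voxel_size)
}

#' Bin a volume by integer Fourier cropping
#'
#' Crops the Fourier transform to the central `n/factor` cube and inverse
#' transforms, matching the usual cryo-ET binning convention (a factor-4
#' binning of a 2.176 A pixel gives 8.704 A).
#'
#' @param vol a cubic [density_volume()].
#' @param factor integer binning factor; must divide the grid size.
#' @return Binned volume with voxel size multiplied by `factor`.
#' @export
bin_volume <- function(vol, factor) {
  require_cubic(vol, "bin_volume")
  n <- dim(vol$grid)[1]
  factor <- as.integer(factor)
  stopifnot(factor >= 1, n %% factor == 0)
  if (factor == 1) return(vol)
  m <- n %/% factor
  F <- fft(vol$grid)
  Fs <- fftshift3(F)
  lo <- (n - m) %/% 2 + 1
  Fc <- Fs[lo:(lo + m - 1), lo:(lo + m - 1), lo:(lo + m - 1)]
  g <- Re(fft(ifftshift3(Fc), inverse = TRUE)) / n^3
  density_volume(array(g, c(m, m, m)), vol$voxel_size * factor, vol$origin)
}

fftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) ((0:(n - 1)) + floor(n / 2)) %% n + 1)
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

ifftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) ((0:(n - 1)) + ceiling(n / 2)) %% n + 1)
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
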