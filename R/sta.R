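#' Angular search grids
#'
#' `angular_grid_zyz` enumerates a uniform grid over intrinsic ZYZ Euler
#' angles with the given step (phi, psi over [0, 360), theta over [0, 180]);
#' `angular_grid_inplane` enumerates rotations about the pore (third) axis
#' only, the grid used for spoke alignment after the pore axis is fixed.
#' Grids are returned in a fixed deterministic order; alignment ties are
#' broken by the first-encountered pose.
#'
#' @param step angular step in degrees.
#' @return List of 3x3 rotation matrices.
#' @export
angular_grid_inplane <- function(step) {
  stopifnot(step > 0)
  lapply(seq(0, 360 - step, by = step), rot_z)
}

#' @rdname angular_grid_inplane
#' @export
angular_grid_zyz <- function(step) {
  stopifnot(step > 0)
  grid <- list()
  for (theta in seq(0, 180, by = step)) {
    for (phi in seq(0, 360 - step, by = step)) {
      for (psi in seq(0, 360 - step, by = step)) {
        grid[[length(grid) + 1]] <- rot_zyz(phi, theta, psi)
        if (theta %in% c(0, 180)) break  # phi and psi degenerate at the poles
      }
      if (theta %in% c(0, 180) && phi > 0) break
    }
  }
  grid
}

#' Align a subtomogram to a reference
#'
#' Exhaustive search over a rotation grid with FFT-based translational
#' search: for each candidate rotation the reference is rotated, degraded by
#' the particle's missing wedge, mean/variance-normalized under the
#' real-space mask, and cross-correlated with the (equally normalized)
#' particle. The returned pose maximizes this constrained cross-correlation;
#' applying it to the reference reproduces the particle's orientation
#' (`particle ~ reference` transformed by `pose`).
#'
#' @param particle,reference cubic [density_volume()]s on identical grids.
#' @param mask real-space mask volume with values in `[0, 1]`, or `NULL`
#'   for no mask.
#' @param wedge the particle's [wedge_model()].
#' @param rotations list of candidate rotation matrices (e.g. from
#'   [angular_grid_inplane()]), or `NULL` to build a ZYZ grid from
#'   `angular_step`.
#' @param angular_step grid step in degrees when `rotations` is `NULL`.
#' @param shift_limit maximum translation searched, Angstrom; must not
#'   exceed half the box.
#' @return An alignment result: `list(pose, cc_score, on_grid)`.
#' @export
align_subtomogram <- function(particle, reference, mask = NULL,
                              wedge = wedge_model(-90, 90),
                              rotations = NULL, angular_step = 30,
                              shift_limit = 0) {
  check_same_grid(particle, reference, "align_subtomogram")
  require_cubic(particle, "align_subtomogram")
  n <- dim(particle$grid)[1]
  if (is.null(mask)) {
    mask_arr <- array(1, dim(particle$grid))
  } else {
    check_same_grid(particle, mask, "align_subtomogram")
    mask_arr <- mask$grid
    if (min(mask_arr) < 0 || max(mask_arr) > 1) {
      stop("align_subtomogram(): mask values must lie in [0, 1]")
    }
    if (sum(mask_arr) == 0) stop("align_subtomogram(): mask is empty")
  }
  half_box <- n * particle$voxel_size / 2
  if (shift_limit > half_box) {
    stop(sprintf("align_subtomogram(): shift_limit %g A exceeds half-box %g A",
                 shift_limit, half_box))
  }
  if (is.null(rotations)) rotations <- angular_grid_zyz(angular_step)
  wmask <- wedge_mask(n, wedge)

  b <- normalize_under_mask(particle$grid, mask_arr)
  Fb <- fft(b)
  s_max <- floor(shift_limit / particle$voxel_size)
  shift_ok <- shift_index_mask(n, s_max)

  unmasked <- is.null(mask)
  best <- list(cc = -Inf, idx = NA_integer_, shift = c(0, 0, 0))
  for (ri in seq_along(rotations)) {
    R <- rotations[[ri]]
    refR <- rotate_volume(reference, R)$grid
    if (unmasked) {
      # With a trivial mask, mean subtraction is zeroing the DC term and
      # the norm follows from Parseval — no round trip to real space.
      Fa <- fft(refR) * wmask
      Fa[1] <- 0
      na <- sqrt(sum(Mod(Fa)^2) / n^3)
      if (na == 0) next
      Fa <- Fa / na
    } else {
      refW <- Re(fft(fft(refR) * wmask, inverse = TRUE)) / n^3
      Fa <- fft(normalize_under_mask(refW, mask_arr))
    }
    if (s_max == 0) {
      cc <- Re(sum(Conj(Fa) * Fb)) / n^3
      if (cc > best$cc + 1e-12) best <- list(cc = cc, idx = ri, shift = c(0, 0, 0))
    } else {
      cc_map <- Re(fft(Conj(Fa) * Fb, inverse = TRUE)) / n^3
      cc_map[!shift_ok] <- -Inf
      j <- which.max(cc_map)
      if (cc_map[j] > best$cc + 1e-12) {
        ijk <- arrayInd(j, dim(cc_map)) - 1L
        sh <- ifelse(ijk > n / 2, ijk - n, ijk)
        best <- list(cc = cc_map[j], idx = ri, shift = as.numeric(sh))
      }
    }
  }
  list(pose = pose(rotations[[best$idx]],
                   best$shift * particle$voxel_size),
       cc_score = max(-1, min(1, best$cc)),
       on_grid = TRUE)
}

# Subtract the mean under the mask, apply the mask, scale to unit L2 norm.
normalize_under_mask <- function(grid, mask_arr) {
  w <- sum(mask_arr)
  mu <- sum(grid * mask_arr) / w
  a <- (grid - mu) * mask_arr
  nrm <- sqrt(sum(a^2))
  if (nrm == 0) a else a / nrm
}

shift_index_mask <- function(n, s_max) {
  k <- 0:(n - 1)
  sh <- ifelse(k > n / 2, k - n, k)
  ok <- abs(sh) <= s_max
  outer(outer(ok, ok, "&"), ok, "&")
}

#' Wedge-compensated subtomogram averaging
#'
#' Each particle is mapped back to the reference frame by the inverse of
#' its pose; the average is the sum of aligned Fourier terms divided by the
#' sum of (rotated) wedge sampling masks, with the divisor floored at one
#' sample. Fourier voxels covered by no particle are set to zero.
#'
#' @param particles list of cubic [density_volume()]s, or the particle
#'   records from [simulate_particles()] (their `$subtomogram` and `$wedge`
#'   are used).
#' @param poses list of [pose()]s mapping the reference into each particle.
#' @param wedges list of [wedge_model()]s, a single model recycled for all
#'   particles, or `NULL` to take wedges from the particle records.
#' @return The averaged [density_volume()].
#' @export
average_subtomograms <- function(particles, poses, wedges = NULL) {
  stopifnot(length(particles) >= 1, length(particles) == length(poses))
  vols <- lapply(particles, function(p) {
    if (inherits(p, "density_volume")) p else p$subtomogram
  })
  if (is.null(wedges)) {
    wedges <- lapply(particles, function(p) {
      if (inherits(p, "density_volume")) wedge_model(-90, 90) else p$wedge
    })
  } else if (inherits(wedges, "wedge_model")) {
    wedges <- rep(list(wedges), length(particles))
  }
  require_cubic(vols[[1]], "average_subtomograms")
  n <- dim(vols[[1]]$grid)[1]
  Fsum <- array(complex(real = 0, imaginary = 0), rep(n, 3))
  Wsum <- array(0, rep(n, 3))
  for (i in seq_along(vols)) {
    check_same_grid(vols[[1]], vols[[i]], "average_subtomograms")
    aligned <- transform_volume(vols[[i]], poses[[i]], inverse = TRUE)
    Fsum <- Fsum + fft(aligned$grid)
    Wsum <- Wsum + rotated_wedge_mask(n, wedges[[i]], t(poses[[i]]$rotation))
  }
  Favg <- Fsum / pmax(Wsum, 1)
  Favg[Wsum < 0.5] <- 0
  g <- Re(fft(Favg, inverse = TRUE)) / n^3
  density_volume(array(g, rep(n, 3)), vols[[1]]$voxel_size, vols[[1]]$origin)
}

#' Expand a whole-pore pose into symmetry-related spoke poses
#'
#' Given the pose of a whole C_n-symmetric pore, returns the `order` spoke
#' coordinates and orientations related by successive rotations of
#' `360/order` degrees about the pore axis (the third axis of the whole
#' pose's rotation frame).
#'
#' @param whole_pose the pore's [pose()].
#' @param whole_centre pore centre in the lab frame, Angstrom.
#' @param order symmetry order (default 8).
#' @param spoke_radius spoke anchor distance from the pore axis, Angstrom.
#' @return List of `order` entries `list(position, pose)`.
#' @export
symmetry_expand <- function(whole_pose, whole_centre = c(0, 0, 0), order = 8,
                            spoke_radius = 0) {
  stopifnot(inherits(whole_pose, "pose"), order >= 1)
  Rw <- whole_pose$rotation
  centre <- as.numeric(whole_centre) + whole_pose$shift
  lapply(0:(order - 1), function(k) {
    Rk <- Rw %*% rot_z(k * 360 / order)
    posk <- centre + as.numeric(Rk %*% c(spoke_radius, 0, 0))
    list(position = posk, pose = pose(Rk, posk))
  })
}

#' Fourier shell correlation between two half-maps
#'
#' Per shell: `Re(sum(F1 * Conj(F2))) / sqrt(sum(|F1|^2) * sum(|F2|^2))`.
#'
#' @param half1,half2 cubic [density_volume()]s on identical grids.
#' @param shell_width shell width in 1/Angstrom; default one Fourier voxel.
#' @return An object of class `"fsc_curve"`: `list(shell_frequencies,
#'   correlations, shell_width)`; frequencies are shell midpoints.
#' @export
fsc <- function(half1, half2, shell_width = NULL) {
  check_same_grid(half1, half2, "fsc")
  require_cubic(half1, "fsc")
  n <- dim(half1$grid)[1]
  if (is.null(shell_width)) shell_width <- 1 / (n * half1$voxel_size)
  F1 <- fft(half1$grid)
  F2 <- fft(half2$grid)
  r <- sqrt(freq_radius_sq(dim(half1$grid), half1$voxel_size))
  nyquist <- 1 / (2 * half1$voxel_size)
  shell <- floor(r / shell_width)
  keep <- r <= nyquist
  shell_ids <- sort(unique(shell[keep]))
  num <- rowsum(Re(F1[keep] * Conj(F2[keep])), shell[keep])
  p1 <- rowsum(Mod(F1[keep])^2, shell[keep])
  p2 <- rowsum(Mod(F2[keep])^2, shell[keep])
  corr <- as.numeric(num) / sqrt(as.numeric(p1) * as.numeric(p2))
  corr[!is.finite(corr)] <- 0
  structure(list(shell_frequencies = (shell_ids + 0.5) * shell_width,
                 correlations = corr, shell_width = shell_width),
            class = "fsc_curve")
}

#' Resolution at an FSC threshold
#'
#' Returns `1/frequency` (Angstrom) at the first downward crossing of the
#' threshold, linearly interpolated between shells. If the curve never
#' falls below the threshold the map is resolved beyond Nyquist at this
#' criterion and `NA` is returned (with attribute `beyond_nyquist = TRUE`).
#'
#' @param curve an `"fsc_curve"` from [fsc()].
#' @param threshold FSC threshold; 0.143 is the half-map convention.
#' @return Resolution in Angstrom, or `NA`.
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  stopifnot(inherits(curve, "fsc_curve"))
  f <- curve$shell_frequencies
  c_ <- curve$correlations
  for (i in seq_along(c_)) {
    if (c_[i] < threshold) {
      if (i == 1) return(1 / f[1])
      # interpolate between shells i-1 and i
      frac <- (c_[i - 1] - threshold) / (c_[i - 1] - c_[i])
      fc <- f[i - 1] + frac * (f[i] - f[i - 1])
      return(1 / fc)
    }
  }
  structure(NA_real_, beyond_nyquist = TRUE)
}

#' Iterative alignment and averaging
#'
#' Alternates [align_subtomogram()] and [average_subtomograms()] for
#' `n_iter` iterations. Particles are split into even/odd halves by index
#' for the final FSC (post-hoc half-map FSC against a single-reference
#' refinement — a desk-scale simplification of gold-standard refinement).
#' A divergence guard aborts if the mean constrained cross-correlation
#' drops by more than 0.2 in one iteration.
#'
#' @param stack particle records from [simulate_particles()], or a list of
#'   volumes (then `wedge` is used for all).
#' @param initial_reference starting [density_volume()].
#' @param mask alignment mask or `NULL`.
#' @param wedge fallback [wedge_model()] for plain-volume stacks.
#' @param n_iter number of iterations (>= 1).
#' @param angular_schedule list of rotation-grid lists (one per iteration),
#'   a single grid recycled, or a numeric vector of ZYZ steps.
#' @param lowpass_schedule per-iteration low-pass cutoffs in Angstrom
#'   (`Inf` = none); recycled.
#' @param shift_limit translational search limit, Angstrom.
#' @param seed integer seed (the refinement itself is deterministic; the
#'   seed is recorded in the output for provenance).
#' @return `list(map, poses, fsc, resolution, cc_trace, results, seed)`.
#' @export
iterative_refine <- function(stack, initial_reference, mask = NULL,
                             wedge = wedge_model(-90, 90), n_iter = 3,
                             angular_schedule = 15,
                             lowpass_schedule = Inf,
                             shift_limit = 0, seed = 1) {
  stopifnot(n_iter >= 1, length(stack) >= 1)
  vols <- lapply(stack, function(p) if (inherits(p, "density_volume")) p else p$subtomogram)
  wedges <- lapply(stack, function(p) if (inherits(p, "density_volume")) wedge else p$wedge)
  grids <- if (is.numeric(angular_schedule)) {
    lapply(rep_len(angular_schedule, n_iter), angular_grid_zyz)
  } else if (is.list(angular_schedule) && is.matrix(angular_schedule[[1]])) {
    rep(list(angular_schedule), n_iter)
  } else {
    rep_len(angular_schedule, n_iter)
  }
  lowpass <- rep_len(lowpass_schedule, n_iter)
  reference <- initial_reference
  cc_trace <- numeric(0)
  poses <- NULL
  results <- NULL
  for (it in seq_len(n_iter)) {
    ref_it <- lowpass_volume(reference, lowpass[it])
    results <- lapply(seq_along(vols), function(i) {
      align_subtomogram(vols[[i]], ref_it, mask = mask, wedge = wedges[[i]],
                        rotations = grids[[it]], shift_limit = shift_limit)
    })
    mean_cc <- mean(vapply(results, function(r) r$cc_score, 0))
    if (length(cc_trace) > 0 && mean_cc < tail(cc_trace, 1) - 0.2) {
      stop(sprintf(
        "iterative_refine(): divergence at iteration %d (mean cc %.3f -> %.3f)",
        it, tail(cc_trace, 1), mean_cc))
    }
    cc_trace <- c(cc_trace, mean_cc)
    poses <- lapply(results, function(r) r$pose)
    reference <- average_subtomograms(vols, poses, wedges)
  }
  even <- seq_along(vols) %% 2 == 0
  curve <- if (sum(even) >= 1 && sum(!even) >= 1) {
    fsc(average_subtomograms(vols[!even], poses[!even], wedges[!even]),
        average_subtomograms(vols[even], poses[even], wedges[even]))
  } else NULL
  list(map = reference, poses = poses, fsc = curve,
       resolution = if (!is.null(curve)) resolution_at(curve) else NA_real_,
       cc_trace = cc_trace, results = results, seed = seed)
}

#' Drop misaligned or rejected particles
#'
#' @param results list of alignment results from [align_subtomogram()].
#' @param cc_floor minimum `cc_score` to keep.
#' @param manual_reject_list integer indices to drop regardless of score.
#' @return The kept subset, order preserved. A message reports the counts;
#'   a warning is raised if nothing survives.
#' @export
clean_particles <- function(results, cc_floor = -1,
                            manual_reject_list = integer(0)) {
  keep <- vapply(seq_along(results), function(i) {
    results[[i]]$cc_score >= cc_floor && !(i %in% manual_reject_list)
  }, TRUE)
  message(sprintf("clean_particles: kept %d of %d particles", sum(keep),
                  length(results)))
  if (!any(keep) && length(results) > 0) {
    warning("clean_particles(): all particles rejected")
  }
  results[keep]
}
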