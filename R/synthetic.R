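#' Ground-truth C_n ring complex specification
#'
#' Describes a synthetic ring-shaped complex with `n_spokes`-fold rotational
#' symmetry about the third (pore) axis, embedded between two parallel
#' membrane slabs — the stand-in for an NPC spanning the double membrane of
#' the nuclear envelope. Each spoke is a set of Gaussian blobs placed at
#' `ring_radius` from the axis.
#'
#' @param n_spokes symmetry order (>= 1; the NPC default is 8).
#' @param ring_radius radius of the spoke ring, Angstrom.
#' @param spoke_blob_spec list of blobs, each `list(offset = c(x, y, z),
#'   sigma = <A>, amplitude = <au>)`; offsets are relative to the spoke
#'   anchor point on the ring.
#' @param membrane_spacing distance between the two slab midplanes,
#'   Angstrom. `0` disables the membranes.
#' @param membrane_sigma,membrane_amplitude Gaussian profile of each slab.
#' @param seed integer seed (reserved; the complex itself is deterministic).
#' @return An object of class `"ground_truth_complex"`.
#' @export
ground_truth_complex <- function(n_spokes = 8, ring_radius = 350,
                                 spoke_blob_spec = list(list(offset = c(0, 0, 0),
                                                             sigma = 40,
                                                             amplitude = 1)),
                                 membrane_spacing = 300,
                                 membrane_sigma = 15,
                                 membrane_amplitude = 0.25,
                                 seed = 0) {
  stopifnot(n_spokes >= 1, ring_radius > 0, length(spoke_blob_spec) >= 1)
  for (b in spoke_blob_spec) {
    stopifnot(length(b$offset) == 3, b$sigma > 0)
  }
  structure(list(n_spokes = as.integer(n_spokes), ring_radius = ring_radius,
                 spoke_blob_spec = spoke_blob_spec,
                 membrane_spacing = membrane_spacing,
                 membrane_sigma = membrane_sigma,
                 membrane_amplitude = membrane_amplitude,
                 seed = as.integer(seed)),
            class = "ground_truth_complex")
}

#' Render a ground-truth complex as a density volume
#'
#' Renders the spec's Gaussian blobs at all `n_spokes` symmetry-related
#' positions plus the two membrane slabs, on a cubic grid. The result is
#' C_n-symmetric by construction (exact up to interpolation when resampled).
#'
#' @param spec a [ground_truth_complex()].
#' @param box_size cubic grid size in voxels.
#' @param voxel_size voxel size in Angstrom.
#' @return `list(volume = density_volume, poses = list of pose)`. Pose `k`
#'   (k = 0..n_spokes-1) has rotation `rot_z(k * 360/n)` and shift equal to
#'   the spoke anchor position (Angstrom, relative to the pore axis).
#' @examples
#' gt <- make_complex(ground_truth_complex(ring_radius = 60, membrane_spacing = 0,
#'   spoke_blob_spec = list(list(offset = c(0, 0, 0), sigma = 10, amplitude = 1))),
#'   box_size = 32, voxel_size = 8)
#' @export
make_complex <- function(spec, box_size = 64, voxel_size = 16) {
  stopifnot(inherits(spec, "ground_truth_complex"))
  max_sig <- max(vapply(spec$spoke_blob_spec, function(b) b$sigma, 0))
  max_off <- max(vapply(spec$spoke_blob_spec,
                        function(b) sqrt(sum(b$offset^2)), 0))
  need <- 2 * (spec$ring_radius + max_off + 3 * max_sig)
  have <- box_size * voxel_size
  if (have < need) {
    stop(sprintf(
      "make_complex(): box of %g A too small; need >= %g A (%d voxels at %g A/voxel)",
      have, need, ceiling(need / voxel_size), voxel_size))
  }
  n <- spec$n_spokes
  centre_vox <- (box_size - 1) / 2
  centres <- NULL
  amps <- NULL
  sigmas <- NULL
  poses <- vector("list", n)
  for (k in 0:(n - 1)) {
    Rk <- rot_z(k * 360 / n)
    anchor <- as.numeric(Rk %*% c(spec$ring_radius, 0, 0))
    poses[[k + 1]] <- pose(Rk, anchor)
    for (b in spec$spoke_blob_spec) {
      p <- anchor + as.numeric(Rk %*% b$offset)
      centres <- rbind(centres, p / voxel_size + centre_vox)
      amps <- c(amps, b$amplitude)
      sigmas <- c(sigmas, b$sigma / voxel_size)
    }
  }
  g <- cpp_render_gaussians(centres, amps, sigmas, rep(as.integer(box_size), 3))
  g <- array(g, rep(box_size, 3))
  if (spec$membrane_spacing > 0 && spec$membrane_amplitude > 0) {
    z <- ((0:(box_size - 1)) - centre_vox) * voxel_size
    prof <- spec$membrane_amplitude *
      (exp(-(z - spec$membrane_spacing / 2)^2 / (2 * spec$membrane_sigma^2)) +
       exp(-(z + spec$membrane_spacing / 2)^2 / (2 * spec$membrane_sigma^2)))
    # Bound the slabs by a soft radial disc so the rendered patch of
    # envelope is rotation-invariant inside the finite box (no corner
    # clipping under resampling).
    xy <- ((0:(box_size - 1)) - centre_vox) * voxel_size
    r <- sqrt(outer(xy^2, xy^2, "+"))
    disc_edge <- box_size * voxel_size / 2 - 2 * voxel_size
    disc <- 1 / (1 + exp((r - disc_edge) / (0.75 * voxel_size)))
    g <- g + outer(disc, prof)
  }
  list(volume = density_volume(g, voxel_size), poses = poses)
}

#' Pose distributions for particle simulation
#'
#' Factories returning a sampler `function(n)` that draws `n` poses from the
#' current RNG stream. `pose_dist_identity` always returns identity poses;
#' `pose_dist_inplane` draws uniform rotations about the pore axis with an
#' optional uniform in-plane shift; `pose_dist_uniform` draws rotations up
#' to `max_angle` about random axes.
#'
#' @param max_shift maximum |shift| per axis, Angstrom.
#' @param max_angle maximum rotation angle, degrees.
#' @return A function `function(n)` returning a list of [pose()]s.
#' @export
pose_dist_identity <- function() {
  function(n) replicate(n, pose(), simplify = FALSE)
}

#' @rdname pose_dist_identity
#' @export
pose_dist_inplane <- function(max_shift = 0) {
  function(n) {
    lapply(seq_len(n), function(i) {
      pose(rot_z(runif(1, 0, 360)),
           c(runif(2, -max_shift, max_shift), 0))
    })
  }
}

#' @rdname pose_dist_identity
#' @export
pose_dist_uniform <- function(max_angle = 180, max_shift = 0) {
  function(n) {
    lapply(seq_len(n), function(i) {
      R <- if (max_angle >= 180) random_rotation() else random_small_rotation(max_angle)
      pose(R, runif(3, -max_shift, max_shift))
    })
  }
}

#' Simulate wedge-degraded noisy subtomograms
#'
#' Each particle is the reference transformed by a ground-truth pose, with
#' Fourier components inside the missing wedge zeroed and i.i.d. Gaussian
#' noise added. Identical `(arguments, seed)` give identical stacks.
#'
#' @param reference a cubic [density_volume()].
#' @param n number of particles (>= 1).
#' @param noise_sigma Gaussian noise sd, intensity units. Use
#'   [snr_to_sigma()] to target a signal-to-noise ratio.
#' @param wedge a [wedge_model()].
#' @param pose_distribution a sampler from [pose_dist_identity()] and
#'   friends, or a list of `n` poses.
#' @param seed integer seed.
#' @return List of particles, each
#'   `list(particle_id, true_pose, subtomogram, wedge, noise_sigma)`.
#' @export
simulate_particles <- function(reference, n, noise_sigma, wedge,
                               pose_distribution = pose_dist_identity(),
                               seed = 1) {
  stopifnot(inherits(reference, "density_volume"), n >= 1,
            inherits(wedge, "wedge_model"), noise_sigma >= 0)
  require_cubic(reference, "simulate_particles")
  with_seed(seed, {
    poses <- if (is.list(pose_distribution)) pose_distribution
             else pose_distribution(n)
    stopifnot(length(poses) == n)
    lapply(seq_len(n), function(i) {
      v <- transform_volume(reference, poses[[i]])
      v <- apply_wedge(v, wedge)
      if (noise_sigma > 0) {
        v$grid <- v$grid + array(rnorm(length(v$grid), 0, noise_sigma),
                                 dim(v$grid))
      }
      list(particle_id = i, true_pose = poses[[i]], subtomogram = v,
           wedge = wedge, noise_sigma = noise_sigma)
    })
  })
}

#' Noise sd achieving a target SNR against a reference signal
#'
#' SNR is defined as var(signal)/var(noise) over the reference grid.
#'
#' @param reference a [density_volume()].
#' @param snr target signal-to-noise ratio.
#' @return Noise standard deviation.
#' @export
snr_to_sigma <- function(reference, snr) {
  stopifnot(snr > 0)
  sd(as.numeric(reference$grid)) / sqrt(snr)
}

#' Simulate per-NPC subunit coordinate tables
#'
#' Emits, for `n_npcs` pores at a common true diameter, subunit positions on
#' a randomly oriented, randomly centred ring of radius `true_diameter/2`
#' (plus isotropic Gaussian positional noise) and unit inward direction
#' vectors pointing from each noisy subunit position toward the true
#' centre — so direction noise is consistent with positional noise. The
#' subunit occupancy of each pore is drawn from `occupancy_distribution`.
#'
#' @param n_npcs number of pores.
#' @param true_diameter ground-truth diameter, Angstrom.
#' @param positional_noise_sigma per-axis positional noise sd, Angstrom.
#' @param occupancy_distribution either a single integer (constant
#'   occupancy), a named numeric vector of probabilities (names = occupancy
#'   values), or a `function(n)` returning `n` integers in 0..8.
#' @param seed integer seed.
#' @param n_subunits ring symmetry order (default 8).
#' @param centre_spread half-width of the uniform cube the true centres are
#'   drawn from, Angstrom.
#' @return `data.frame` with columns `npc_id`, `subunit_index` (0-based),
#'   `x, y, z` (Angstrom) and unit direction `dx, dy, dz`.
#' @export
simulate_subunit_table <- function(n_npcs, true_diameter,
                                   positional_noise_sigma = 0,
                                   occupancy_distribution = 8L,
                                   seed = 1, n_subunits = 8,
                                   centre_spread = 2000) {
  stopifnot(n_npcs >= 1, true_diameter > 0, positional_noise_sigma >= 0)
  radius <- true_diameter / 2
  with_seed(seed, {
    occ <- draw_occupancy(occupancy_distribution, n_npcs, n_subunits)
    rows <- vector("list", n_npcs)
    for (i in seq_len(n_npcs)) {
      centre <- runif(3, -centre_spread / 2, centre_spread / 2)
      Rn <- random_rotation()
      idx <- sort(sample.int(n_subunits, occ[i]) - 1L)
      if (occ[i] == 0) next
      ang <- idx * 2 * pi / n_subunits
      local <- cbind(radius * cos(ang), radius * sin(ang), 0)
      posn <- t(Rn %*% t(local)) + matrix(centre, occ[i], 3, byrow = TRUE)
      posn <- posn + matrix(rnorm(3 * occ[i], 0, positional_noise_sigma),
                            occ[i], 3)
      dirs <- matrix(centre, occ[i], 3, byrow = TRUE) - posn
      dirs <- dirs / sqrt(rowSums(dirs^2))
      rows[[i]] <- data.frame(npc_id = i, subunit_index = idx,
                              x = posn[, 1], y = posn[, 2], z = posn[, 3],
                              dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3])
    }
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  })
}

draw_occupancy <- function(dist, n, n_subunits) {
  occ <- if (is.function(dist)) {
    as.integer(dist(n))
  } else if (length(dist) == 1 && is.null(names(dist))) {
    rep(as.integer(dist), n)
  } else {
    vals <- as.integer(names(dist))
    if (any(is.na(vals))) stop("occupancy_distribution probabilities must have integer names")
    sample(vals, n, replace = TRUE, prob = as.numeric(dist))
  }
  if (any(occ < 0 | occ > n_subunits)) {
    stop(sprintf("occupancy values must be in 0..%d", n_subunits))
  }
  occ
}

#' Simulate replicate peptide detection tables
#'
#' For each replicate, every tryptic peptide of every catalogue protein is
#' observed as an independent Bernoulli draw with the protein's detection
#' probability — the stand-in for replicate LC-MS/MS runs feeding the
#' presence/emPAI bookkeeping.
#'
#' @param protein_catalogue `data.frame` with columns `protein_id` and
#'   `sequence` (one-letter amino-acid codes), e.g. from
#'   [read_protein_fasta()].
#' @param detect_prob scalar detection probability, or a named vector
#'   keyed by `protein_id`.
#' @param replicates number of technical replicates.
#' @param seed integer seed.
#' @param length_range observable peptide length window passed to
#'   [tryptic_digest()].
#' @return A peptide table: `data.frame(protein_id, replicate, peptide)`.
#' @export
simulate_peptide_table <- function(protein_catalogue, detect_prob,
                                   replicates = 3, seed = 1,
                                   length_range = c(6, 30)) {
  stopifnot(is.data.frame(protein_catalogue),
            nrow(protein_catalogue) >= 1,
            all(c("protein_id", "sequence") %in% names(protein_catalogue)))
  if (any(!nzchar(protein_catalogue$sequence))) {
    stop("simulate_peptide_table(): empty protein sequence in catalogue")
  }
  probs <- if (length(detect_prob) == 1 && is.null(names(detect_prob))) {
    setNames(rep(detect_prob, nrow(protein_catalogue)),
             protein_catalogue$protein_id)
  } else detect_prob
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(protein_catalogue))) {
      pid <- protein_catalogue$protein_id[i]
      peps <- tryptic_digest(protein_catalogue$sequence[i],
                             length_range = length_range)
      if (length(peps) == 0) next
      p <- probs[[pid]]
      for (r in seq_len(replicates)) {
        keep <- peps[runif(length(peps)) < p]
        if (length(keep)) {
          rows[[length(rows) + 1]] <-
            data.frame(protein_id = pid, replicate = r, peptide = keep)
        }
      }
    }
    if (length(rows) == 0) {
      data.frame(protein_id = character(), replicate = integer(),
                 peptide = character())
    } else {
      do.call(rbind, rows)
    }
  })
}
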