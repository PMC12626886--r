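# Alignment, averaging, symmetry expansion and FSC.

test_that("self-alignment returns the identity with cc ~ 1", {
  ref <- spoke_reference(box = 24)
  res <- align_subtomogram(ref, ref, rotations = angular_grid_inplane(45),
                           shift_limit = 0)
  expect_lt(rotation_distance(res$pose$rotation), 1e-9)
  expect_gte(res$cc_score, 0.999)
})

test_that("an on-grid rotation and shift are recovered exactly, wedge included", {
  ref <- spoke_reference(box = 24)
  w <- wedge_model(-60, 60)
  truth <- pose(rot_z(90), c(32, 0, 0))  # 90 deg and 2 voxels: grid-exact
  part <- apply_wedge(transform_volume(ref, truth), w)
  res <- align_subtomogram(part, ref, wedge = w,
                           rotations = angular_grid_inplane(30),
                           shift_limit = 64)
  expect_lt(rotation_distance(res$pose$rotation, truth$rotation), 1e-9)
  expect_equal(res$pose$shift, truth$shift, tolerance = 1e-9)
  expect_gt(res$cc_score, 0.99)
})

test_that("alignment winner matches the exhaustive brute-force oracle", {
  ref <- spoke_reference(box = 24)
  w <- wedge_model(-50, 70)
  rotations <- angular_grid_inplane(30)  # 12 poses
  sig <- snr_to_sigma(ref, 1)
  parts <- simulate_particles(ref, 3, sig, w, pose_dist_inplane(), seed = 21)
  for (pp in parts) {
    mine <- align_subtomogram(pp$subtomogram, ref, wedge = w,
                              rotations = rotations, shift_limit = 0)
    oracle <- oracle_align(pp$subtomogram, ref, rotations, w, shift_vox = 0)
    expect_lt(rotation_distance(mine$pose$rotation, oracle$rotation), 1e-9)
  }
})

test_that("alignment validates masks and shift limits", {
  ref <- spoke_reference(box = 24)
  zero_mask <- density_volume(array(0, dim(ref$grid)), ref$voxel_size)
  expect_error(align_subtomogram(ref, ref, mask = zero_mask), "empty")
  bad_mask <- density_volume(array(2, dim(ref$grid)), ref$voxel_size)
  expect_error(align_subtomogram(ref, ref, mask = bad_mask), "\\[0, 1\\]")
  expect_error(align_subtomogram(ref, ref, shift_limit = 1e5), "half-box")
})

test_that("averaging noiseless aligned copies reproduces the reference", {
  ref <- spoke_reference(box = 24, membrane = 0)
  parts <- simulate_particles(ref, 4, 0, wedge_model(-90, 90),
                              pose_dist_identity(), seed = 1)
  avg <- average_subtomograms(parts, lapply(parts, function(p) p$true_pose))
  expect_gt(volume_correlation(avg, ref), 0.999)
  # known rotated poses, still noiseless
  poses <- list(pose(rot_z(90)), pose(rot_z(180)))
  parts2 <- simulate_particles(ref, 2, 0, wedge_model(-90, 90), poses, seed = 1)
  avg2 <- average_subtomograms(parts2, poses)
  expect_gt(volume_correlation(avg2, ref), 0.999)
})

test_that("wedge compensation unions complementary Fourier supports", {
  n <- 24
  ref <- spoke_reference(box = n, membrane = 0)
  w <- wedge_model(-45, 45)
  poses <- list(pose(), pose(rot_y(90)))  # second wedge rotated onto the first's gap
  parts <- simulate_particles(ref, 2, 0, w, poses, seed = 1)
  avg <- average_subtomograms(parts, poses)
  # support-mask arithmetic: union of the one-particle sampling masks
  m1 <- wedge_mask(n, w)
  m2 <- porekit:::rotated_wedge_mask(n, w, t(rot_y(90)))
  union_mask <- pmax(m1, m2 > 0.5)
  expect_gt(mean(union_mask), mean(m1) + 0.1)
  # evaluate coverage only where the reference itself has power (the
  # blob spectrum decays, so empty high-frequency voxels are uninformative)
  Fref <- Mod(fft(ref$grid))^2
  S <- Fref > 1e-6 * max(Fref)
  F <- Mod(fft(avg$grid))^2
  covered <- F > 1e-9 * max(F)
  # the average carries power across the union, including the region only
  # the second (rotated) wedge samples
  expect_gt(mean(covered[S & union_mask > 0.5]), 0.95)
  only2 <- S & (m2 > 0.5) & (m1 < 0.5)
  expect_gt(sum(only2), 0)
  expect_gt(mean(covered[only2]), 0.9)
})

test_that("average/truth correlation rises monotonically with N", {
  ref <- spoke_reference(box = 24, membrane = 0)
  w <- wedge_model(-60, 60)
  sig <- snr_to_sigma(ref, 0.5)
  parts <- simulate_particles(ref, 32, sig, w, pose_dist_identity(), seed = 3)
  cors <- vapply(c(2, 8, 32), function(N) {
    avg <- average_subtomograms(parts[1:N],
                                lapply(parts[1:N], function(p) p$true_pose))
    volume_correlation(avg, ref)
  }, 0)
  expect_true(all(diff(cors) > 0))
})

test_that("symmetry expansion produces the C8 orbit and is group-closed", {
  sp <- symmetry_expand(pose(), whole_centre = c(10, 20, 30), order = 8,
                        spoke_radius = 350)
  expect_length(sp, 8)
  angs <- vapply(seq_along(sp), function(k) {
    rotation_distance(sp[[k]]$pose$rotation, rot_z((k - 1) * 45))
  }, 0)
  expect_lt(max(angs), 1e-9)
  dists <- vapply(sp, function(s) sqrt(sum((s$position - c(10, 20, 30))^2)), 0)
  expect_equal(dists, rep(350, 8), tolerance = 1e-9)
  # composing with one further 45-degree step permutes the pose set
  rotated <- lapply(sp, function(s) s$pose$rotation %*% rot_z(45))
  for (r in rotated) {
    best <- min(vapply(sp, function(s) rotation_distance(r, s$pose$rotation), 0))
    expect_lt(best, 1e-6)
  }
})

test_that("FSC of a map with itself is 1 in every shell", {
  v <- spoke_reference(box = 32)
  curve <- fsc(v, v)
  expect_true(all(abs(curve$correlations - 1) < 1e-6))
  expect_true(all(diff(curve$shell_frequencies) > 0))
})

test_that("independent noise volumes decorrelate beyond the first shell", {
  a <- rand_volume(64, voxel = 8, seed = 5)
  b <- rand_volume(64, voxel = 8, seed = 6)
  # 1.5-voxel shells: enough Fourier voxels per shell for a stable estimate
  curve <- fsc(a, b, shell_width = 1.5 / (64 * 8))
  expect_lt(max(abs(curve$correlations[-1])), 0.2)
})

test_that("a constructed band limit crosses 0.143 at the right shell", {
  # two half-maps share a signal strictly band-limited at 1/35 per Angstrom
  # (brick-wall, built here from first principles) plus independent noise
  n <- 64; voxel <- 8
  k <- c(0:(n / 2), -(n / 2 - 1):-1) / (n * voxel)
  r <- sqrt(outer(outer(k^2, k^2, "+"), k^2, "+"))
  set.seed(9)
  white <- array(rnorm(n^3, 0, 10), rep(n, 3))
  signal <- Re(fft(fft(white) * (r <= 1 / 35), inverse = TRUE)) / n^3
  h1 <- density_volume(signal + array(rnorm(n^3, 0, 1), rep(n, 3)), voxel)
  h2 <- density_volume(signal + array(rnorm(n^3, 0, 1), rep(n, 3)), voxel)
  curve <- fsc(h1, h2)
  res <- resolution_at(curve, 0.143)
  expect_false(is.na(res))
  # crossing within +-2 shells of the 35 A band limit, in frequency units
  expect_lt(abs(1 / res - 1 / 35), 2 * curve$shell_width)
})

test_that("resolution_at is monotone in the threshold and flags non-crossing", {
  v <- spoke_reference(box = 32)
  h1 <- density_volume(v$grid + array(rnorm(32^3, 0, 0.05), dim(v$grid)),
                       v$voxel_size)
  h2 <- density_volume(v$grid + array(rnorm(32^3, 0, 0.05), dim(v$grid)),
                       v$voxel_size)
  curve <- fsc(h1, h2)
  res_low <- resolution_at(curve, 0.05)
  res_high <- resolution_at(curve, 0.5)
  if (!is.na(res_low) && !is.na(res_high)) expect_lte(res_low, res_high)
  self <- fsc(v, v)
  expect_true(is.na(resolution_at(self)))
  expect_true(attr(resolution_at(self), "beyond_nyquist"))
})

test_that("clean_particles drops by floor and reject list, preserving order", {
  results <- lapply(c(0.9, 0.2, 0.8, 0.1, 0.7, 0.05, 0.6, 0.5, 0.4, 0.3),
                    function(cc) list(pose = pose(), cc_score = cc))
  expect_length(suppressMessages(clean_particles(results, cc_floor = -1)), 10)
  kept <- suppressMessages(clean_particles(results, cc_floor = 0.25))
  expect_length(kept, 7)
  expect_equal(vapply(kept, function(r) r$cc_score, 0),
               c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3))
  expect_warning(suppressMessages(clean_particles(results, cc_floor = 2)),
                 "all particles")
  kept2 <- suppressMessages(clean_particles(results, cc_floor = -1,
                                            manual_reject_list = c(1, 3)))
  expect_length(kept2, 8)
})

test_that("iterative refinement is deterministic and converges on noiseless data", {
  ref <- spoke_reference(box = 24, membrane = 0)
  w <- wedge_model(-60, 60)
  # off-grid poses, each within one step of the 10-degree grid
  true_poses <- lapply(c(9, 61, 122, 213), function(a) pose(rot_z(a)))
  parts <- simulate_particles(ref, 4, 0, w, true_poses, seed = 2)
  grid <- angular_grid_inplane(10)
  run1 <- iterative_refine(parts, ref, wedge = w, n_iter = 2,
                           angular_schedule = list(grid, grid), seed = 1)
  run2 <- iterative_refine(parts, ref, wedge = w, n_iter = 2,
                           angular_schedule = list(grid, grid), seed = 1)
  expect_identical(run1$map$grid, run2$map$grid)
  errs <- vapply(seq_along(parts), function(i) {
    rotation_distance(run1$poses[[i]]$rotation, true_poses[[i]]$rotation)
  }, 0)
  expect_lt(max(errs), 10 + 1e-9)  # within one grid step of ground truth
  # mean cc never drops (divergence guard would abort otherwise)
  expect_gte(length(run1$cc_trace), 2)
})

test_that("align then average reproduces the reference on noiseless data", {
  ref <- spoke_reference(box = 24, membrane = 0)
  full <- wedge_model(-90, 90)
  true_poses <- lapply(c(0, 60, 120, 210), function(a) pose(rot_z(a)))
  parts <- simulate_particles(ref, 4, 0, full, true_poses, seed = 2)
  grid <- angular_grid_inplane(10)
  results <- lapply(parts, function(p) {
    align_subtomogram(p$subtomogram, ref, wedge = full, rotations = grid)
  })
  avg <- average_subtomograms(parts, lapply(results, function(r) r$pose))
  expect_gt(volume_correlation(avg, ref), 0.99)
})
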