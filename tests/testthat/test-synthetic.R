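test_that("rendered complexes are C_n-symmetric and expose ground-truth spokes", {
  gt <- make_complex(ground_truth_complex(ring_radius = 240,
    spoke_blob_spec = list(list(offset = c(0, 0, 0), sigma = 48, amplitude = 1)),
    membrane_spacing = 240), box_size = 48, voxel_size = 16)
  expect_gt(volume_correlation(rotate_volume(gt$volume, rot_z(45)), gt$volume),
            0.999)
  expect_length(gt$poses, 8)
  # brute-force angular separations of the returned spoke anchors
  pos <- t(vapply(gt$poses, function(p) p$shift, numeric(3)))
  ang <- sort(atan2(pos[, 2], pos[, 1]) * 180 / pi)
  expect_equal(diff(ang), rep(45, 7), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(pos^2)), rep(240, 8), tolerance = 1e-9)
})

test_that("n_spokes = 1 renders the blob at the radius offset", {
  gt <- make_complex(ground_truth_complex(n_spokes = 1, ring_radius = 120,
    spoke_blob_spec = list(list(offset = c(0, 0, 0), sigma = 40, amplitude = 1)),
    membrane_spacing = 0), box_size = 32, voxel_size = 16)
  peak <- arrayInd(which.max(gt$volume$grid), dim(gt$volume$grid))
  centre_vox <- (32 - 1) / 2
  expect_equal((peak[1] - 1 - centre_vox) * 16, 120, tolerance = 16)
  expect_equal(peak[2] - 1, centre_vox, tolerance = 0.51)
})

test_that("undersized boxes are rejected with the minimal box named", {
  expect_error(
    make_complex(ground_truth_complex(ring_radius = 500), box_size = 32,
                 voxel_size = 16),
    "need >= .* A")
})

test_that("particle simulation is exact without noise and deterministic with it", {
  ref <- spoke_reference(box = 24, membrane = 0)
  full <- wedge_model(-90, 90)
  p0 <- simulate_particles(ref, 1, 0, full, pose_dist_identity(), seed = 1)
  expect_lt(max(abs(p0[[1]]$subtomogram$grid - ref$grid)), 1e-3)
  # a 90-degree on-grid rotation is reproduced exactly
  p90 <- simulate_particles(ref, 1, 0, full, list(pose(rot_z(90))), seed = 1)
  expect_lt(max(abs(p90[[1]]$subtomogram$grid -
                      rotate_volume(ref, rot_z(90))$grid)), 1e-9)
  # determinism: identical seeds give bitwise-identical stacks
  sig <- snr_to_sigma(ref, 0.5)
  w <- wedge_model(-60, 60)
  a <- simulate_particles(ref, 5, sig, w, pose_dist_inplane(), seed = 7)
  b <- simulate_particles(ref, 5, sig, w, pose_dist_inplane(), seed = 7)
  expect_identical(lapply(a, function(p) p$subtomogram$grid),
                   lapply(b, function(p) p$subtomogram$grid))
  expect_false(identical(
    a[[1]]$subtomogram$grid,
    simulate_particles(ref, 5, sig, w, pose_dist_inplane(), seed = 8)[[1]]$subtomogram$grid))
})

test_that("wedge masking removes a strict subset of power and nothing else", {
  v <- rand_volume(16, seed = 11)
  w <- wedge_model(-60, 60)
  m <- wedge_mask(16, w)
  expect_true(all(m %in% c(0, 1)))
  expect_gt(sum(m == 0), 0)
  vw <- apply_wedge(v, w)
  P0 <- Mod(fft(v$grid))^2
  P1 <- Mod(fft(vw$grid))^2
  expect_lte(sum(P1), sum(P0) * (1 + 1e-9))       # power never increases
  expect_lt(max(P1[m == 0]), 1e-12 * max(P0))      # zero inside the wedge
  expect_equal(P1[m == 1], P0[m == 1], tolerance = 1e-6)  # untouched outside
})

test_that("subunit tables honour radius, occupancy and direction consistency", {
  # noise-free: exact radius
  tab <- simulate_subunit_table(5, 700, 0, 8L, seed = 2)
  dd <- diameter_distribution(tab)
  expect_equal(dd$summary$mean, 700, tolerance = 1e-6)
  expect_equal(dd$summary$sd, 0, tolerance = 1e-6)

  # occupancy fixed at 4: zero admissible pores downstream
  tab4 <- simulate_subunit_table(6, 700, 0, 4L, seed = 3)
  dd4 <- diameter_distribution(tab4, min_occupancy = 5)
  expect_equal(dd4$summary$n, 0)
  expect_equal(dd4$summary$n_rejected, 6)

  # noisy: per-pore mean radius matches brute-force recomputation from
  # the emitted coordinates
  tabn <- simulate_subunit_table(4, 700, 10, 8L, seed = 5)
  for (id in unique(tabn$npc_id)) {
    sub <- tabn[tabn$npc_id == id, ]
    g <- pore_diameter(sub)
    P <- as.matrix(sub[, c("x", "y", "z")])
    expect_equal(g$mean_radius,
                 mean(sqrt(rowSums(sweep(P, 2, g$centre)^2))),
                 tolerance = 1e-9)
  }
  # inward directions are unit length
  expect_equal(sqrt(tabn$dx^2 + tabn$dy^2 + tabn$dz^2),
               rep(1, nrow(tabn)), tolerance = 1e-9)
})

test_that("peptide simulation hits its detection probability", {
  catalogue <- data.frame(
    protein_id = "P1",
    sequence = paste(rep("AAAAAAAAK", 1000), collapse = ""))
  # detect_prob 0 and 1 edge cases
  expect_equal(nrow(simulate_peptide_table(catalogue, 0, seed = 1)), 0)
  full <- simulate_peptide_table(catalogue, 1, replicates = 3, seed = 1)
  n_obs <- length(tryptic_digest(catalogue$sequence, length_range = c(6, 30)))
  expect_equal(nrow(full), 3 * n_obs)

  # binomial check at p = 0.5 over many i.i.d. draws
  many <- data.frame(
    protein_id = sprintf("Q%04d", 1:250),
    sequence = vapply(1:250, function(i) {
      set.seed(i)
      paste(vapply(1:4, function(j) {
        paste(c(sample(c("A", "G", "L", "S", "T", "V"), 8, TRUE), "K"),
              collapse = "")
      }, ""), collapse = "")
    }, ""))
  tab <- simulate_peptide_table(many, 0.5, replicates = 1, seed = 7)
  n_total <- sum(vapply(many$sequence, function(s) {
    length(tryptic_digest(s, length_range = c(6, 30)))
  }, 1))
  frac <- nrow(tab) / n_total
  se <- sqrt(0.25 / n_total)
  expect_lt(abs(frac - 0.5), 3 * se)
  expect_error(simulate_peptide_table(data.frame(protein_id = "X",
                                                 sequence = ""), 1),
               "empty")
})
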