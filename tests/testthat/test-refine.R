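# Restraint scores and simulated-annealing refinement.

two_bead_model <- function(d, n_pad = 0) {
  # two single-residue chains a distance d apart (plus optional padding
  # residues far away so superposition stays well defined elsewhere)
  mk <- function(cid, sub, xyz) {
    list(chain_id = cid, species = cid, ring = "IR", subcomplex = sub,
         copy_index = 1L, asym_unit = 0L, ca = matrix(xyz, 1, 3))
  }
  scaffold_model(list(mk("P", "bodyP", c(0, 0, 0)),
                      mk("Q", "bodyQ", c(d, 0, 0))), 1)
}

test_that("closed-form clash value: radii 2 A at distance 3 A scores 1.0", {
  m <- two_bead_model(3)
  expect_equal(clash_score(m, radius = 2, k = 1), 1.0, tolerance = 1e-12)
  # two bodies far apart score exactly zero
  expect_equal(clash_score(two_bead_model(100), radius = 2, k = 1), 0)
})

test_that("clash score is non-increasing as bodies separate along any line", {
  set.seed(8)
  mk1 <- function(cid, sub, xyz) list(chain_id = cid, species = cid,
                                      ring = "IR", subcomplex = sub,
                                      copy_index = 1L, asym_unit = 0L,
                                      ca = matrix(xyz, 1, 3))
  for (rep in 1:5) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    vals <- vapply(seq(0.2, 8, by = 0.2), function(s) {
      m <- scaffold_model(list(mk1("P", "bP", c(0, 0, 0)),
                               mk1("Q", "bQ", dir * s)), 1)
      clash_score(m, radius = 2, k = 1)
    }, 0)
    expect_gt(vals[1], 0)             # overlapping at 0.2 A separation
    expect_true(all(diff(vals) <= 1e-9))
    expect_equal(vals[length(vals)], 0)
  }
  # multi-atom bodies: positive when overlapped, exactly zero once the
  # bodies are beyond contact distance (per-pair monotonicity does not
  # imply whole-body monotonicity while atoms slide past each other)
  truth <- toy_two_body_scaffold()
  bodies <- make_rigid_bodies(truth)
  cenA <- porekit:::body_centroid(truth, bodies[[1]])
  cenB <- porekit:::body_centroid(truth, bodies[[2]])
  dir <- (cenB - cenA) / sqrt(sum((cenB - cenA)^2))
  sweep_vals <- vapply(c(0, 40), function(s) {
    shifted <- apply_body_poses(truth, bodies,
                                list(pose(),
                                     pose(diag(3), dir * s + (cenA - cenB))))
    clash_score(shifted, bodies)
  }, 0)
  expect_gt(sweep_vals[1], 0)         # fully overlapped start
  expect_equal(sweep_vals[2], 0)      # fully separated
})

test_that("closed-form connectivity: 48 A apart with 38 A slack scores 100", {
  m <- two_bead_model(48)
  pairs <- connectivity_restraint("P", 1, "Q", 1, max_length = 38, k = 1)
  expect_equal(connectivity_score(m, pairs), 100.0, tolerance = 1e-9)
  # within the maximum length: zero
  m5 <- two_bead_model(5)
  expect_equal(connectivity_score(m5, pairs), 0)
  # zero-length linker: max_length 3.8, d = 3.8 scores 0
  m38 <- two_bead_model(3.8)
  p0 <- connectivity_restraint("P", 1, "Q", 1, n_linker = 0, k = 1)
  expect_equal(p0$max_length, 3.8)
  expect_equal(connectivity_score(m38, p0), 0, tolerance = 1e-12)
  # dangling reference errors
  bad <- connectivity_restraint("P", 99, "Q", 1, max_length = 38, k = 1)
  expect_error(connectivity_score(m, bad), "dangling")
})

test_that("closed-form elastic: one pair, rest 8, current 10, k 0.5 scores 2", {
  m <- two_bead_model(10)
  pairs <- data.frame(chain_i = "P", res_i = 1L, chain_j = "Q", res_j = 1L,
                      rest_length = 8, k = 0.5)
  expect_equal(elastic_network_score(m, pairs), 2.0, tolerance = 1e-12)
  # zero at the reference geometry by construction
  truth <- toy_two_body_scaffold()
  en <- derive_elastic_network(truth, make_rigid_bodies(truth))
  expect_gt(nrow(en), 0)
  expect_equal(elastic_network_score(truth, en), 0, tolerance = 1e-18)
  # invariant under global rigid motion
  bodies <- make_rigid_bodies(truth)
  g <- pose(rot_zyz(11, 23, 37), c(5, -3, 7))
  moved <- apply_body_poses(truth, list(list(name = "all",
                                             chain_idx = seq_along(truth$chains),
                                             max_translation = Inf,
                                             max_rotation = Inf)), list(g))
  expect_equal(elastic_network_score(moved, en), 0, tolerance = 1e-12)
})

test_that("EM fit is 0 against itself, 1 against a flat map, worse displaced", {
  truth <- toy_two_body_scaffold()
  map <- render_model_density(truth, box_size = 32, voxel_size = 8,
                              bead_sigma = 10)
  expect_lt(em_fit_score(truth, map), 1e-6)
  zero_map <- density_volume(array(0, dim(map$grid)), map$voxel_size,
                             map$origin)
  expect_equal(em_fit_score(truth, zero_map), 1)
  expect_error(em_fit_score(scaffold_model(list(), 1), map), "empty")
  # monotone displacement sweep: 20 A translation clearly worse than truth
  bodies <- make_rigid_bodies(truth)
  scores <- vapply(c(0, 5, 10, 20), function(s) {
    m <- apply_body_poses(truth, bodies,
                          list(pose(diag(3), c(s, 0, 0)),
                               pose(diag(3), c(s, 0, 0))))
    em_fit_score(m, map)
  }, 0)
  expect_true(all(diff(scores) > 0))
})

test_that("total is exactly the weighted component sum along a trajectory", {
  truth <- toy_two_body_scaffold()
  bodies <- make_rigid_bodies(truth)
  map <- render_model_density(truth, box_size = 32, voxel_size = 8,
                              bead_sigma = 10)
  rs <- restraint_set(em_weight = 50, bead_sigma = 10,
                      elastic = derive_elastic_network(truth, bodies),
                      connectivity = connectivity_restraint(
                        "A2", 22, "B1", 1, n_linker = 10))
  fit <- refine(perturb_model(truth, bodies, 8, 5, seed = 3), map, rs,
                bodies, schedule = refine_schedule(n_temps = 2,
                                                   steps_per_temp = 150),
                seed = 3)
  tr <- fit$trajectory
  expect_equal(tr$total,
               rs$em_weight * tr$em_fit + tr$clash + tr$connectivity +
                 tr$elastic, tolerance = 1e-9)
  # best-so-far total is non-increasing
  expect_true(all(diff(tr$best_total) <= 1e-9))
  # refine's final breakdown agrees with the standalone scorer
  sb <- score_breakdown(fit$model, map, rs, bodies)
  expect_equal(fit$best$total, sb$total, tolerance = 1e-9)
})

test_that("the rendered ground truth is a local minimum of the total score", {
  truth <- toy_two_body_scaffold()
  bodies <- make_rigid_bodies(truth)
  map <- render_model_density(truth, box_size = 32, voxel_size = 8,
                              bead_sigma = 10)
  rs <- restraint_set(bead_sigma = 10,
                      elastic = derive_elastic_network(truth, bodies))
  s0 <- score_breakdown(truth, map, rs, bodies)$total
  set.seed(17)
  worse <- vapply(1:50, function(i) {
    p <- perturb_model(truth, bodies, 3, 2, seed = 1000 + i)
    score_breakdown(p, map, rs, bodies)$total
  }, 0)
  expect_true(all(worse > s0))
})

test_that("refinement does not drift from a ground-truth start and is deterministic", {
  truth <- toy_two_body_scaffold()
  bodies <- make_rigid_bodies(truth)
  map <- render_model_density(truth, box_size = 32, voxel_size = 8,
                              bead_sigma = 10)
  rs <- restraint_set(bead_sigma = 10,
                      elastic = derive_elastic_network(truth, bodies))
  fit <- refine(truth, map, rs, bodies,
                schedule = refine_schedule(n_temps = 2, steps_per_temp = 200),
                seed = 5)
  expect_lt(model_rmsd(fit$model, truth), 0.5)
  fit2 <- refine(truth, map, rs, bodies,
                 schedule = refine_schedule(n_temps = 2, steps_per_temp = 200),
                 seed = 5)
  expect_identical(fit$trajectory, fit2$trajectory)
  expect_equal(model_rmsd(fit$model, fit2$model), 0, tolerance = 1e-12)
})
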