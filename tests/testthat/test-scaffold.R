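test_that("the packaged default composition encodes the expected architecture", {
  comp <- default_composition()
  expect_s3_class(comp, "composition_config")
  expect_equal(comp$symmetry_order, 8L)
  expect_length(composition_species(comp), 20)
  # one Y-complex per CR asymmetric unit, two per NR asymmetric unit
  expect_true(all(comp$rings$CR$copies[comp$rings$CR$subcomplex == "Y-complex"] == 1))
  expect_true(all(comp$rings$NR$copies[comp$rings$NR$subcomplex == "Y-complex"] == 2))
  expect_equal(comp$homologue_map$HOS1, "ELYS")
})

test_that("composition schema violations name the offending field", {
  comp <- default_composition()
  path <- withr::local_tempfile(fileext = ".json")

  bad <- comp
  bad$rings$CR$copies[1] <- 0L
  save_composition(bad, path)
  expect_error(load_composition(path), "copies")

  bad2 <- jsonlite::fromJSON(system.file("extdata", "atnpc_composition.json",
                                         package = "porekit"),
                             simplifyVector = FALSE)
  bad2$rings$CR[[1]]$species <- NULL
  jsonlite::write_json(bad2, path, auto_unbox = TRUE)
  expect_error(load_composition(path), "species")

  bad3 <- jsonlite::fromJSON(system.file("extdata", "atnpc_composition.json",
                                         package = "porekit"),
                             simplifyVector = FALSE)
  bad3$symmetry_order <- NULL
  jsonlite::write_json(bad3, path, auto_unbox = TRUE)
  expect_error(load_composition(path), "symmetry_order")
})

test_that("compositions round-trip through save/load", {
  comp <- default_composition()
  path <- withr::local_tempfile(fileext = ".json")
  save_composition(comp, path)
  rt <- load_composition(path)
  expect_equal(rt$rings, comp$rings)
  expect_equal(rt$symmetry_order, comp$symmetry_order)
  expect_equal(rt$homologue_map, comp$homologue_map)
})

test_that("toy placement is deterministic in topology with seeded jitter", {
  comp <- default_composition()
  m0 <- place_toy_chains(comp, seed = 0)
  m1 <- place_toy_chains(comp, seed = 1)
  expect_equal(vapply(m0$chains, function(ch) ch$chain_id, ""),
               vapply(m1$chains, function(ch) ch$chain_id, ""))
  expect_false(identical(m0$chains[[1]]$ca, m1$chains[[1]]$ca))
  expect_identical(place_toy_chains(comp, seed = 0)$chains[[1]]$ca,
                   m0$chains[[1]]$ca)
  # no two chains of one unit closer than 4 A, so the clash score is 0
  expect_gt(porekit:::min_interchain_distance(m0), 4)
  expect_equal(clash_score(m0, make_rigid_bodies(m0)), 0)
})

test_that("composite expansion emits the symmetry orbit with unique ids", {
  comp <- default_composition()
  unit <- place_toy_chains(comp, seed = 0)
  whole <- assemble_composite(unit, 8)
  expect_length(whole$chains, 8 * length(unit$chains))
  expect_false(anyDuplicated(vapply(whole$chains, function(c_) c_$chain_id, "")) > 0)
  # order 1 is the identity
  expect_identical(assemble_composite(unit, 1), unit)
  # positions of one chain's copies lie on a circle about the pore axis
  ca0 <- colMeans(unit$chains[[1]]$ca)
  copies <- Filter(function(c_) {
    c_$species == unit$chains[[1]]$species &&
      c_$subcomplex == unit$chains[[1]]$subcomplex &&
      c_$ring == unit$chains[[1]]$ring && c_$copy_index == 1
  }, whole$chains)
  radii <- vapply(copies, function(c_) {
    sqrt(sum(colMeans(c_$ca)[1:2]^2))
  }, 0)
  expect_equal(radii, rep(sqrt(sum(ca0[1:2]^2)), 8), tolerance = 1e-6)
})

test_that("composite maps are invariant under a further 45-degree turn", {
  # band-limited single-spoke map, as real focused ring maps would be
  v <- lowpass_volume(spoke_reference(box = 24, membrane = 0), 100)
  comp_map <- assemble_composite(list(v), 8)
  expect_gt(volume_correlation(rotate_volume(comp_map, rot_z(45)), comp_map),
            0.999)
})

test_that("stoichiometry reproduces the ring architecture counts", {
  comp <- default_composition()
  whole <- assemble_composite(place_toy_chains(comp, seed = 0), 8)
  by_sub <- stoichiometry(whole, "subcomplex", "ring")
  y <- by_sub[by_sub$subcomplex == "Y-complex", ]
  expect_equal(y$count[y$ring == "CR"], 8)
  expect_equal(y$count[y$ring == "NR"], 16)
  # per-asymmetric-unit counts
  per_au <- stoichiometry(whole, "subcomplex", "asym_unit", ring = "CR")
  expect_equal(per_au$count[per_au$subcomplex == "NUP205-NUP93"], 2)
  hos1 <- stoichiometry(whole, "species", "asym_unit", ring = "NR")
  expect_equal(hos1$count[hos1$species == "HOS1"], 2)
})

test_that("whole-scaffold counts conserve per-unit counts times the order", {
  comp <- default_composition()
  unit <- place_toy_chains(comp, seed = 0)
  whole <- assemble_composite(unit, 8)
  s_unit <- stoichiometry(unit, "species", "whole")    # scaled by order
  s_whole <- stoichiometry(whole, "species", "whole")  # counted directly
  expect_equal(s_unit, s_whole)
  per_au <- stoichiometry(whole, "species", "asym_unit")
  m <- merge(per_au, s_whole, by = "species")
  expect_equal(m$count.x * 8, m$count.y)
})

test_that("empty models yield empty tables and unknown groupings error", {
  empty <- scaffold_model(list(), 8)
  expect_equal(nrow(stoichiometry(empty, "species", "whole")), 0)
  comp <- default_composition()
  unit <- place_toy_chains(comp, seed = 0)
  expect_error(stoichiometry(unit, "flavour"), "arg")
})
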