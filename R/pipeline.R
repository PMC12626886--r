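#' Packaged toy two-body refinement problem
#'
#' Two rigid bodies of two helical chains each, centred on the origin —
#' the standard small problem for exercising the refinement restraints
#' and recovery behaviour.
#'
#' @param gap x-spacing between chains, Angstrom.
#' @return A [scaffold_model()] whose chains form two subcomplex
#'   instances (`toyA`, `toyB`). Chain lengths and helix tilts differ so
#'   the bodies have no internal pseudo-symmetry and the score landscape
#'   has a unique minimum at the reference geometry.
#' @export
toy_two_body_scaffold <- function(gap = 16) {
  mk <- function(cid, sub, n_res, x, z, tilt_axis, tilt_deg) {
    ca <- helix_ca(n_res, c(0, 0, 0))
    ca <- t(axis_angle_matrix(tilt_axis, tilt_deg) %*% t(ca))
    ca <- sweep(ca, 2, c(x, 0, z), "+")
    list(chain_id = cid, species = cid, ring = "IR", subcomplex = sub,
         copy_index = 1L, asym_unit = 0L, ca = ca)
  }
  # Distinct chain lengths, tilts and axial offsets: no body has internal
  # pseudo-symmetry and the coarse-bead lattice has no common translation
  # period, so the EM score has a unique optimum at this geometry.
  xs <- c(-1.5, -0.5, 0.5, 1.5) * gap
  scaffold_model(list(
    mk("A1", "toyA", 30L, xs[1], 0, c(0, 1, 0), 25),
    mk("A2", "toyA", 22L, xs[2], 8, c(1, 0, 0), -30),
    mk("B1", "toyB", 34L, xs[3], -6, c(0, 1, 0), -18),
    mk("B2", "toyB", 26L, xs[4], 4, c(1, 1, 0), 28)),
    symmetry_order = 1)
}

#' @rdname toy_two_body_scaffold
#' @param truth the reference [toy_two_body_scaffold()].
#' @param bodies its rigid bodies.
#' @return `toy_two_body_restraints`: the packaged [restraint_set()] for
#'   the toy problem — EM fit, clash, sequence connectivity between
#'   consecutive chains (the four chains mimic consecutive domains of one
#'   polypeptide) and an elastic network over the reference interfaces.
#' @export
toy_two_body_restraints <- function(truth = toy_two_body_scaffold(),
                                    bodies = make_rigid_bodies(truth)) {
  nres <- vapply(truth$chains, function(ch) nrow(ch$ca), 1L)
  # linker lengths sized so every restraint is satisfied (with margin) at
  # the reference geometry
  conn <- rbind(
    connectivity_restraint("A1", nres[1], "A2", 1, n_linker = 9),
    connectivity_restraint("A2", nres[2], "B1", 1, n_linker = 16),
    connectivity_restraint("B1", nres[3], "B2", 1, n_linker = 10))
  restraint_set(bead_sigma = 10, connectivity = conn,
                elastic = derive_elastic_network(truth, bodies,
                                                 cutoff = 12, k = 0.1))
}

#' Randomly perturb rigid-body placements
#'
#' Applies an independent random pose (rotation up to `max_rot` degrees
#' about a random axis through the body centroid, translation up to
#' `max_trans` Angstrom per axis direction) to every body.
#'
#' @param model a [scaffold_model()].
#' @param bodies rigid bodies from [make_rigid_bodies()].
#' @param max_trans,max_rot perturbation bounds (Angstrom, degrees).
#' @param seed integer seed.
#' @return Perturbed model.
#' @export
perturb_model <- function(model, bodies, max_trans = 15, max_rot = 10,
                          seed = 1) {
  with_seed(seed, {
    poses <- lapply(bodies, function(b) {
      dt <- runif(3, -1, 1)
      dt <- dt / max(1e-9, sqrt(sum(dt^2))) * runif(1, 0, max_trans)
      pose(random_small_rotation(max_rot), dt)
    })
    apply_body_poses(model, bodies, poses)
  })
}

#' Default demo configuration
#'
#' Fixed parameters mirror the field's conventions: FSC threshold 0.143,
#' minimum subunit occupancy 5, symmetry order 8. Every stochastic stage
#' carries its own explicit seed so that stages are isolated: changing one
#' stage's seed leaves the other sections of the report untouched.
#'
#' @param seed master seed; per-stage seeds are derived from it once.
#' @return A nested configuration list.
#' @export
demo_config <- function(seed = 1) {
  list(
    version = 1L,
    sta = list(box_size = 32, voxel_size = 16, ring_radius = 50,
               blob_sigma = 38, membrane_spacing = 240, n_particles = 8,
               snr = 0.5, tilt_min = -60, tilt_max = 60,
               angular_step = 30, shift_limit = 0, n_iter = 1,
               fsc_threshold = 0.143, seed = child_seed(seed, 1)),
    geometry = list(n_npcs = 20, true_diameter = 700, noise_sigma = 10,
                    occupancy = c("6" = 0.2, "7" = 0.3, "8" = 0.5),
                    min_occupancy = 5, seed = child_seed(seed, 2)),
    scaffold = list(composition = "default", symmetry_order = 8,
                    seed = child_seed(seed, 3)),
    refine = list(max_perturb_trans = 10, max_perturb_rot = 8,
                  n_temps = 3, steps_per_temp = 300,
                  box_size = 32, voxel_size = 8, bead_sigma = 10,
                  seed = child_seed(seed, 4)),
    compare = list(n_res = 60, hinge_at = 30, hinge_angle = 60),
    proteomics = list(n_proteins = 6, detect_prob = 0.4, replicates = 3,
                      min_peptides = 2, seed = child_seed(seed, 5))
  )
}

#' Run the end-to-end demo pipeline
#'
#' Executes synthetic generation, subtomogram averaging, pore geometry,
#' composite assembly and stoichiometry, rigid-body refinement, structure
#' comparison and the proteomics census, writing MRC maps, TSV tables and
#' a versioned JSON report. Identical configuration and seeds give a
#' byte-identical report. A failing stage yields a partial report whose
#' `failed_stage` field names the stage and error.
#'
#' @param config configuration list from [demo_config()], or a path to a
#'   JSON file holding one.
#' @param out_dir output directory (created if missing).
#' @return The report, invisibly; written to `out_dir/report.json`.
#' @export
run_demo <- function(config = demo_config(), out_dir = tempfile("porekit_demo_")) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("run_demo(): config stage failed, missing input path: ", config)
    }
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
    config$geometry$occupancy <- unlist(config$geometry$occupancy)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(schema = "porekit-demo-report", schema_version = 1L,
                 config_hash = config_hash(config))
  stage <- function(name, fun) {
    if (!is.null(report$failed_stage)) return(NULL)
    res <- tryCatch(fun(), error = function(e) {
      report$failed_stage <<- list(stage = name, error = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) report[[name]] <<- res
    invisible(NULL)
  }

  stage("sta", function() {
    cf <- config$sta
    # single-spoke (asymmetric unit) reference: in-plane pose recovery is
    # well posed, unlike on the full C8 ring
    L <- cf$box_size * cf$voxel_size
    gt <- make_complex(
      ground_truth_complex(
        n_spokes = 1, ring_radius = cf$ring_radius,
        spoke_blob_spec = list(
          list(offset = c(0, 0, 0), sigma = cf$blob_sigma, amplitude = 1),
          list(offset = c(-0.05, 0.08, 0.06) * L, sigma = 0.75 * cf$blob_sigma,
               amplitude = 0.9),
          list(offset = c(0.04, -0.07, -0.08) * L, sigma = 0.6 * cf$blob_sigma,
               amplitude = 0.7)),
        membrane_spacing = cf$membrane_spacing),
      box_size = cf$box_size, voxel_size = cf$voxel_size)
    wedge <- wedge_model(cf$tilt_min, cf$tilt_max)
    sigma <- snr_to_sigma(gt$volume, cf$snr)
    parts <- simulate_particles(gt$volume, cf$n_particles, sigma, wedge,
                                pose_dist_inplane(), seed = cf$seed)
    grid <- angular_grid_inplane(cf$angular_step)
    res <- iterative_refine(parts, gt$volume, wedge = wedge,
                            n_iter = cf$n_iter, angular_schedule = list(grid),
                            shift_limit = cf$shift_limit, seed = cf$seed)
    err <- vapply(seq_along(parts), function(i) {
      rotation_distance(res$poses[[i]]$rotation, parts[[i]]$true_pose$rotation)
    }, 0)
    write_mrc(res$map, file.path(out_dir, "sta_average.mrc"))
    write_pose_table(res$results, file.path(out_dir, "sta_poses.tsv"),
                     comment = c(seed = cf$seed,
                                 config_hash = report$config_hash))
    resol <- resolution_at(res$fsc, cf$fsc_threshold)
    list(n_particles = cf$n_particles, mean_cc = mean(res$cc_trace),
         frac_within_step = mean(err <= cf$angular_step + 1e-6),
         map_truth_correlation = volume_correlation(res$map, gt$volume),
         fsc_resolution_A = if (is.na(resol)) "beyond_nyquist" else round(resol, 3))
  })

  stage("geometry", function() {
    cf <- config$geometry
    tab <- simulate_subunit_table(cf$n_npcs, cf$true_diameter,
                                  cf$noise_sigma, cf$occupancy,
                                  seed = cf$seed)
    dd <- diameter_distribution(tab, min_occupancy = cf$min_occupancy)
    write.table(dd$per_npc, file.path(out_dir, "pore_diameters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_admissible = dd$summary$n, n_rejected = dd$summary$n_rejected,
         mean_diameter_A = round(dd$summary$mean, 4),
         sd_diameter_A = round(dd$summary$sd, 4),
         true_diameter_A = cf$true_diameter)
  })

  stage("scaffold", function() {
    cf <- config$scaffold
    comp <- if (identical(cf$composition, "default")) default_composition()
            else load_composition(cf$composition)
    unit <- place_toy_chains(comp, seed = cf$seed)
    whole <- assemble_composite(unit, cf$symmetry_order)
    by_species <- stoichiometry(whole, "species", "whole")
    by_sub <- stoichiometry(whole, "subcomplex", "ring")
    write.table(by_species, file.path(out_dir, "stoichiometry_species.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(by_sub, file.path(out_dir, "stoichiometry_subcomplex.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_pdb_ca(whole, file.path(out_dir, "composite_model.pdb"))
    ysub <- by_sub[by_sub$subcomplex == "Y-complex", ]
    list(n_species = length(composition_species(comp)),
         n_chains_composite = length(whole$chains),
         y_complexes_cr = ysub$count[ysub$ring == "CR"],
         y_complexes_nr = ysub$count[ysub$ring == "NR"])
  })

  stage("refine", function() {
    cf <- config$refine
    truth <- toy_two_body_scaffold()
    bodies <- make_rigid_bodies(truth)
    map <- render_model_density(truth, box_size = cf$box_size,
                                voxel_size = cf$voxel_size,
                                bead_sigma = cf$bead_sigma)
    rs <- restraint_set(bead_sigma = cf$bead_sigma,
                        elastic = derive_elastic_network(truth, bodies,
                                                         cutoff = 25, k = 0.02))
    start <- perturb_model(truth, bodies, cf$max_perturb_trans,
                           cf$max_perturb_rot, seed = cf$seed)
    fit <- refine(start, map, rs, make_rigid_bodies(start),
                  schedule = refine_schedule(n_temps = cf$n_temps,
                                             steps_per_temp = cf$steps_per_temp),
                  seed = cf$seed)
    list(start_rmsd_A = round(model_rmsd(start, truth), 4),
         final_rmsd_A = round(model_rmsd(fit$model, truth), 4),
         best_total = round(fit$best$total, 6))
  })

  stage("compare", function() {
    cf <- config$compare
    a <- hinge_toy(cf$n_res, cf$hinge_at, 0)
    b <- hinge_toy(cf$n_res, cf$hinge_at, cf$hinge_angle)
    whole <- tm_score(a, b)
    doms <- lapply(list(c(1, cf$hinge_at), c(cf$hinge_at + 1, cf$n_res)),
                   function(rg) {
                     tm_score(split_domains(a, list(rg))[[1]],
                              split_domains(b, list(rg))[[1]])$tm_score
                   })
    list(whole_chain_tm = round(whole$tm_score, 4),
         per_domain_tm = round(unlist(doms), 4))
  })

  stage("proteomics", function() {
    cf <- config$proteomics
    fixture <- read_empai_fixture()
    cens <- census(fixture, read_nup_catalogue())
    ys <- y_complex_sets()
    ov <- y_complex_overlap(ys$arabidopsis, ys$human, ys$homologue_map)
    catalogue <- synthetic_protein_catalogue(cf$n_proteins,
                                             seed = child_seed(cf$seed, 1))
    peps <- simulate_peptide_table(catalogue, cf$detect_prob,
                                   replicates = cf$replicates,
                                   seed = child_seed(cf$seed, 2))
    pres <- presence_table(peps, min_peptides = cf$min_peptides,
                           n_replicates = cf$replicates)
    list(census_n_detected = cens$n_detected,
         census_histogram = as.list(cens$histogram),
         y_complex_shared = ov$count,
         simulated_presence = setNames(as.list(pres$presence),
                                       pres$protein_id))
  })

  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null")
  invisible(report)
}

# Two-domain chain with a hinge bend between the domains (degrees); used
# for the per-domain TM-score demonstration.
hinge_toy <- function(n_res, hinge_at, bend_deg) {
  ca <- helix_ca(n_res, c(0, 0, 0))
  if (bend_deg != 0) {
    Rb <- rot_y(bend_deg)
    pivot <- ca[hinge_at, ]
    idx <- (hinge_at + 1):n_res
    ca[idx, ] <- t(Rb %*% (t(ca[idx, , drop = FALSE]) - pivot)) +
      matrix(pivot, length(idx), 3, byrow = TRUE)
  }
  coord_set(ca)
}

# Deterministic random-sequence catalogue for peptide-table demos.
synthetic_protein_catalogue <- function(n_proteins, length_aa = 300, seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    data.frame(
      protein_id = sprintf("PROT%02d", seq_len(n_proteins)),
      sequence = vapply(seq_len(n_proteins), function(i) {
        paste(sample(aa, length_aa, replace = TRUE), collapse = "")
      }, ""))
  })
}

# Polynomial rolling hash of the canonical JSON serialization of a config;
# provenance fingerprint only, not cryptographic.
config_hash <- function(config) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                   digits = 12)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
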