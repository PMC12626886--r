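#' Group chains into rigid bodies
#'
#' Rigid bodies keep their internal coordinates fixed during refinement;
#' only their poses move. The default grouping makes one body per
#' subcomplex instance `(ring, asymmetric unit, subcomplex, copy index)`,
#' matching how fitted subcomplex models are treated as rigid units.
#'
#' @param model a [scaffold_model()].
#' @param by `"subcomplex"` (instance) or `"chain"`.
#' @param max_translation,max_rotation hard move limits per body relative
#'   to the starting pose (Angstrom, degrees).
#' @return List of bodies: `list(name, chain_idx, max_translation,
#'   max_rotation)`.
#' @export
make_rigid_bodies <- function(model, by = c("subcomplex", "chain"),
                              max_translation = Inf, max_rotation = Inf) {
  stopifnot(inherits(model, "scaffold_model"))
  by <- match.arg(by)
  keys <- vapply(seq_along(model$chains), function(i) {
    ch <- model$chains[[i]]
    if (by == "chain") ch$chain_id
    else sprintf("%s.au%d.%s.%d", ch$ring, ch$asym_unit, ch$subcomplex,
                 ch$copy_index)
  }, "")
  lapply(unique(keys), function(k) {
    list(name = k, chain_idx = which(keys == k),
         max_translation = max_translation, max_rotation = max_rotation)
  })
}

#' Restraint set for rigid-body refinement
#'
#' Four restraint classes score a model against a density map: the EM fit
#' (on the 10-residue coarse beads), a soft-sphere clash score between
#' Calpha beads of different bodies, connectivity restraints between
#' sequence-neighbouring domains, and elastic-network restraints
#' preserving interface geometry taken from a reference model. The total
#' is `em_weight * em_fit + clash + connectivity + elastic`.
#'
#' @param em_weight weight of the EM fit component. The default puts the
#'   components on the same order of magnitude on the packaged toy problem.
#' @param clash_radius,clash_k Calpha bead radius (Angstrom) and stiffness.
#' @param connectivity `data.frame` of connectivity restraints (see
#'   [connectivity_restraint()]).
#' @param elastic `data.frame` of elastic pairs (see
#'   [derive_elastic_network()]).
#' @param bead_sigma Gaussian sigma (Angstrom) used to render coarse beads
#'   for the EM fit.
#' @return An object of class `"restraint_set"`.
#' @export
restraint_set <- function(em_weight = 50, clash_radius = 2, clash_k = 1,
                          connectivity = NULL, elastic = NULL,
                          bead_sigma = 10) {
  stopifnot(em_weight >= 0, clash_radius > 0, clash_k >= 0, bead_sigma > 0)
  structure(list(em_weight = em_weight, clash_radius = clash_radius,
                 clash_k = clash_k,
                 connectivity = connectivity, elastic = elastic,
                 bead_sigma = bead_sigma),
            class = "restraint_set")
}

#' Render a model's coarse beads as a density map
#'
#' Each 10-residue bead becomes an isotropic Gaussian weighted by the
#' number of residues it represents. Used both for the EM-fit restraint
#' and to build noiseless refinement targets.
#'
#' @param model a [scaffold_model()].
#' @param box_size,voxel_size output grid (cubic), Angstrom.
#' @param bead_sigma Gaussian sigma, Angstrom.
#' @return A [density_volume()].
#' @export
render_model_density <- function(model, box_size = 64, voxel_size = 16,
                                 bead_sigma = 10) {
  stopifnot(inherits(model, "scaffold_model"), length(model$chains) >= 1)
  beads <- NULL
  w <- NULL
  for (ch in model$chains) {
    b <- coarse_beads(ch)
    n <- nrow(ch$ca)
    cnt <- as.numeric(table(ceiling(seq_len(n) / 10)))
    beads <- rbind(beads, b)
    w <- c(w, cnt)
  }
  vol0 <- density_volume(array(0, rep(box_size, 3)), voxel_size)
  pts <- phys_to_voxel(vol0, beads)
  g <- cpp_render_gaussians(pts, w, rep(bead_sigma / voxel_size, nrow(pts)),
                            rep(as.integer(box_size), 3))
  density_volume(array(g, rep(box_size, 3)), voxel_size, vol0$origin)
}

#' EM fit score
#'
#' `1 - NCC(map, rendered coarse-bead density)`, in `[0, 2]`; lower is
#' better. A zero-variance map (or model rendering entirely outside the
#' map) has no correlation and scores 1.
#'
#' @param model a [scaffold_model()].
#' @param map target [density_volume()].
#' @param bead_sigma rendering sigma, Angstrom.
#' @return Scalar score.
#' @export
em_fit_score <- function(model, map, bead_sigma = 10) {
  stopifnot(inherits(model, "scaffold_model"))
  if (length(model$chains) == 0) stop("em_fit_score(): empty model")
  rendered <- render_model_density(model, box_size = dim(map$grid)[1],
                                   voxel_size = map$voxel_size,
                                   bead_sigma = bead_sigma)
  1 - ncc_arrays(map$grid, rendered$grid)
}

ncc_arrays <- function(a, b) {
  a <- as.numeric(a) - mean(a)
  b <- as.numeric(b) - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Soft-sphere clash score
#'
#' Sum over Calpha pairs from different rigid bodies of
#' `k * max(0, r_i + r_j - d_ij)^2`; zero when no inter-body pair is closer
#' than the sum of radii.
#'
#' @param model a [scaffold_model()].
#' @param bodies rigid bodies from [make_rigid_bodies()]; default one body
#'   per chain.
#' @param radius per-bead radius, Angstrom.
#' @param k stiffness.
#' @return Scalar score.
#' @export
clash_score <- function(model, bodies = NULL, radius = 2, k = 1) {
  stopifnot(inherits(model, "scaffold_model"))
  if (is.null(bodies)) bodies <- make_rigid_bodies(model, by = "chain")
  coords <- lapply(bodies, function(b) {
    do.call(rbind, lapply(model$chains[b$chain_idx], function(ch) ch$ca))
  })
  total <- 0
  nb <- length(bodies)
  if (nb < 2) return(0)
  for (i in 1:(nb - 1)) {
    for (j in (i + 1):nb) {
      d <- sqrt(pmax(cross_dist2(coords[[i]], coords[[j]]), 0))
      ov <- pmax(0, 2 * radius - d)
      total <- total + k * sum(ov^2)
    }
  }
  total
}

#' Connectivity restraints
#'
#' `connectivity_restraint` builds one restraint row between two residues
#' (typically domain termini) with maximum length `3.8 * (n_linker + 1)`
#' Angstrom — the extended Calpha-Calpha reach of the unmodelled linker.
#' `connectivity_score` evaluates `sum k * max(0, d - max_length)^2`.
#'
#' @param chain_i,chain_j chain ids.
#' @param res_i,res_j 1-based residue indices within the chains.
#' @param n_linker number of unmodelled linker residues.
#' @param k stiffness.
#' @param max_length override the default maximum length, Angstrom.
#' @return `connectivity_restraint`: one-row `data.frame`;
#'   `connectivity_score`: scalar.
#' @export
connectivity_restraint <- function(chain_i, res_i, chain_j, res_j,
                                   n_linker = 0, k = 1,
                                   max_length = 3.8 * (n_linker + 1)) {
  data.frame(chain_i = chain_i, res_i = res_i, chain_j = chain_j,
             res_j = res_j, max_length = max_length, k = k)
}

#' @rdname connectivity_restraint
#' @param model a [scaffold_model()].
#' @param pairs `data.frame` of restraints.
#' @export
connectivity_score <- function(model, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) return(0)
  d <- pair_distances(model, pairs, "connectivity_score")
  sum(pairs$k * pmax(0, d - pairs$max_length)^2)
}

# Vectorized distances for restraint pairs (chain_i/res_i vs chain_j/res_j),
# validating all references.
pair_distances <- function(model, pairs, what) {
  ids <- vapply(model$chains, function(ch) ch$chain_id, "")
  nres <- vapply(model$chains, function(ch) nrow(ch$ca), 1L)
  offset <- c(0L, cumsum(nres))[seq_along(nres)]
  names(offset) <- ids
  ci <- match(pairs$chain_i, ids)
  cj <- match(pairs$chain_j, ids)
  if (anyNA(ci) || anyNA(cj)) {
    stop(sprintf("%s(): unknown chain in restraint table", what))
  }
  if (any(pairs$res_i < 1 | pairs$res_i > nres[ci]) ||
      any(pairs$res_j < 1 | pairs$res_j > nres[cj])) {
    stop(sprintf("%s(): dangling residue reference", what))
  }
  X <- do.call(rbind, lapply(model$chains, function(ch) ch$ca))
  A <- X[offset[ci] + pairs$res_i, , drop = FALSE]
  B <- X[offset[cj] + pairs$res_j, , drop = FALSE]
  sqrt(rowSums((A - B)^2))
}

#' Elastic network restraints
#'
#' `derive_elastic_network` records all inter-body Calpha pairs within
#' `cutoff` of each other at the reference geometry, freezing their
#' current distances as rest lengths. `elastic_network_score` evaluates
#' `sum k * (d - rest_length)^2`; it is zero at the reference geometry and
#' invariant under global rigid motion of the whole assembly.
#'
#' @param model reference [scaffold_model()].
#' @param bodies rigid bodies; pairs within one body are skipped.
#' @param cutoff interface distance cutoff, Angstrom.
#' @param k per-pair stiffness.
#' @return `derive_elastic_network`: `data.frame(chain_i, res_i, chain_j,
#'   res_j, rest_length, k)`; `elastic_network_score`: scalar.
#' @export
derive_elastic_network <- function(model, bodies = NULL, cutoff = 10, k = 0.1) {
  stopifnot(inherits(model, "scaffold_model"))
  if (is.null(bodies)) bodies <- make_rigid_bodies(model, by = "chain")
  body_of <- integer(length(model$chains))
  for (bi in seq_along(bodies)) body_of[bodies[[bi]]$chain_idx] <- bi
  out <- list()
  nc <- length(model$chains)
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (j <= i || body_of[i] == body_of[j]) next
      A <- model$chains[[i]]$ca; B <- model$chains[[j]]$ca
      d2 <- cross_dist2(A, B)
      hits <- which(d2 <= cutoff^2, arr.ind = TRUE)
      if (nrow(hits)) {
        out[[length(out) + 1]] <- data.frame(
          chain_i = model$chains[[i]]$chain_id, res_i = hits[, 1],
          chain_j = model$chains[[j]]$chain_id, res_j = hits[, 2],
          rest_length = sqrt(pmax(d2[hits], 0)), k = k)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chain_i = character(), res_i = integer(),
               chain_j = character(), res_j = integer(),
               rest_length = numeric(), k = numeric())
}

#' @rdname derive_elastic_network
#' @param pairs `data.frame` of elastic pairs.
#' @export
elastic_network_score <- function(model, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) return(0)
  d <- pair_distances(model, pairs, "elastic_network_score")
  sum(pairs$k * (d - pairs$rest_length)^2)
}

#' Score breakdown
#'
#' Evaluates all four restraint classes; `total` is exactly the weighted
#' component sum.
#'
#' @param model a [scaffold_model()].
#' @param map target density.
#' @param restraints a [restraint_set()].
#' @param bodies rigid bodies for the clash term.
#' @return `list(em_fit, clash, connectivity, elastic, total)`.
#' @export
score_breakdown <- function(model, map, restraints, bodies = NULL) {
  em <- em_fit_score(model, map, bead_sigma = restraints$bead_sigma)
  cl <- clash_score(model, bodies, radius = restraints$clash_radius,
                    k = restraints$clash_k)
  cn <- connectivity_score(model, restraints$connectivity)
  el <- elastic_network_score(model, restraints$elastic)
  comps <- c(em_fit = em, clash = cl, connectivity = cn, elastic = el)
  if (any(!is.finite(comps))) {
    stop("score_breakdown(): non-finite component: ",
         paste(names(comps)[!is.finite(comps)], collapse = ", "))
  }
  list(em_fit = em, clash = cl, connectivity = cn, elastic = el,
       total = restraints$em_weight * em + cl + cn + el)
}

#' Apply per-body poses to a scaffold model
#'
#' Each body's pose rotates its chains about the body's reference centroid
#' and then translates them; `poses` is a list parallel to `bodies`.
#'
#' @param model a [scaffold_model()].
#' @param bodies rigid bodies from [make_rigid_bodies()].
#' @param poses list of [pose()]s, one per body.
#' @return The transformed model.
#' @export
apply_body_poses <- function(model, bodies, poses) {
  out <- model
  for (bi in seq_along(bodies)) {
    b <- bodies[[bi]]
    p <- poses[[bi]]
    cen <- body_centroid(model, b)
    for (ci in b$chain_idx) {
      ca <- model$chains[[ci]]$ca
      out$chains[[ci]]$ca <-
        t(p$rotation %*% (t(ca) - cen)) +
        matrix(cen + p$shift, nrow(ca), 3, byrow = TRUE)
    }
  }
  out
}

body_centroid <- function(model, body) {
  all <- do.call(rbind, lapply(model$chains[body$chain_idx], function(ch) ch$ca))
  colMeans(all)
}

#' Simulated-annealing rigid-body refinement
#'
#' Metropolis Monte Carlo over rigid-body translations and rotations with
#' geometric cooling. Proposals outside a body's move limits are rejected
#' outright; the best-scoring model seen is returned (its running best
#' total is non-increasing by construction).
#'
#' @param model starting [scaffold_model()] (also the reference geometry
#'   for body centroids).
#' @param map target [density_volume()].
#' @param restraints a [restraint_set()].
#' @param bodies rigid bodies from [make_rigid_bodies()].
#' @param schedule `list(temperatures, steps_per_temp)`; the default is 5
#'   geometric temperatures, 2000 steps each.
#' @param max_step_trans,max_step_rot proposal sizes (Angstrom, degrees).
#' @param seed integer seed; identical seeds give identical trajectories.
#' @return `list(model, poses, best, trajectory)` where `trajectory` is a
#'   `data.frame` of component scores at each recorded step.
#' @export
refine <- function(model, map, restraints, bodies,
                   schedule = refine_schedule(),
                   max_step_trans = 4, max_step_rot = 4, seed = 1) {
  stopifnot(inherits(model, "scaffold_model"), length(bodies) >= 1,
            inherits(restraints, "restraint_set"))
  nb <- length(bodies)
  if (!setequal(unlist(lapply(bodies, function(b) b$chain_idx)),
                seq_along(model$chains))) {
    stop("refine(): bodies must partition all chains of the model")
  }
  d <- dim(map$grid)
  n_vox <- prod(d)
  map_c <- as.numeric(map$grid) - mean(map$grid)
  map_n <- sqrt(sum(map_c^2))

  # --- static per-body state ------------------------------------------------
  cens <- lapply(bodies, function(b) body_centroid(model, b))
  ref_atoms <- lapply(bodies, function(b) {
    do.call(rbind, lapply(model$chains[b$chain_idx], function(ch) ch$ca))
  })
  ref_beads <- lapply(bodies, function(b) {
    do.call(rbind, lapply(model$chains[b$chain_idx], coarse_beads))
  })
  bead_w <- lapply(bodies, function(b) {
    unlist(lapply(model$chains[b$chain_idx], function(ch) {
      as.numeric(table(ceiling(seq_len(nrow(ch$ca)) / 10)))
    }))
  })
  # global atom indexing: body b owns rows atom_rows[[b]] of X
  nat <- vapply(ref_atoms, nrow, 1L)
  atom_rows <- split(seq_len(sum(nat)), rep(seq_len(nb), nat))
  # restraint rows -> global atom rows (stack order must match X below)
  chain_body <- integer(length(model$chains))
  chain_local_off <- integer(length(model$chains))
  for (bi in seq_len(nb)) {
    off <- 0L
    for (ci in bodies[[bi]]$chain_idx) {
      chain_body[ci] <- bi
      chain_local_off[ci] <- off
      off <- off + nrow(model$chains[[ci]]$ca)
    }
  }
  ids <- vapply(model$chains, function(ch) ch$chain_id, "")
  global_row <- function(chain, res) {
    ci <- match(chain, ids)
    if (anyNA(ci)) stop("refine(): restraint references unknown chain")
    atom_rows_start <- vapply(seq_len(nb), function(b) atom_rows[[b]][1], 1L)
    atom_rows_start[chain_body[ci]] + chain_local_off[ci] + res - 1L
  }
  conn <- restraints$connectivity
  elas <- restraints$elastic
  conn_i <- if (!is.null(conn) && nrow(conn)) global_row(conn$chain_i, conn$res_i) else integer(0)
  conn_j <- if (!is.null(conn) && nrow(conn)) global_row(conn$chain_j, conn$res_j) else integer(0)
  elas_i <- if (!is.null(elas) && nrow(elas)) global_row(elas$chain_i, elas$res_i) else integer(0)
  elas_j <- if (!is.null(elas) && nrow(elas)) global_row(elas$chain_j, elas$res_j) else integer(0)

  # --- mutable state ---------------------------------------------------------
  poses <- replicate(nb, pose(), simplify = FALSE)
  atoms_cur <- ref_atoms
  beads_cur <- ref_beads
  X <- do.call(rbind, atoms_cur)
  renders <- lapply(seq_len(nb), function(bi) render_body(beads_cur[[bi]],
                                                          bead_w[[bi]], map,
                                                          restraints$bead_sigma))
  total_render <- Reduce(`+`, renders)
  clash_blocks <- matrix(0, nb, nb)
  if (nb > 1 && restraints$clash_k > 0) {
    for (i in 1:(nb - 1)) for (j in (i + 1):nb) {
      clash_blocks[i, j] <- clash_block(atoms_cur[[i]], atoms_cur[[j]],
                                        restraints$clash_radius,
                                        restraints$clash_k)
    }
  }
  comp <- function() {
    em <- 1 - ncc_precentred(map_c, map_n, total_render, n_vox)
    cl <- sum(clash_blocks)
    cn <- if (length(conn_i)) {
      dd <- sqrt(rowSums((X[conn_i, , drop = FALSE] - X[conn_j, , drop = FALSE])^2))
      sum(conn$k * pmax(0, dd - conn$max_length)^2)
    } else 0
    el <- if (length(elas_i)) {
      dd <- sqrt(rowSums((X[elas_i, , drop = FALSE] - X[elas_j, , drop = FALSE])^2))
      sum(elas$k * (dd - elas$rest_length)^2)
    } else 0
    if (!all(is.finite(c(em, cl, cn, el)))) {
      bad <- c("em_fit", "clash", "connectivity", "elastic")[
        !is.finite(c(em, cl, cn, el))]
      stop("refine(): non-finite component: ", paste(bad, collapse = ", "))
    }
    list(em_fit = em, clash = cl, connectivity = cn, elastic = el,
         total = restraints$em_weight * em + cl + cn + el)
  }
  cur <- comp()
  best <- list(total = cur$total, poses = poses)
  traj <- list()
  record <- function(step, s, best_total) {
    traj[[length(traj) + 1]] <<- data.frame(
      step = step, em_fit = s$em_fit, clash = s$clash,
      connectivity = s$connectivity, elastic = s$elastic,
      total = s$total, best_total = best_total)
  }
  record(0L, cur, best$total)
  step <- 0L
  t0 <- schedule$temperatures[1]
  with_seed(seed, {
    for (Tk in schedule$temperatures) {
      # move sizes anneal with the temperature for fine late-stage moves
      sc <- sqrt(Tk / t0)
      for (s_ in seq_len(schedule$steps_per_temp)) {
        step <- step + 1L
        # collective moves (all bodies as one) descend the EM term along
        # the assembly's rigid modes, which single-body moves cannot do
        # without paying elastic/connectivity penalties
        collective <- nb > 1 && runif(1) < 0.25
        dR <- random_small_rotation(max_step_rot * sc)
        dt <- runif(3, -max_step_trans * sc, max_step_trans * sc)
        targets <- if (collective) seq_len(nb) else sample.int(nb, 1)
        C_all <- if (collective) {
          Reduce(`+`, lapply(targets, function(b) cens[[b]])) / nb
        } else NULL
        old_poses <- poses[targets]
        prop_poses <- lapply(targets, function(bi) {
          p <- poses[[bi]]
          if (collective) {
            cb <- cens[[bi]]
            pose(dR %*% p$rotation,
                 as.numeric(dR %*% (cb + p$shift - C_all)) + C_all + dt - cb)
          } else {
            pose(dR %*% p$rotation, as.numeric(dR %*% p$shift) + dt)
          }
        })
        ok <- all(vapply(seq_along(targets), function(ii) {
          b <- bodies[[targets[ii]]]
          sqrt(sum(prop_poses[[ii]]$shift^2)) <= b$max_translation &&
            rotation_distance(prop_poses[[ii]]$rotation) <= b$max_rotation
        }, TRUE))
        if (!ok) next
        old_atoms <- atoms_cur[targets]
        old_beads <- beads_cur[targets]
        old_renders <- renders[targets]
        old_blocks <- clash_blocks
        for (ii in seq_along(targets)) {
          bi <- targets[ii]
          cen <- cens[[bi]]
          atoms_cur[[bi]] <- rigid_apply(ref_atoms[[bi]], prop_poses[[ii]], cen)
          beads_cur[[bi]] <- rigid_apply(ref_beads[[bi]], prop_poses[[ii]], cen)
          new_render <- render_body(beads_cur[[bi]], bead_w[[bi]], map,
                                    restraints$bead_sigma)
          total_render <- total_render - renders[[bi]] + new_render
          renders[[bi]] <- new_render
          X[atom_rows[[bi]], ] <- atoms_cur[[bi]]
        }
        if (nb > 1 && restraints$clash_k > 0) {
          for (bi in targets) {
            for (jj in seq_len(nb)) {
              if (jj == bi || (collective && jj < bi)) next
              v <- clash_block(atoms_cur[[bi]], atoms_cur[[jj]],
                               restraints$clash_radius, restraints$clash_k)
              if (jj < bi) clash_blocks[jj, bi] <- v else clash_blocks[bi, jj] <- v
            }
          }
        }
        cand <- comp()
        dE <- cand$total - cur$total
        if (dE <= 0 || runif(1) < exp(-dE / Tk)) {
          cur <- cand
          for (ii in seq_along(targets)) poses[[targets[ii]]] <- prop_poses[[ii]]
          if (cur$total < best$total) best <- list(total = cur$total,
                                                   poses = poses)
        } else {
          for (ii in seq_along(targets)) {
            bi <- targets[ii]
            total_render <- total_render - renders[[bi]] + old_renders[[ii]]
            atoms_cur[[bi]] <- old_atoms[[ii]]
            beads_cur[[bi]] <- old_beads[[ii]]
            renders[[bi]] <- old_renders[[ii]]
            X[atom_rows[[bi]], ] <- old_atoms[[ii]]
          }
          clash_blocks <- old_blocks
        }
        if (step %% 100 == 0) record(step, cur, best$total)
      }
    }
  })
  best_model <- apply_body_poses(model, bodies, best$poses)
  list(model = best_model, poses = best$poses,
       best = score_breakdown(best_model, map, restraints, bodies),
       trajectory = do.call(rbind, traj))
}

rigid_apply <- function(coords, p, cen) {
  t(p$rotation %*% (t(coords) - cen)) +
    matrix(cen + p$shift, nrow(coords), 3, byrow = TRUE)
}

render_body <- function(beads, w, map, bead_sigma) {
  pts <- phys_to_voxel(map, beads)
  as.numeric(cpp_render_gaussians(pts, w,
                                  rep(bead_sigma / map$voxel_size, nrow(pts)),
                                  dim(map$grid)))
}

clash_block <- function(A, B, radius, k) {
  d2 <- cross_dist2(A, B)
  sel <- d2 < (2 * radius)^2
  if (!any(sel)) return(0)
  k * sum((2 * radius - sqrt(pmax(d2[sel], 0)))^2)
}

ncc_precentred <- function(map_c, map_n, render_vec, n_vox) {
  r <- render_vec - sum(render_vec) / n_vox
  rn <- sqrt(sum(r^2))
  if (rn == 0 || map_n == 0) return(0)
  sum(map_c * r) / (map_n * rn)
}

#' @rdname refine
#' @param t_start,t_end,n_temps,steps_per_temp geometric cooling schedule.
#' @export
refine_schedule <- function(t_start = 2, t_end = 0.02, n_temps = 5,
                            steps_per_temp = 2000) {
  list(temperatures = t_start * (t_end / t_start)^(seq(0, 1, length.out = n_temps)),
       steps_per_temp = steps_per_temp)
}

#' Calpha RMSD between two models with identical chain topology
#'
#' @param a,b [scaffold_model()]s with matching chains.
#' @return RMSD in Angstrom.
#' @export
model_rmsd <- function(a, b) {
  stopifnot(length(a$chains) == length(b$chains))
  ss <- 0; n <- 0
  for (i in seq_along(a$chains)) {
    d <- a$chains[[i]]$ca - b$chains[[i]]$ca
    ss <- ss + sum(d^2)
    n <- n + nrow(d)
  }
  sqrt(ss / n)
}
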