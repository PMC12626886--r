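#' Load and validate a scaffold composition
#'
#' A composition lists, per ring (CR, IR, NR), the nucleoporin species
#' placed in one asymmetric unit with their copy numbers and subcomplex
#' labels, plus the ring symmetry order and a homologue map (e.g. the plant
#' ELYS homologue HOS1). Species joined by `"|"` (e.g. `"NUP93A|NUP93B"`)
#' are alternatives counted as one placement. Entries of one subcomplex
#' within a ring must share a copy number — that number is the subcomplex's
#' instance count per asymmetric unit.
#'
#' @param path JSON config file; [default_composition()] loads the packaged
#'   default encoding the AtNPC scaffold (20 NUP species; one Y-complex
#'   ring at the CR, two at the NR).
#' @return An object of class `"composition_config"`.
#' @export
load_composition <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  order <- raw$symmetry_order
  if (is.null(order) || !is.numeric(order) || order < 1) {
    stop("composition schema: 'symmetry_order' must be a number >= 1")
  }
  if (is.null(raw$rings) || !all(c("CR", "IR", "NR") %in% names(raw$rings))) {
    stop("composition schema: 'rings' must contain CR, IR and NR")
  }
  rings <- lapply(names(raw$rings), function(rn) {
    entries <- raw$rings[[rn]]
    if (length(entries) == 0) {
      return(data.frame(species = character(), copies = integer(),
                        subcomplex = character()))
    }
    df <- do.call(rbind, lapply(seq_along(entries), function(i) {
      e <- entries[[i]]
      for (f in c("species", "copies", "subcomplex")) {
        if (is.null(e[[f]])) {
          stop(sprintf("composition schema: rings.%s[%d] missing field '%s'",
                       rn, i, f))
        }
      }
      if (!is.numeric(e$copies) || e$copies < 1 || e$copies != round(e$copies)) {
        stop(sprintf("composition schema: rings.%s[%d].copies must be an integer >= 1",
                     rn, i))
      }
      data.frame(species = e$species, copies = as.integer(e$copies),
                 subcomplex = e$subcomplex)
    }))
    if (anyDuplicated(paste(df$species, df$subcomplex))) {
      stop(sprintf("composition schema: duplicate (species, subcomplex) entry in ring %s", rn))
    }
    for (sc in unique(df$subcomplex)) {
      if (length(unique(df$copies[df$subcomplex == sc])) != 1) {
        stop(sprintf(
          "composition schema: members of subcomplex '%s' in ring %s disagree on copies",
          sc, rn))
      }
    }
    df
  })
  names(rings) <- names(raw$rings)
  hmap <- lapply(raw$homologue_map, as.character)
  structure(list(symmetry_order = as.integer(order),
                 rings = rings[c("CR", "IR", "NR")],
                 homologue_map = hmap,
                 optional = raw$optional,
                 name = raw$name),
            class = "composition_config")
}

#' @rdname load_composition
#' @export
default_composition <- function() {
  load_composition(system.file("extdata", "atnpc_composition.json",
                               package = "porekit", mustWork = TRUE))
}

#' Save a composition config back to JSON
#'
#' `save_composition` then [load_composition()] round-trips to an equal
#' config.
#'
#' @param config a `"composition_config"`.
#' @param path output path.
#' @export
save_composition <- function(config, path) {
  stopifnot(inherits(config, "composition_config"))
  rings <- lapply(config$rings, function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      list(species = df$species[i], copies = df$copies[i],
           subcomplex = df$subcomplex[i])
    })
  })
  out <- list(name = config$name, symmetry_order = config$symmetry_order,
              homologue_map = config$homologue_map, rings = rings,
              optional = config$optional)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Distinct species in a composition
#'
#' Alternatives groups (`"A|B"`) count as one species.
#'
#' @param config a `"composition_config"`.
#' @return Character vector of species labels.
#' @export
composition_species <- function(config) {
  stopifnot(inherits(config, "composition_config"))
  sort(unique(unlist(lapply(config$rings, function(df) df$species))))
}

#' @export
print.composition_config <- function(x, ...) {
  cat(sprintf("<composition_config> %s\n", if (!is.null(x$name)) x$name else ""))
  cat(sprintf("  symmetry order %d, %d distinct species\n",
              x$symmetry_order, length(composition_species(x))))
  for (rn in names(x$rings)) {
    df <- x$rings[[rn]]
    cat(sprintf("  %s: %d entries, %d chains per asymmetric unit\n",
                rn, nrow(df), sum(df$copies)))
  }
  invisible(x)
}

#' Scaffold model container
#'
#' A multi-chain Calpha coordinate model. Each chain carries its
#' nucleoporin species, ring (CR/IR/NR), subcomplex label, copy index
#' within the asymmetric unit, asymmetric-unit index, and an `n x 3`
#' Calpha coordinate matrix (Angstrom). The coarse 10-residue-bead
#' representation is derived with [coarse_beads()]. The coordinate frame
#' puts the pore axis along the third axis with the nucleoplasm at
#' negative third coordinate (so the NR sits below the CR).
#'
#' @param chains list of chain records (`chain_id`, `species`, `ring`,
#'   `subcomplex`, `copy_index`, `asym_unit`, `ca`).
#' @param symmetry_order the symmetry order the model belongs to.
#' @return An object of class `"scaffold_model"`.
#' @export
scaffold_model <- function(chains, symmetry_order = 8) {
  ids <- vapply(chains, function(ch) ch$chain_id, "")
  if (anyDuplicated(ids)) {
    stop("scaffold_model(): overlapping chain ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (ch in chains) {
    stopifnot(is.matrix(ch$ca), ncol(ch$ca) == 3,
              ch$ring %in% c("CR", "IR", "NR"))
  }
  structure(list(chains = chains, symmetry_order = as.integer(symmetry_order)),
            class = "scaffold_model")
}

#' @export
print.scaffold_model <- function(x, ...) {
  nres <- sum(vapply(x$chains, function(ch) nrow(ch$ca), 1L))
  cat(sprintf("<scaffold_model> %d chains, %d residues, symmetry order %d\n",
              length(x$chains), nres, x$symmetry_order))
  invisible(x)
}

#' Ten-residue coarse beads of a chain
#'
#' Consecutive 10-residue fragments are represented by their centroid;
#' a chain of n residues yields `ceiling(n/10)` beads.
#'
#' @param chain a chain record of a [scaffold_model()].
#' @return `m x 3` matrix of bead coordinates.
#' @export
coarse_beads <- function(chain) {
  ca <- chain$ca
  n <- nrow(ca)
  groups <- ceiling(seq_len(n) / 10)
  out <- rowsum(ca, groups) / as.numeric(table(groups))
  unname(out)
}

#' Place toy chains for a composition
#'
#' Builds one asymmetric unit of simple helical Calpha dummies at the
#' stated ring radii — deterministic stand-ins for predicted subunit
#' structures, sufficient to exercise stoichiometry accounting, composite
#' assembly and rigid-body refinement. Chains within the unit are spread
#' over the 360/order-degree wedge with radial and axial staggering so no
#' two chains approach closer than 4 Angstrom; a small seed-dependent
#' azimuthal jitter varies placements between seeds without changing the
#' topology.
#'
#' @param composition a `"composition_config"`.
#' @param ring_radius named radii (Angstrom) per ring.
#' @param ring_z named axial offsets (Angstrom) per ring; NR negative
#'   (nucleoplasmic side).
#' @param residues_per_chain helix length in residues.
#' @param seed integer seed for the azimuthal jitter.
#' @return A [scaffold_model()] with `asym_unit = 0` chains.
#' @export
place_toy_chains <- function(composition,
                             ring_radius = c(CR = 380, IR = 300, NR = 380),
                             ring_z = c(CR = 120, IR = 0, NR = -120),
                             residues_per_chain = 40, seed = 0) {
  stopifnot(inherits(composition, "composition_config"))
  order <- composition$symmetry_order
  wedge_deg <- 360 / order
  chains <- list()
  with_seed(seed, {
    for (rn in names(composition$rings)) {
      df <- composition$rings[[rn]]
      if (nrow(df) == 0) next
      slots <- list()
      for (i in seq_len(nrow(df))) {
        for (cp in seq_len(df$copies[i])) {
          slots[[length(slots) + 1]] <-
            list(species = df$species[i], subcomplex = df$subcomplex[i],
                 copy_index = cp)
        }
      }
      m <- length(slots)
      span <- 0.8 * wedge_deg
      for (s in seq_along(slots)) {
        az <- -span / 2 + span * (s - 1) / max(1, m - 1) + runif(1, -0.5, 0.5)
        r <- ring_radius[[rn]] + 30 * ((s %% 3) - 1)
        z0 <- ring_z[[rn]] + 25 * ((s %% 2) - 0.5)
        anchor <- c(r * cos(az * pi / 180), r * sin(az * pi / 180), z0)
        ca <- helix_ca(residues_per_chain, anchor)
        sl <- slots[[s]]
        chains[[length(chains) + 1]] <- list(
          chain_id = sprintf("%s.au0.%s.%s.%d", rn, sl$subcomplex,
                             sl$species, sl$copy_index),
          species = sl$species, ring = rn, subcomplex = sl$subcomplex,
          copy_index = sl$copy_index, asym_unit = 0L, ca = ca)
      }
    }
  })
  model <- scaffold_model(chains, symmetry_order = order)
  dmin <- min_interchain_distance(model)
  if (dmin <= 4) {
    stop(sprintf("place_toy_chains(): infeasible packing, min inter-chain Calpha distance %.2f A <= 4 A", dmin))
  }
  model
}

# Ideal alpha-helix Calpha trace along the pore axis, centred on `anchor`.
helix_ca <- function(n, anchor) {
  i <- seq_len(n)
  t <- (i - (n + 1) / 2) * 1.5          # 1.5 A rise per residue
  a <- i * 100 * pi / 180               # 100 degrees per residue
  cbind(anchor[1] + 2.3 * cos(a), anchor[2] + 2.3 * sin(a), anchor[3] + t)
}

min_interchain_distance <- function(model) {
  ch <- model$chains
  if (length(ch) < 2) return(Inf)
  dmin <- Inf
  for (i in seq_along(ch)[-length(ch)]) {
    for (j in (i + 1):length(ch)) {
      d2 <- min(cross_dist2(ch[[i]]$ca, ch[[j]]$ca))
      if (d2 < dmin^2) dmin <- sqrt(d2)
    }
  }
  dmin
}

# Squared distances between rows of A and rows of B.
cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
}

#' Expand an asymmetric unit by rotational symmetry
#'
#' For a [scaffold_model()], emits `symmetry_order` copies of every chain
#' related by rotations of `k * 360/order` degrees about the pore axis,
#' with unique chain ids and asymmetric-unit indices. For a list of
#' [density_volume()]s, the composite map is the voxelwise maximum over
#' the rotated copies (max-combination avoids double-counting overlapping
#' ring maps).
#'
#' @param x a `"scaffold_model"` or a list of [density_volume()]s.
#' @param symmetry_order copies to emit; `1` is the identity.
#' @return Expanded model or composite [density_volume()].
#' @export
assemble_composite <- function(x, symmetry_order = 8) {
  UseMethod("assemble_composite")
}

#' @export
assemble_composite.scaffold_model <- function(x, symmetry_order = 8) {
  stopifnot(symmetry_order >= 1)
  if (symmetry_order == 1) return(x)
  chains <- list()
  for (k in 0:(symmetry_order - 1)) {
    Rk <- rot_z(k * 360 / symmetry_order)
    for (ch in x$chains) {
      ch2 <- ch
      ch2$ca <- t(Rk %*% t(ch$ca))
      ch2$asym_unit <- k
      ch2$chain_id <- sub("\\.au[0-9]+\\.", sprintf(".au%d.", k), ch$chain_id)
      if (identical(ch2$chain_id, ch$chain_id) && k > 0) {
        ch2$chain_id <- sprintf("%s.au%d", ch$chain_id, k)
      }
      chains[[length(chains) + 1]] <- ch2
    }
  }
  scaffold_model(chains, symmetry_order = x$symmetry_order)
}

#' @export
assemble_composite.list <- function(x, symmetry_order = 8) {
  stopifnot(length(x) >= 1, all(vapply(x, inherits, TRUE, "density_volume")))
  out <- NULL
  for (k in 0:(symmetry_order - 1)) {
    Rk <- rot_z(k * 360 / symmetry_order)
    for (v in x) {
      vr <- if (k == 0) v else rotate_volume(v, Rk)
      out <- if (is.null(out)) vr else {
        check_same_grid(out, vr, "assemble_composite")
        density_volume(pmax(out$grid, vr$grid), v$voxel_size, v$origin)
      }
    }
  }
  out
}

#' Stoichiometry accounting
#'
#' Counts chains (by species) or subcomplex instances in a scaffold model.
#' A subcomplex instance is a distinct `(ring, asymmetric unit, subcomplex,
#' copy index)` combination. Counts at `scope = "whole"` or `"ring"` are
#' scaled to the full pore: a model holding only one asymmetric unit is
#' multiplied by its symmetry order.
#'
#' @param model a [scaffold_model()].
#' @param group_by `"species"` or `"subcomplex"`.
#' @param scope `"asym_unit"` (one asymmetric unit), `"ring"` (per ring,
#'   whole pore) or `"whole"` (whole pore, all rings pooled).
#' @param ring optionally restrict to one ring.
#' @return `data.frame` with the grouping columns and `count`.
#' @export
stoichiometry <- function(model, group_by = c("species", "subcomplex"),
                          scope = c("asym_unit", "ring", "whole"),
                          ring = NULL) {
  stopifnot(inherits(model, "scaffold_model"))
  group_by <- match.arg(group_by)
  scope <- match.arg(scope)
  ch <- model$chains
  if (!is.null(ring)) {
    stopifnot(ring %in% c("CR", "IR", "NR"))
    ch <- Filter(function(c_) c_$ring == ring, ch)
  }
  if (length(ch) == 0) {
    cols <- if (scope == "ring") c("ring", group_by) else group_by
    out <- setNames(rep(list(character(0)), length(cols)), cols)
    out$count <- numeric(0)
    return(as.data.frame(out))
  }
  df <- data.frame(
    ring = vapply(ch, function(c_) c_$ring, ""),
    asym_unit = vapply(ch, function(c_) c_$asym_unit, 0L),
    species = vapply(ch, function(c_) c_$species, ""),
    subcomplex = vapply(ch, function(c_) c_$subcomplex, ""),
    copy_index = vapply(ch, function(c_) c_$copy_index, 0L))
  n_units <- length(unique(df$asym_unit))
  scale_to_whole <- model$symmetry_order / n_units
  if (scope == "asym_unit") {
    df <- df[df$asym_unit == min(df$asym_unit), , drop = FALSE]
    scale <- 1
  } else {
    scale <- scale_to_whole
  }
  if (group_by == "subcomplex") {
    inst <- unique(df[, c("ring", "asym_unit", "subcomplex", "copy_index")])
    keys <- if (scope == "ring") c("ring", "subcomplex") else "subcomplex"
    agg <- stats::aggregate(list(count = rep(1, nrow(inst))),
                            inst[, keys, drop = FALSE], sum)
  } else {
    keys <- if (scope == "ring") c("ring", "species") else "species"
    agg <- stats::aggregate(list(count = rep(1, nrow(df))),
                            df[, keys, drop = FALSE], sum)
  }
  agg$count <- agg$count * scale
  agg[do.call(base::order, agg[keys]), , drop = FALSE]
}
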