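#' Estimate a pore centre by least-squares line intersection
#'
#' Each subunit defines a 3D line through its position along its inward
#' direction vector. The centre is the point minimizing the sum of squared
#' perpendicular distances to all lines (the normal-equations solution of
#' `sum_i (I - d_i d_i^T) (c - p_i) = 0`). When the lines are concurrent
#' this is their exact intersection.
#'
#' @param subunits `data.frame` with columns `x, y, z` (positions,
#'   Angstrom) and `dx, dy, dz` (unit inward directions), one row per
#'   subunit of a single pore.
#' @return Numeric centre `c(x, y, z)`.
#' @export
estimate_centre <- function(subunits) {
  stopifnot(nrow(subunits) >= 2)
  P <- as.matrix(subunits[, c("x", "y", "z")])
  D <- as.matrix(subunits[, c("dx", "dy", "dz")])
  D <- D / sqrt(rowSums(D^2))
  A <- matrix(0, 3, 3)
  b <- numeric(3)
  for (i in seq_len(nrow(P))) {
    M <- diag(3) - tcrossprod(D[i, ])
    A <- A + M
    b <- b + as.numeric(M %*% P[i, ])
  }
  if (rcond(A) < 1e-10) {
    stop("estimate_centre(): degenerate geometry (all direction lines parallel)")
  }
  as.numeric(solve(A, b))
}

#' Per-pore geometry from subunit observations
#'
#' Pores with fewer than `min_occupancy` observed subunits are rejected
#' (a typed rejection record, not an error). For admissible pores the
#' centre is estimated by [estimate_centre()], the mean radius is the
#' average distance from the centre to each subunit, and the diameter is
#' twice the mean radius plus an optional constant membrane offset.
#' Distances between opposing subunits (index `i` vs `i + 4 mod 8`, where
#' both are present) are reported as diagnostics only.
#'
#' @param subunits `data.frame` rows for one pore (columns `npc_id`,
#'   `subunit_index`, `x, y, z`, `dx, dy, dz`).
#' @param min_occupancy minimum subunit count (default 5).
#' @param membrane_offset constant added to the diameter to convert
#'   subunit-centre measurements to membrane-to-membrane ones; default 0
#'   (report subunit-centre diameters).
#' @param n_subunits ring symmetry order.
#' @return An object of class `"pore_geometry"` (`npc_id`, `centre`,
#'   `mean_radius`, `diameter`, `occupancy`, `opposing_distances`) or of
#'   class `"pore_rejection"` when occupancy is insufficient.
#' @export
pore_diameter <- function(subunits, min_occupancy = 5, membrane_offset = 0,
                          n_subunits = 8) {
  stopifnot(length(unique(subunits$npc_id)) == 1)
  npc_id <- subunits$npc_id[1]
  occ <- nrow(subunits)
  if (occ < min_occupancy) {
    return(structure(list(npc_id = npc_id, occupancy = occ,
                          reason = sprintf("occupancy %d < %d", occ, min_occupancy)),
                     class = "pore_rejection"))
  }
  centre <- estimate_centre(subunits)
  P <- as.matrix(subunits[, c("x", "y", "z")])
  radii <- sqrt(rowSums(sweep(P, 2, centre)^2))
  mean_radius <- mean(radii)
  opp <- numeric(0)
  half <- n_subunits / 2
  idx <- subunits$subunit_index
  for (i in idx) {
    j <- (i + half) %% n_subunits
    if (j > i && j %in% idx) {
      pi_ <- P[match(i, idx), ]
      pj_ <- P[match(j, idx), ]
      opp <- c(opp, sqrt(sum((pi_ - pj_)^2)))
    }
  }
  structure(list(npc_id = npc_id, centre = centre, mean_radius = mean_radius,
                 diameter = 2 * mean_radius + membrane_offset,
                 occupancy = occ, opposing_distances = opp),
            class = "pore_geometry")
}

#' Diameter distribution over a subunit table
#'
#' Applies [pore_diameter()] to every pore in the table and summarizes the
#' admissible diameters.
#'
#' @param table subunit `data.frame` as from [simulate_subunit_table()].
#' @param min_occupancy,membrane_offset,n_subunits passed to
#'   [pore_diameter()].
#' @return `list(geometries, rejected, per_npc, summary)` where `per_npc`
#'   is a `data.frame` (npc_id, occupancy, diameter, mean_radius) of
#'   admissible pores and `summary` is `list(mean, sd, n, n_rejected)`
#'   (with `n = 0` and `NA` moments when nothing is admissible).
#' @export
diameter_distribution <- function(table, min_occupancy = 5,
                                  membrane_offset = 0, n_subunits = 8) {
  ids <- unique(table$npc_id)
  geoms <- list()
  rejected <- list()
  for (id in ids) {
    g <- pore_diameter(table[table$npc_id == id, , drop = FALSE],
                       min_occupancy = min_occupancy,
                       membrane_offset = membrane_offset,
                       n_subunits = n_subunits)
    if (inherits(g, "pore_rejection")) {
      rejected[[length(rejected) + 1]] <- g
    } else {
      geoms[[length(geoms) + 1]] <- g
    }
  }
  per_npc <- if (length(geoms)) {
    data.frame(npc_id = vapply(geoms, function(g) g$npc_id, 1),
               occupancy = vapply(geoms, function(g) g$occupancy, 1L),
               mean_radius = vapply(geoms, function(g) g$mean_radius, 1),
               diameter = vapply(geoms, function(g) g$diameter, 1))
  } else {
    data.frame(npc_id = numeric(), occupancy = integer(),
               mean_radius = numeric(), diameter = numeric())
  }
  summary <- list(
    mean = if (nrow(per_npc)) mean(per_npc$diameter) else NA_real_,
    sd = if (nrow(per_npc) > 1) sd(per_npc$diameter) else NA_real_,
    n = nrow(per_npc),
    n_rejected = length(rejected))
  list(geometries = geoms, rejected = rejected, per_npc = per_npc,
       summary = summary)
}
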