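# Shared fixtures and independent oracles. Everything here is deliberately
# written without reusing the package's implementation paths wherever it
# serves as an oracle (brute-force scorers use their own interpolation and
# correlation code).

# A small random volume.
rand_volume <- function(n = 16, voxel = 4, seed = 1, sigma = 1) {
  set.seed(seed)
  density_volume(array(rnorm(n^3, 0, sigma), rep(n, 3)), voxel)
}

# Single-spoke asymmetric test complex: no rotational degeneracy, so pose
# recovery is well defined. Geometry scales with the box so the blob
# cluster always fits.
spoke_reference <- function(box = 32, voxel = 16, membrane = 240) {
  L <- box * voxel
  make_complex(ground_truth_complex(
    n_spokes = 1, ring_radius = 0.1 * L,
    spoke_blob_spec = list(
      list(offset = c(0, 0, 0), sigma = 0.075 * L, amplitude = 1),
      list(offset = c(-0.05, 0.08, 0.06) * L, sigma = 0.055 * L,
           amplitude = 0.9),
      list(offset = c(0.04, -0.07, -0.08) * L, sigma = 0.045 * L,
           amplitude = 0.7)),
    membrane_spacing = membrane),
    box_size = box, voxel_size = voxel)$volume
}

# --- independent trilinear rotation (oracle-side; pure R) ----------------

oracle_rotate <- function(grid, R) {
  d <- dim(grid)
  cv <- (d - 1) / 2
  out <- array(0, d)
  Rinv <- t(R)
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  src <- t(Rinv %*% (t(idx) - cv) + cv)
  for (n in seq_len(nrow(idx))) {
    p <- src[n, ]
    if (any(p < 0) || any(p > d - 1)) next
    f <- floor(p); w <- p - f
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      i <- pmin(f + c(dx, dy, dz), d - 1) + 1
      wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
      acc <- acc + wt * grid[i[1], i[2], i[3]]
    }
    out[idx[n, 1] + 1, idx[n, 2] + 1, idx[n, 3] + 1] <- acc
  }
  out
}

# Brute-force alignment oracle: scores every grid pose (and every integer
# shift within the limit) by direct masked Pearson correlation between the
# wedge-filtered rotated reference and the particle.
oracle_align <- function(particle, reference, rotations, wedge,
                         shift_vox = 0, mask = NULL) {
  n <- dim(particle$grid)[1]
  wm <- oracle_wedge_mask(n, wedge)
  m <- if (is.null(mask)) array(TRUE, dim(particle$grid)) else mask$grid > 0.5
  shifts <- expand.grid(sx = -shift_vox:shift_vox, sy = -shift_vox:shift_vox,
                        sz = -shift_vox:shift_vox)
  best <- list(cc = -Inf)
  for (ri in seq_along(rotations)) {
    rr <- oracle_rotate(reference$grid, rotations[[ri]])
    rw <- Re(fft(fft(rr) * wm, inverse = TRUE)) / n^3
    for (si in seq_len(nrow(shifts))) {
      s <- as.integer(shifts[si, ])
      shifted <- oracle_shift(rw, s)
      cc <- suppressWarnings(stats::cor(shifted[m], particle$grid[m]))
      if (!is.na(cc) && cc > best$cc + 1e-12) {
        best <- list(cc = cc, rotation = rotations[[ri]], idx = ri,
                     shift = s)
      }
    }
  }
  best
}

# Integer circular shift moving content by +s voxels.
oracle_shift <- function(grid, s) {
  d <- dim(grid)
  idx <- lapply(1:3, function(a) ((0:(d[a] - 1)) - s[a]) %% d[a] + 1)
  grid[idx[[1]], idx[[2]], idx[[3]]]
}

# Independent wedge mask built from first principles (angle of the
# (axis1, axis3) projection measured from axis3).
oracle_wedge_mask <- function(n, wedge) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  m <- array(1, rep(n, 3))
  for (i in 1:n) for (kk in 1:n) {
    ang <- atan2(k[i], k[kk]) * 180 / pi
    if (ang > 90) ang <- ang - 180
    if (ang <= -90) ang <- ang + 180
    if (ang > wedge$tilt_max || ang < wedge$tilt_min) m[i, , kk] <- 0
  }
  m
}

# Grid-search oracle for the pore-centre least-squares objective.
oracle_centre_grid <- function(subunits, span = 40, pitch = 1) {
  P <- as.matrix(subunits[, c("x", "y", "z")])
  D <- as.matrix(subunits[, c("dx", "dy", "dz")])
  D <- D / sqrt(rowSums(D^2))
  obj <- function(c_) {
    v <- sweep(P, 2, c_, "-")
    perp <- v - D * rowSums(v * D)
    sum(perp^2)
  }
  c0 <- colMeans(P)
  g <- seq(-span, span, by = pitch)
  best <- list(val = Inf)
  for (dx in g) for (dy in g) for (dz in g) {
    cand <- c0 + c(dx, dy, dz)
    v <- obj(cand)
    if (v < best$val) best <- list(val = v, centre = cand)
  }
  best$centre
}

# Rotation-search oracle for minimal RMSD superposition: a coarse global
# scan over random rotations followed by hierarchical zoom around the best
# one. Independent of the SVD solution.
oracle_rmsd_grid <- function(A, B, n_coarse = 800, n_zoom = 200) {
  cp <- colMeans(A); cq <- colMeans(B)
  Ac <- sweep(A, 2, cp); Bc <- sweep(B, 2, cq)
  rmsd_of <- function(R) sqrt(mean(rowSums((t(R %*% t(Ac)) - Bc)^2)))
  set.seed(99)
  best <- list(val = rmsd_of(diag(3)), R = diag(3))
  for (i in seq_len(n_coarse)) {
    u <- runif(3)
    q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
           sqrt(1 - u[1]) * cos(2 * pi * u[2]),
           sqrt(u[1]) * sin(2 * pi * u[3]),
           sqrt(u[1]) * cos(2 * pi * u[3]))
    q <- q / sqrt(sum(q^2))
    R <- porekit:::quat_to_matrix(q)
    v <- rmsd_of(R)
    if (v < best$val) best <- list(val = v, R = R)
  }
  for (scale in c(30, 10, 3, 1, 0.3, 0.1, 0.03)) {
    for (i in seq_len(n_zoom)) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      R <- porekit::axis_angle_matrix(ax, runif(1, 0, scale)) %*% best$R
      v <- rmsd_of(R)
      if (v < best$val) best <- list(val = v, R = R)
    }
  }
  best$val
}

# helical Calpha fixture (mirrors the package's toy-chain geometry)
helix_ca <- function(n, anchor) porekit:::helix_ca(n, anchor)

# Position-by-position tryptic digestion oracle.
oracle_digest <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  peps <- character(0)
  cur <- ""
  for (i in seq_along(aa)) {
    cur <- paste0(cur, aa[i])
    is_site <- aa[i] %in% c("K", "R") &&
      (i == length(aa) || aa[i + 1] != "P")
    if (is_site) {
      peps <- c(peps, cur)
      cur <- ""
    }
  }
  if (nzchar(cur)) peps <- c(peps, cur)
  peps
}

# Toy subunit table: perfect octagon of a given radius/centre/orientation.
octagon_table <- function(radius = 350, centre = c(0, 0, 0), R = diag(3),
                          npc_id = 1, idx = 0:7) {
  ang <- idx * pi / 4
  local <- cbind(radius * cos(ang), radius * sin(ang), 0)
  posn <- t(R %*% t(local)) + matrix(centre, length(idx), 3, byrow = TRUE)
  dirs <- matrix(centre, length(idx), 3, byrow = TRUE) - posn
  dirs <- dirs / sqrt(rowSums(dirs^2))
  data.frame(npc_id = npc_id, subunit_index = idx,
             x = posn[, 1], y = posn[, 2], z = posn[, 3],
             dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3])
}
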