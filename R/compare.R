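#' Ordered Calpha coordinate set
#'
#' @param coords `n x 3` matrix of Calpha coordinates, Angstrom.
#' @param resno residue numbering (default 1..n).
#' @param confidence optional per-residue confidence.
#' @return An object of class `"coord_set"`.
#' @export
coord_set <- function(coords, resno = seq_len(nrow(coords)),
                      confidence = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, length(resno) == nrow(coords))
  structure(list(coords = coords, resno = as.integer(resno),
                 confidence = confidence),
            class = "coord_set")
}

as_coord_matrix <- function(x) {
  if (inherits(x, "coord_set")) x$coords else as.matrix(x)
}

#' Kabsch superposition
#'
#' Finds the rigid transform of `A` minimizing the RMSD to `B` over the
#' given correspondence (SVD solution, reflection-corrected). Collinear or
#' otherwise degenerate sets (a vanishing covariance singular value) still
#' return the SVD optimum but with a warning, since the in-plane component
#' of the rotation is then arbitrary.
#'
#' @param A,B [coord_set()]s or coordinate matrices.
#' @param correspondence two-column matrix of row indices (A, B); default
#'   1:1 by order (equal lengths required).
#' @return `list(rotation, translation, rmsd)`: `rotation %*% a +
#'   translation` superposes A onto B.
#' @export
kabsch_superpose <- function(A, B, correspondence = NULL) {
  A <- as_coord_matrix(A); B <- as_coord_matrix(B)
  if (is.null(correspondence)) {
    stopifnot(nrow(A) == nrow(B))
    correspondence <- cbind(seq_len(nrow(A)), seq_len(nrow(B)))
  }
  if (nrow(correspondence) < 3) {
    stop("kabsch_superpose(): need at least 3 corresponding points")
  }
  P <- A[correspondence[, 1], , drop = FALSE]
  Q <- B[correspondence[, 2], , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  if (min(sv$d) < 1e-8 * max(sv$d, 1e-300)) {
    warning("kabsch_superpose(): degenerate (near-collinear) point set; rotation not unique")
  }
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cq - as.numeric(Rm %*% cp)
  Pt <- t(Rm %*% t(P)) + matrix(tr, nrow(P), 3, byrow = TRUE)
  list(rotation = Rm, translation = tr,
       rmsd = sqrt(mean(rowSums((Pt - Q)^2))))
}

#' TM-score distance scale
#'
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom for short
#' targets (L <= 21).
#'
#' @param L_target normalizing length.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L_target) {
  if (L_target > 21) max(0.5, 1.24 * (L_target - 15)^(1 / 3) - 1.8) else 0.5
}

#' TM-score at a fixed residue correspondence
#'
#' `TM = (1/L_target) * sum_i 1 / (1 + (d_i/d0)^2)` maximized over rigid
#' superpositions. The search seeds superpositions from contiguous
#' fragments of several lengths and iteratively re-superposes on the
#' subset of close pairs, in the spirit of TM-align's score refinement —
#' the sequence-independent alignment search itself is out of scope, so a
#' correspondence (default 1:1 by order) must be supplied.
#'
#' @param A,B [coord_set()]s or coordinate matrices.
#' @param correspondence two-column index matrix; default 1:1.
#' @param L_target normalizing length; default the length of `B` (the
#'   reference).
#' @return An object of class `"tm_result"`: `list(tm_score, rmsd,
#'   aligned_length, d0, L_target)`.
#' @export
tm_score <- function(A, B, correspondence = NULL, L_target = NULL) {
  Am <- as_coord_matrix(A); Bm <- as_coord_matrix(B)
  if (is.null(correspondence)) {
    stopifnot(nrow(Am) == nrow(Bm))
    correspondence <- cbind(seq_len(nrow(Am)), seq_len(nrow(Bm)))
  }
  if (nrow(correspondence) == 0) stop("tm_score(): empty correspondence")
  if (is.null(L_target)) L_target <- nrow(Bm)
  d0 <- tm_d0(L_target)
  P <- Am[correspondence[, 1], , drop = FALSE]
  Q <- Bm[correspondence[, 2], , drop = FALSE]
  n <- nrow(P)
  score_of <- function(sub) {
    # superpose on `sub`, iterate inclusion of close pairs, return best TM
    best <- 0
    for (iter in 1:20) {
      if (length(sub) < 3) break
      # short contiguous seeds are often near-collinear; the degeneracy
      # warning is expected here and the iteration self-corrects
      k <- suppressWarnings(kabsch_superpose(P, Q, cbind(sub, sub)))
      Pt <- t(k$rotation %*% t(P)) + matrix(k$translation, n, 3, byrow = TRUE)
      d <- sqrt(rowSums((Pt - Q)^2))
      tm <- sum(1 / (1 + (d / d0)^2)) / L_target
      if (tm > best) best <- tm
      new_sub <- which(d < max(d0, 3))
      if (length(new_sub) < 3 || identical(new_sub, sub)) break
      sub <- new_sub
    }
    best
  }
  best_tm <- 0
  for (frag in unique(pmax(4, c(n, floor(n / 2), floor(n / 4))))) {
    starts <- unique(floor(seq(1, n - frag + 1, length.out = 6)))
    for (s in starts) {
      tm <- score_of(s:(s + frag - 1))
      if (tm > best_tm) best_tm <- tm
    }
  }
  k <- kabsch_superpose(P, Q)
  structure(list(tm_score = min(1, best_tm), rmsd = k$rmsd,
                 aligned_length = n, d0 = d0, L_target = L_target),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("<tm_result> TM = %.4f (L = %d, d0 = %.2f A), rmsd = %.2f A over %d residues\n",
              x$tm_score, x$L_target, x$d0, x$rmsd, x$aligned_length))
  invisible(x)
}

#' Split a coordinate set into domains
#'
#' @param coords a [coord_set()].
#' @param ranges list of `c(start, end)` residue-number ranges;
#'   non-overlapping and within the numbering.
#' @return List of [coord_set()]s preserving residue numbering.
#' @export
split_domains <- function(coords, ranges) {
  stopifnot(inherits(coords, "coord_set"))
  taken <- integer(0)
  out <- lapply(ranges, function(rg) {
    stopifnot(length(rg) == 2, rg[1] <= rg[2])
    sel <- which(coords$resno >= rg[1] & coords$resno <= rg[2])
    if (length(sel) == 0 || rg[1] < min(coords$resno) || rg[2] > max(coords$resno)) {
      stop(sprintf("split_domains(): range %d-%d outside residue numbering", rg[1], rg[2]))
    }
    if (any(sel %in% taken)) {
      stop(sprintf("split_domains(): range %d-%d overlaps a previous range", rg[1], rg[2]))
    }
    taken <<- c(taken, sel)
    coord_set(coords$coords[sel, , drop = FALSE], coords$resno[sel],
              if (!is.null(coords$confidence)) coords$confidence[sel])
  })
  out
}
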