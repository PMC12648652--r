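# Deterministic single-conformer embedding.
#
# One conformer per species, reproducible bit-for-bit for a given
# (structure, seed) pair. Coordinates are generated by classical distance
# geometry: exact distances for bonded pairs (covalent-radius bond length
# table), geminal pairs (ideal angles by hybridisation) and aromatic rings
# (planar polygon distances); triangle-smoothed upper bounds and steric
# lower bounds elsewhere. A seeded metric-matrix embedding is refined by
# deterministic pairwise corrections. The goal is a chemically sane, fully
# reproducible 3D pose for geometric scoring and interaction profiling,
# not a force-field-quality conformation.

.COV_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20,
                I = 1.39)

# idealised bond length (Angstrom) for an element pair and Kekule order
.bond_length <- function(e1, e2, order) {
  r1 <- .COV_RADII[[e1]]; r2 <- .COV_RADII[[e2]]
  if (is.null(r1)) r1 <- 0.77
  if (is.null(r2)) r2 <- 0.77
  len <- r1 + r2
  if (order == 2L) len <- len - 0.14
  if (order == 3L) len <- len - 0.24
  len
}

.hyb_angle <- function(h) c(180, 120, 109.471)[h]

# Distance bounds matrices (lower, upper) for an explicit-H molecular graph.
.dg_bounds <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- .mol_adj(mol)
  hyb <- .hybridization(mol)
  BIG <- 999
  L <- matrix(0, n, n)
  U <- matrix(BIG, n, n)
  diag(U) <- 0
  set_exact <- function(i, j, d) {
    L[i, j] <<- d; L[j, i] <<- d
    U[i, j] <<- d; U[j, i] <<- d
  }
  # 1-2: bond lengths
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]
    set_exact(i, j, .bond_length(mol$atoms$elem[i], mol$atoms$elem[j],
                                 b$order[k]))
  }
  # 1-3: law of cosines with the central atom's ideal angle
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    theta <- .hyb_angle(hyb[j]) * pi / 180
    for (p in seq_len(length(nb) - 1L)) {
      for (q in (p + 1L):length(nb)) {
        i <- nb[p]; k <- nb[q]
        dij <- U[i, j]; djk <- U[j, k]
        d <- sqrt(dij^2 + djk^2 - 2 * dij * djk * cos(theta))
        if (U[i, k] >= BIG) set_exact(i, k, d)
      }
    }
  }
  # aromatic rings: exact planar polygon distances
  for (r in .aromatic_rings(mol)) {
    m <- length(r)
    blen <- mean(vapply(seq_len(m), function(i) {
      U[r[i], r[i %% m + 1L]]
    }, 0))
    circ <- blen / (2 * sin(pi / m))
    for (p in seq_len(m - 1L)) {
      for (q in (p + 1L):m) {
        sep <- min(q - p, m - (q - p))
        d <- 2 * circ * sin(sep * pi / m)
        set_exact(r[p], r[q], d)
      }
    }
  }
  # steric lower bounds for unconstrained pairs
  radii <- .COV_RADII[mol$atoms$elem]
  radii[is.na(radii)] <- 0.77
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (L[i, j] == 0) {
        lo <- 0.9 * (radii[i] + radii[j]) + 0.6
        L[i, j] <- L[j, i] <- min(lo, U[i, j])
      }
    }
  }
  # triangle smoothing of upper bounds (Floyd-Warshall)
  for (k in seq_len(n)) {
    Uk <- outer(U[, k], U[k, ], `+`)
    U <- pmin(U, Uk)
  }
  L <- pmin(L, U)
  list(L = L, U = U)
}

#' Embed one deterministic 3D conformer
#'
#' Generates exactly one conformer with explicit hydrogens. The same
#' structure and seed always produce identical coordinates.
#'
#' @param structure a SMILES string or an `fl_mol`.
#' @param seed integer seed controlling the distance-sampling stage.
#' @return an `fl_mol` with 3D coordinates and explicit hydrogens.
#' @export
embed_conformer <- function(structure, seed = 42L) {
  mol <- if (inherits(structure, "fl_mol")) structure
         else mol_from_smiles(structure)
  mol <- add_hydrogens(mol)
  n <- nrow(mol$atoms)
  if (n == 1L) {
    mol$atoms$x <- mol$atoms$y <- mol$atoms$z <- 0
    return(mol)
  }
  bounds <- .dg_bounds(mol)
  L <- bounds$L; U <- bounds$U
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647L))
  # sample a distance matrix within bounds
  D <- L + (U - L) * matrix(stats::runif(n * n), n, n)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  diag(D) <- 0
  # metric-matrix embedding into 3 dimensions
  D2 <- D^2
  d0 <- rowMeans(D2) - sum(D2) / (2 * n^2)
  G <- (outer(d0, d0, `+`) - D2) / 2
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values[1:3], 0)
  X <- eg$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(ev), 3L)
  # refinement: deterministic sweeps correcting bound violations
  pairs <- which(upper.tri(U), arr.ind = TRUE)
  constrained <- pairs[(U[pairs] - L[pairs]) < 1e-9 | L[pairs] > 0, ,
                       drop = FALSE]
  for (sweep in seq_len(200L)) {
    lambda <- 0.6 * (1 - sweep / 220)
    maxviol <- 0
    for (r in seq_len(nrow(constrained))) {
      i <- constrained[r, 1L]; j <- constrained[r, 2L]
      d <- sqrt(sum((X[i, ] - X[j, ])^2))
      tgt <- if (d < L[i, j]) L[i, j] else if (d > U[i, j]) U[i, j] else next
      viol <- abs(d - tgt)
      maxviol <- max(maxviol, viol)
      if (d < 1e-8) {
        # coincident points: separate along a fixed axis
        X[j, ] <- X[j, ] + c(tgt / 2, 0, 0)
        X[i, ] <- X[i, ] - c(tgt / 2, 0, 0)
        next
      }
      shift <- lambda * (d - tgt) / (2 * d) * (X[j, ] - X[i, ])
      X[i, ] <- X[i, ] + shift
      X[j, ] <- X[j, ] - shift
    }
    if (maxviol < 1e-4) break
  }
  X <- sweep(X, 2L, colMeans(X))
  mol$atoms$x <- round(X[, 1L], 4L)
  mol$atoms$y <- round(X[, 2L], 4L)
  mol$atoms$z <- round(X[, 3L], 4L)
  mol
}

# save/restore .Random.seed so embedding never perturbs user RNG state
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}
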