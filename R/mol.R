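# Lightweight molecular graph model.
#
# Molecules are held as an atom table (element, formal charge, coordinates)
# plus a bond table (atom indices, Kekule bond order), populated from SDF
# records produced by OpenBabel and parsed with ChemmineR. The virtual
# reaction, state expansion and interaction typing all operate on this
# graph; canonical identity is always delegated back to OpenBabel.
#
# ChemmineR's SDF container does not expose V2000 "M  CHG" formal-charge
# properties, so charges are recovered from the raw record text, and the
# writer below emits them again.

.fl_mol <- function(atoms, bonds, title = "") {
  structure(list(atoms = atoms, bonds = bonds, title = title),
            class = "fl_mol")
}

#' @export
print.fl_mol <- function(x, ...) {
  cat("<fl_mol> ", x$title, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

# Parse many SDF records in one ChemmineR pass. `recs` is a list of
# character vectors (one record each, with or without trailing $$$$).
# Returns a list of fl_mol (NULL for records ChemmineR rejects).
.mols_from_sdf_records <- function(recs) {
  if (length(recs) == 0L) return(list())
  recs <- lapply(recs, function(r) {
    r <- r[!grepl("^\\${4}", r)]
    c(r, "$$$$")
  })
  out <- rep(list(NULL), length(recs))
  # ChemmineR's SDF container cannot represent bond-less records (single
  # atoms); those are read directly from the V2000 atom block
  nbonds <- vapply(recs, function(r) {
    as.integer(substr(r[4L], 4L, 6L))
  }, 0L)
  for (i in which(!is.na(nbonds) & nbonds == 0L)) {
    out[[i]] <- tryCatch(.mol_degenerate(recs[[i]]),
                         error = function(e) NULL)
  }
  norm <- which(is.na(nbonds) | nbonds > 0L)
  if (length(norm) > 0L) {
    f <- tempfile(fileext = ".sdf")
    on.exit(unlink(f), add = TRUE)
    writeLines(unlist(recs[norm]), f)
    sdfs <- suppressWarnings(ChemmineR::read.SDFset(f))
    valid <- ChemmineR::validSDF(sdfs)
    for (j in seq_along(norm)) {
      if (j > length(sdfs) || !valid[j]) next
      out[[norm[j]]] <- .mol_from_parsed(sdfs[[j]], recs[[norm[j]]])
    }
  }
  out
}

# bond-less V2000 record (atoms only)
.mol_degenerate <- function(rec) {
  natoms <- as.integer(substr(rec[4L], 1L, 3L))
  if (is.na(natoms) || natoms < 1L) stop("empty record")
  al <- rec[5L:(4L + natoms)]
  atoms <- data.frame(
    elem = trimws(substr(al, 32L, 34L)),
    chg = 0L,
    x = as.numeric(substr(al, 1L, 10L)),
    y = as.numeric(substr(al, 11L, 20L)),
    z = as.numeric(substr(al, 21L, 30L)),
    stringsAsFactors = FALSE
  )
  for (ln in grep("^M  CHG", rec, value = TRUE)) {
    v <- as.integer(strsplit(trimws(sub("^M  CHG\\s*\\d+", "", ln)),
                             "\\s+")[[1]])
    if (length(v) >= 2L) {
      atoms$chg[v[seq(1L, length(v), 2L)]] <- v[seq(2L, length(v), 2L)]
    }
  }
  .fl_mol(atoms,
          data.frame(a1 = integer(), a2 = integer(), order = integer()),
          title = trimws(rec[[1L]]))
}

# Single-record convenience wrapper.
.mol_from_sdf_record <- function(rec) {
  m <- .mols_from_sdf_records(list(rec))[[1]]
  if (is.null(m)) stop("unparseable SDF record", call. = FALSE)
  m
}

# Build fl_mol from a parsed ChemmineR SDF plus the raw record text
# (for M CHG recovery).
.mol_from_parsed <- function(sdf, rec) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  atoms <- data.frame(
    elem = elem,
    chg = integer(n),
    x = as.numeric(ab[, 1L]),
    y = as.numeric(ab[, 2L]),
    z = if (ncol(ab) >= 3L) as.numeric(ab[, 3L]) else numeric(n),
    stringsAsFactors = FALSE
  )
  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    data.frame(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
               order = as.integer(bb[, 3L]))
  }
  for (ln in grep("^M  CHG", rec, value = TRUE)) {
    v <- as.integer(strsplit(trimws(sub("^M  CHG\\s*\\d+", "", ln)),
                             "\\s+")[[1]])
    if (length(v) >= 2L) {
      idx <- v[seq(1L, length(v), 2L)]
      chg <- v[seq(2L, length(v), 2L)]
      atoms$chg[idx] <- chg
    }
  }
  .fl_mol(atoms, bonds, title = trimws(rec[[1L]]))
}

#' Parse SMILES into molecular graphs
#'
#' @param smiles character vector of SMILES strings.
#' @return list of `fl_mol` objects (`NULL` where parsing failed).
#' @export
mols_from_smiles <- function(smiles) {
  recs <- .smiles_to_sdf(smiles)
  ok <- !vapply(recs, is.null, TRUE)
  out <- rep(list(NULL), length(recs))
  out[ok] <- .mols_from_sdf_records(recs[ok])
  out
}

#' @rdname mols_from_smiles
#' @param smi a single SMILES string.
#' @export
mol_from_smiles <- function(smi) {
  m <- mols_from_smiles(smi)[[1]]
  if (is.null(m)) stop("unparseable SMILES: ", smi, call. = FALSE)
  m
}

#' Write a molecular graph as a V2000 SDF record
#'
#' Emits formal charges as `M  CHG` properties and a fixed, timestamp-free
#' header so that identical molecules serialise to identical bytes.
#'
#' @param mol an `fl_mol`.
#' @param title record title.
#' @return character vector of SDF lines, terminated by `$$$$`.
#' @export
mol_to_sdf_text <- function(mol, title = mol$title) {
  a <- mol$atoms
  b <- mol$bonds
  hdr <- c(title, " focuslib", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(a), nrow(b))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   a$x, a$y, a$z, a$elem)
  bonds <- if (nrow(b) > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", b$a1, b$a2, b$order)
  } else character()
  chg <- which(a$chg != 0L)
  chglines <- if (length(chg) > 0L) {
    # M CHG lines carry at most 8 (index, charge) pairs each
    grp <- split(chg, ceiling(seq_along(chg) / 8L))
    vapply(grp, function(g) {
      paste0(sprintf("M  CHG%3d", length(g)),
             paste0(sprintf("%4d%4d", g, a$chg[g]), collapse = ""))
    }, "")
  } else character()
  c(hdr, counts, atoms, bonds, chglines, "M  END", "$$$$")
}

#' Canonical SMILES of molecular graphs
#'
#' @param mols a list of `fl_mol` objects (or a single one).
#' @return character vector of canonical SMILES (`NA` on failure).
#' @export
mols_to_smiles <- function(mols) {
  if (inherits(mols, "fl_mol")) mols <- list(mols)
  if (length(mols) == 0L) return(character())
  ttl <- .ob_titles(length(mols))
  lines <- unlist(lapply(seq_along(mols), function(i) {
    mol_to_sdf_text(mols[[i]], title = ttl[i])
  }))
  out <- .sdf_to_canon(lines)
  res <- rep(NA_character_, length(mols))
  idx <- match(names(out), ttl)
  res[idx[!is.na(idx)]] <- unname(out[!is.na(idx)])
  res
}

#' @rdname mols_to_smiles
#' @param mol a single `fl_mol`.
#' @export
mol_to_smiles <- function(mol) mols_to_smiles(list(mol))[[1]]

# ---- graph utilities -------------------------------------------------------

# adjacency list: for each atom, integer vector of bonded atom indices
.mol_adj <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- rep(list(integer()), n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  adj
}

# bond order between atoms i and j (0 if not bonded)
.bond_order <- function(mol, i, j) {
  b <- mol$bonds
  k <- which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
  if (length(k) == 0L) 0L else b$order[k[1L]]
}

.DEFAULT_VALENCE <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L, Si = 4L
)

#' Implicit hydrogen counts
#'
#' Standard-valence model: the implicit hydrogen count of an atom is the
#' smallest default valence of its element (adjusted by formal charge for
#' N/P and O/S groups) minus its explicit bond-order sum, floored at zero.
#'
#' @param mol an `fl_mol`.
#' @return integer vector, one count per atom.
#' @export
implicit_h <- function(mol) {
  a <- mol$atoms
  bsum <- numeric(nrow(a))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    bsum[b$a1[k]] <- bsum[b$a1[k]] + b$order[k]
    bsum[b$a2[k]] <- bsum[b$a2[k]] + b$order[k]
  }
  vapply(seq_len(nrow(a)), function(i) {
    val <- .DEFAULT_VALENCE[[a$elem[i]]]
    if (is.null(val)) return(0L)
    # charge shifts the target valence: N+ -> 4, N- -> 2, O- -> 1, S- -> 1
    val <- val + a$chg[i]
    val <- val[val >= bsum[i]]
    if (length(val) == 0L) return(0L)
    as.integer(val[1L] - bsum[i])
  }, 0L)
}

# Rings up to `max_size` atoms, as a list of integer vectors. For each bond,
# the shortest alternative path between its ends (BFS with the bond removed)
# closes the smallest ring through that bond.
.mol_rings <- function(mol, max_size = 7L) {
  b <- mol$bonds
  n <- nrow(mol$atoms)
  if (nrow(b) == 0L || n < 3L) return(list())
  adj <- .mol_adj(mol)
  rings <- list()
  seen <- character()
  for (k in seq_len(nrow(b))) {
    s <- b$a1[k]; t <- b$a2[k]
    # BFS from s to t avoiding the direct edge
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0L && is.na(dist[t])) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(dist[v]) && dist[v] >= max_size - 1L) next
      for (w in adj[[v]]) {
        if (v == s && w == t) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          prev[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[t])) next
    path <- t
    while (path[1L] != s) path <- c(prev[path[1L]], path)
    if (length(path) > max_size) next
    key <- paste(sort(path), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

# Aromatic-like rings under the Kekule convention used in OpenBabel SDF
# output: 6-rings of C/N with three double bonds, or 5-rings of C/N/O/S
# with two double bonds.
.aromatic_rings <- function(mol, rings = .mol_rings(mol)) {
  Filter(function(r) .is_aromatic_ring(mol, r), rings)
}

.is_aromatic_ring <- function(mol, ring) {
  n <- length(ring)
  if (!n %in% c(5L, 6L)) return(FALSE)
  elems <- mol$atoms$elem[ring]
  okelem <- if (n == 6L) all(elems %in% c("C", "N"))
            else all(elems %in% c("C", "N", "O", "S"))
  if (!okelem) return(FALSE)
  orders <- vapply(seq_len(n), function(i) {
    .bond_order(mol, ring[i], ring[i %% n + 1L])
  }, 0L)
  if (any(orders == 0L)) return(FALSE)
  ndouble <- sum(orders == 2L)
  (n == 6L && ndouble == 3L) || (n == 5L && ndouble == 2L)
}

# Is atom i part of any aromatic-like ring?
.in_aromatic_ring <- function(mol, rings_arom = .aromatic_rings(mol)) {
  n <- nrow(mol$atoms)
  res <- rep(FALSE, n)
  for (r in rings_arom) res[r] <- TRUE
  res
}

# Hybridisation guess per atom: 1 = sp, 2 = sp2, 3 = sp3.
.hybridization <- function(mol) {
  a <- mol$atoms
  n <- nrow(a)
  ndouble <- integer(n); ntriple <- integer(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    if (b$order[k] == 2L) {
      ndouble[b$a1[k]] <- ndouble[b$a1[k]] + 1L
      ndouble[b$a2[k]] <- ndouble[b$a2[k]] + 1L
    } else if (b$order[k] == 3L) {
      ntriple[b$a1[k]] <- ntriple[b$a1[k]] + 1L
      ntriple[b$a2[k]] <- ntriple[b$a2[k]] + 1L
    }
  }
  arom <- .in_aromatic_ring(mol)
  hyb <- rep(3L, n)
  hyb[ndouble >= 1L | arom] <- 2L
  hyb[ntriple >= 1L | ndouble >= 2L] <- 1L
  # hypervalent sulfur (sulfone/sulfonamide S) is tetrahedral
  deg <- vapply(.mol_adj(mol), length, 0L)
  hyb[a$elem == "S" & deg >= 3L] <- 3L
  hyb
}

#' Add explicit hydrogens to a molecular graph
#'
#' New H atoms are appended after the heavy atoms with zero coordinates
#' (positions are assigned by the conformer embedder).
#'
#' @param mol an `fl_mol`.
#' @return `fl_mol` with explicit hydrogens.
#' @export
add_hydrogens <- function(mol) {
  nh <- implicit_h(mol)
  if (sum(nh) == 0L) return(mol)
  a <- mol$atoms; b <- mol$bonds
  for (i in which(nh > 0L)) {
    for (j in seq_len(nh[i])) {
      a <- rbind(a, data.frame(elem = "H", chg = 0L, x = 0, y = 0, z = 0))
      b <- rbind(b, data.frame(a1 = i, a2 = nrow(a), order = 1L))
    }
  }
  .fl_mol(a, b, mol$title)
}

# heavy-atom (non-H) indices
.heavy_idx <- function(mol) which(mol$atoms$elem != "H")

# Euclidean coordinate matrix (n x 3)
.mol_xyz <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])
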