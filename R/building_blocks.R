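# Building blocks: loading, canonicalisation, role classification and
# retrosynthetic decomposition of the reactive fragments that seed the
# combinatorial library.
#
# The chemistry is N-sulfonylation of primary amino-azines (2-aminopyrazine
# and relatives) with aryl sulfonyl chlorides, so exactly two roles exist:
# "amino_heteroarene" and "sulfonyl_chloride". Everything else is "unknown";
# a block matching both role patterns is flagged "ambiguous" and excluded
# from enumeration.

#' Substructure pattern set for roles and product scaffold
#'
#' The amine pattern requires a primary amine on an aromatic carbon of a
#' six-membered azine ring (at least one ring nitrogen, encoded with
#' recursive SMARTS for the three distinct nitrogen positions). The
#' sulfonyl-chloride pattern requires Cl-S(=O)(=O) on an aromatic carbon.
#' The scaffold pattern defaults to the pyrazinyl-sulfonamide substructure
#' query `[c;R]S(O)(O)Nc1cnccn1`, matched with substructure-search (any
#' bond order) semantics -- see [match_scaffold()].
#'
#' @param amine_pattern SMARTS for the amine role.
#' @param sulfonyl_chloride_pattern SMARTS for the sulfonyl chloride role.
#' @param scaffold_pattern product scaffold query.
#' @return a `fl_patterns` list.
#' @export
pattern_set <- function(
  amine_pattern = "[NX3;H2][c;R;$(c1naaaa1),$(c1anaaa1),$(c1aanaa1)]",
  sulfonyl_chloride_pattern = "Cl[SX4](=O)(=O)[c;R]",
  scaffold_pattern = "[c;R]S(O)(O)Nc1cnccn1"
) {
  for (p in c(amine_pattern, sulfonyl_chloride_pattern, scaffold_pattern)) {
    if (!smarts_ok(p)) stop("pattern does not compile: ", p, call. = FALSE)
  }
  structure(list(amine_pattern = amine_pattern,
                 sulfonyl_chloride_pattern = sulfonyl_chloride_pattern,
                 scaffold_pattern = scaffold_pattern),
            class = "fl_patterns")
}

# Rewrite a substructure query so that bonds written without an explicit
# bond symbol match any bond order ("~"). This reproduces the semantics of
# database substructure searches where the query is written like SMILES
# (e.g. sulfonyl groups written S(O)(O) must hit S(=O)(=O) targets).
.permissive_query <- function(pattern) {
  tokens <- character()
  i <- 1L
  n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "[") {
      j <- i
      depth <- 0L
      repeat {
        cj <- substr(pattern, j, j)
        if (cj == "[") depth <- depth + 1L
        if (cj == "]") depth <- depth - 1L
        if (depth == 0L || j > n) break
        j <- j + 1L
      }
      tokens <- c(tokens, substr(pattern, i, j))
      i <- j + 1L
    } else if (ch == "%") {
      tokens <- c(tokens, substr(pattern, i, i + 2L))
      i <- i + 3L
    } else if (substr(pattern, i, i + 1L) %in% c("Cl", "Br")) {
      tokens <- c(tokens, substr(pattern, i, i + 1L))
      i <- i + 2L
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  atom_like <- function(t) {
    startsWith(t, "[") | t %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                                  "Cl", "Br", "b", "c", "n", "o", "p", "s")
  }
  ring_like <- function(t) grepl("^[0-9]$|^%[0-9]{2}$", t)
  out <- character()
  prev_bondable <- FALSE   # previous token can start a new implicit bond
  for (t in tokens) {
    if ((atom_like(t) || ring_like(t)) && prev_bondable) {
      out <- c(out, "~")
    }
    if (atom_like(t) || t == ")" || ring_like(t)) {
      prev_bondable <- TRUE
    } else if (t == "(") {
      # branch start keeps the branching atom as bond origin
      prev_bondable <- TRUE
    } else {
      prev_bondable <- FALSE
    }
    out <- c(out, t)
  }
  paste(out, collapse = "")
}

#' Load building blocks from a structure file
#'
#' Reads SMILES (`structure id` per line) or SDF files, canonicalises every
#' record (salt stripping and +1/-1 charge neutralisation included),
#' classifies roles, and reports rejected records in the `rejects`
#' attribute -- unparseable records are counted, never silently dropped.
#'
#' @param path structure file (`.smi`/`.txt`/`.ism` SMILES or `.sdf`).
#' @param role_hint optional role to assert for all records
#'   (`"amino_heteroarene"` or `"sulfonyl_chloride"`).
#' @param patterns a [pattern_set()].
#' @param metadata optional sidecar CSV path with columns
#'   `id,role,availability`.
#' @return data.frame of class `fl_blocks` with columns `id`,
#'   `structure` (canonical), `role`, `n_reactive_sites`, `availability`,
#'   `source_file`; attributes `n_rejected` and `rejects`.
#' @export
load_blocks <- function(path, role_hint = NULL, patterns = pattern_set(),
                        metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "sdf") {
    lines <- readLines(path, warn = FALSE)
    recs <- .split_sdf(lines)
    ids <- vapply(seq_along(recs), function(i) {
      t <- trimws(recs[[i]][[1L]])
      if (nzchar(t)) t else sprintf("rec%d", i)
    }, "")
    raw <- vapply(recs, function(r) {
      s <- .sdf_to_canon(c(r, "$$$$"))
      if (length(s) == 1L) unname(s) else NA_character_
    }, "")
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[ \t]+")
    raw <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1L) parts[[i]][[2L]] else sprintf("rec%d", i)
    }, "")
  }
  if (length(raw) == 0L) {
    stop("no records in input file: ", path, call. = FALSE)
  }
  canon <- canon_smiles(strip_salts(raw), neutralize = TRUE)
  bad <- is.na(canon)
  if (all(bad)) {
    stop("no parseable records in input file: ", path, call. = FALSE)
  }
  roles <- classify_structures(canon[!bad], patterns)
  nsites <- .count_reactive_sites(canon[!bad], roles)
  blocks <- data.frame(
    id = ids[!bad],
    structure = canon[!bad],
    role = roles,
    n_reactive_sites = nsites,
    availability = NA_character_,
    source_file = path,
    stringsAsFactors = FALSE
  )
  if (!is.null(metadata)) {
    meta <- utils::read.csv(metadata, stringsAsFactors = FALSE)
    m <- match(blocks$id, meta$id)
    if ("availability" %in% names(meta)) {
      blocks$availability <- meta$availability[m]
    }
  }
  if (!is.null(role_hint)) {
    mismatch <- blocks$role != role_hint
    if (any(mismatch)) {
      warning(sum(mismatch), " block(s) in ", path,
              " do not classify as the hinted role '", role_hint, "'")
    }
  }
  if (any(blocks$role == "ambiguous")) {
    warning(sum(blocks$role == "ambiguous"),
            " block(s) matched both role patterns and are flagged ",
            "'ambiguous'; they are excluded from enumeration")
  }
  attr(blocks, "n_rejected") <- sum(bad)
  attr(blocks, "rejects") <- data.frame(id = ids[bad], structure = raw[bad],
                                        stringsAsFactors = FALSE)
  class(blocks) <- c("fl_blocks", "data.frame")
  blocks
}

#' Classify structures into building-block roles
#'
#' @param smiles character vector of canonical SMILES.
#' @param patterns a [pattern_set()].
#' @return character vector: `"amino_heteroarene"`, `"sulfonyl_chloride"`,
#'   `"ambiguous"` (both patterns hit) or `"unknown"`.
#' @export
classify_structures <- function(smiles, patterns = pattern_set()) {
  if (length(smiles) == 0L) return(character())
  am <- smarts_match(smiles, patterns$amine_pattern)
  su <- smarts_match(smiles, patterns$sulfonyl_chloride_pattern)
  ifelse(am & su, "ambiguous",
         ifelse(am, "amino_heteroarene",
                ifelse(su, "sulfonyl_chloride", "unknown")))
}

#' @rdname classify_structures
#' @param block one-row `fl_blocks` entry, or a single SMILES string.
#' @return for `classify_block`: a single role string.
#' @export
classify_block <- function(block, patterns = pattern_set()) {
  smi <- if (is.character(block)) block else block$structure
  stopifnot(length(smi) == 1L)
  classify_structures(smi, patterns)
}

# number of reactive sites for the assigned role (graph rule)
.count_reactive_sites <- function(smiles, roles) {
  n <- integer(length(smiles))
  todo <- which(roles %in% c("amino_heteroarene", "sulfonyl_chloride"))
  if (length(todo) == 0L) return(n)
  mols <- mols_from_smiles(smiles[todo])
  for (k in seq_along(todo)) {
    i <- todo[k]
    mol <- mols[[k]]
    if (is.null(mol)) next
    n[i] <- if (roles[i] == "amino_heteroarene") {
      length(find_amine_sites(mol))
    } else {
      length(find_sulfonyl_sites(mol))
    }
  }
  n
}

#' Locate reactive amine nitrogens
#'
#' A reactive site is a neutral nitrogen bearing two hydrogens whose single
#' heavy neighbour is an aromatic carbon of a six-membered azine ring.
#'
#' @param mol an `fl_mol`.
#' @return integer vector of nitrogen atom indices.
#' @export
find_amine_sites <- function(mol) {
  a <- mol$atoms
  adj <- .mol_adj(mol)
  nh <- implicit_h(mol)
  rings <- .aromatic_rings(mol)
  out <- integer()
  for (i in seq_len(nrow(a))) {
    if (a$elem[i] != "N" || a$chg[i] != 0L) next
    heavy <- adj[[i]][a$elem[adj[[i]]] != "H"]
    nH <- nh[i] + sum(a$elem[adj[[i]]] == "H")
    if (length(heavy) != 1L || nH != 2L) next
    c1 <- heavy[1L]
    if (a$elem[c1] != "C") next
    in_azine <- any(vapply(rings, function(r) {
      length(r) == 6L && c1 %in% r && sum(a$elem[r] == "N") >= 1L
    }, TRUE))
    if (in_azine) out <- c(out, i)
  }
  out
}

#' Locate reactive sulfonyl-chloride sulfurs
#'
#' A reactive site is a sulfur bonded to one chlorine, two double-bonded
#' oxygens, and one (aromatic) carbon.
#'
#' @param mol an `fl_mol`.
#' @return integer vector of sulfur atom indices.
#' @export
find_sulfonyl_sites <- function(mol) {
  a <- mol$atoms
  adj <- .mol_adj(mol)
  out <- integer()
  for (i in seq_len(nrow(a))) {
    if (a$elem[i] != "S") next
    nb <- adj[[i]]
    cl <- nb[a$elem[nb] == "Cl"]
    od <- nb[a$elem[nb] == "O" &
               vapply(nb, function(j) .bond_order(mol, i, j), 0L) == 2L &
               a$elem[nb] == "O"]
    cc <- nb[a$elem[nb] == "C"]
    if (length(cl) == 1L && length(od) == 2L && length(cc) == 1L) {
      out <- c(out, i)
    }
  }
  out
}

#' Match the product scaffold query
#'
#' Applies the scaffold pattern with substructure-search semantics: bonds
#' written without an explicit bond symbol match any bond order, so the
#' sulfonyl group written `S(O)(O)` hits `S(=O)(=O)` products.
#'
#' @param smiles character vector of SMILES.
#' @param patterns a [pattern_set()].
#' @return logical vector.
#' @export
match_scaffold <- function(smiles, patterns = pattern_set()) {
  bad <- is.na(canon_smiles(smiles))
  if (any(bad)) {
    stop("invalid molecule(s): ", paste(smiles[bad], collapse = ", "),
         call. = FALSE)
  }
  smarts_match(smiles, .permissive_query(patterns$scaffold_pattern))
}

#' Retro-decompose a sulfonamide into its source blocks
#'
#' For every sulfonamide N-S bond in the scaffold context (nitrogen on an
#' aromatic azine carbon, sulfur bearing two double-bonded oxygens and an
#' aryl carbon), returns the amine obtained by restoring the N-H and the
#' sulfonyl chloride obtained by capping the sulfur with Cl.
#'
#' @param smiles a single SMILES string.
#' @param patterns a [pattern_set()].
#' @return data.frame with columns `amine`, `sulfonyl_chloride` (canonical
#'   SMILES), one row per decomposable N-S bond; zero rows when the
#'   scaffold is absent.
#' @export
retro_decompose <- function(smiles, patterns = pattern_set()) {
  mol <- mol_from_smiles(smiles)
  a <- mol$atoms
  adj <- .mol_adj(mol)
  rings <- .aromatic_rings(mol)
  empty <- data.frame(amine = character(), sulfonyl_chloride = character(),
                      stringsAsFactors = FALSE)
  hits <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[k, ]
    if (b$order != 1L) next
    ns <- c(b$a1, b$a2)
    ni <- ns[a$elem[ns] == "N"]
    si <- ns[a$elem[ns] == "S"]
    if (length(ni) != 1L || length(si) != 1L) next
    # sulfur side: two S=O plus one carbon besides the nitrogen
    nb_s <- setdiff(adj[[si]], ni)
    od <- nb_s[a$elem[nb_s] == "O" &
                 vapply(nb_s, function(j) .bond_order(mol, si, j), 0L) == 2L]
    cc <- nb_s[a$elem[nb_s] == "C"]
    if (length(od) != 2L || length(cc) != 1L) next
    # nitrogen side: bonded to an aromatic azine carbon
    nb_n <- setdiff(adj[[ni]], si)
    azc <- nb_n[vapply(nb_n, function(j) {
      a$elem[j] == "C" && any(vapply(rings, function(r) {
        length(r) == 6L && j %in% r && sum(a$elem[r] == "N") >= 1L
      }, TRUE))
    }, TRUE)]
    if (length(azc) < 1L) next
    hits[[length(hits) + 1L]] <- c(n = ni, s = si)
  }
  if (length(hits) == 0L) return(empty)
  frag_mols <- list()
  for (h in hits) {
    keep <- !((mol$bonds$a1 == h[["n"]] & mol$bonds$a2 == h[["s"]]) |
                (mol$bonds$a1 == h[["s"]] & mol$bonds$a2 == h[["n"]]))
    cut <- mol$bonds[keep, ]
    comp <- .components(nrow(a), cut)
    amine_atoms <- which(comp == comp[h[["n"]]])
    sulf_atoms <- which(comp == comp[h[["s"]]])
    frag_mols[[length(frag_mols) + 1L]] <- .subgraph(mol, amine_atoms)
    sm <- .subgraph(mol, sulf_atoms)
    # cap the sulfur with chlorine
    s_new <- match(h[["s"]], sulf_atoms)
    sm$atoms <- rbind(sm$atoms, data.frame(elem = "Cl", chg = 0L,
                                           x = 0, y = 0, z = 0))
    sm$bonds <- rbind(sm$bonds, data.frame(a1 = s_new,
                                           a2 = nrow(sm$atoms), order = 1L))
    frag_mols[[length(frag_mols) + 1L]] <- sm
  }
  smis <- mols_to_smiles(frag_mols)
  out <- data.frame(
    amine = smis[seq(1L, length(smis), 2L)],
    sulfonyl_chloride = smis[seq(2L, length(smis), 2L)],
    stringsAsFactors = FALSE
  )
  unique(out)
}

# connected components given an atom count and a bond table
.components <- function(n, bonds) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$a1[k]; j <- bonds$a2[k]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# induced subgraph on a set of atom indices (renumbered)
.subgraph <- function(mol, atoms_keep) {
  atoms_keep <- sort(atoms_keep)
  map <- match(seq_len(nrow(mol$atoms)), atoms_keep)
  b <- mol$bonds
  keep <- !is.na(map[b$a1]) & !is.na(map[b$a2])
  .fl_mol(
    mol$atoms[atoms_keep, , drop = FALSE],
    data.frame(a1 = map[b$a1[keep]], a2 = map[b$a2[keep]],
               order = b$order[keep]),
    mol$title
  )
}
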