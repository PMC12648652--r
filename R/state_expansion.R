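# Protonation-state and tautomer expansion ("chemical species").
#
# Protonation follows a rule-table approach: ionisable sites are located by
# substructure rules on the molecular graph, each carrying a representative
# pKa. A site whose pKa window (pKa +/- pka_precision) intersects the
# configured pH range contributes both its neutral and ionised forms;
# otherwise only the form dominant in the pH range is kept. The rule table
# is part of the package (see `pka_rules()`) so state counts are stable
# across installations.
#
# Tautomers are enumerated with a single conservative rule family: 1,3
# proton shifts between heteroatoms across a carbon (D-H ... C=A  <->
# D=C ... A-H with D, A in {N, O}). This covers lactam/lactim
# (2-hydroxypyridine/2-pyridone), amide/imidic acid and amidine-type
# shifts; carbon-acid (keto-enol) tautomerism is deliberately out of the
# rule set. The rule set identifier is recorded in expansion manifests.

.TAUTOMER_RULESET <- "heteroatom-1,3-shift/v1"

#' Expansion configuration
#'
#' Defaults reproduce the screening protocol: pH window 6.0-7.2,
#' `pka_precision` 1.0 and at most 128 protonation variants per molecule,
#' with tautomer enumeration on.
#'
#' @param ph_min,ph_max pH window bounds.
#' @param pka_precision half-width (pH units) of each site's pKa window.
#' @param max_variants cap on protonation variants per molecule;
#'   truncation keeps the lexicographically first canonical structures.
#' @param enumerate_tautomers logical.
#' @param tautomer_cap cap on tautomers per molecule.
#' @return a `fl_state_config` list.
#' @export
state_config <- function(ph_min = 6.0, ph_max = 7.2, pka_precision = 1.0,
                         max_variants = 128L, enumerate_tautomers = TRUE,
                         tautomer_cap = 8L) {
  stopifnot(ph_min <= ph_max, max_variants >= 1L, pka_precision >= 0,
            tautomer_cap >= 1L)
  structure(list(ph_min = ph_min, ph_max = ph_max,
                 pka_precision = pka_precision,
                 max_variants = as.integer(max_variants),
                 enumerate_tautomers = isTRUE(enumerate_tautomers),
                 tautomer_cap = as.integer(tautomer_cap)),
            class = "fl_state_config")
}

#' The vendored pKa rule table
#'
#' One row per ionisable-site rule, applied in order (an atom claimed by an
#' earlier rule is not re-examined). pKa values are representative
#' literature values for each site class.
#'
#' @return data.frame with columns `rule`, `kind` (acid/base), `pka`.
#' @export
pka_rules <- function() {
  data.frame(
    rule = c("carboxylic_acid", "sulfonamide_nh", "phenol",
             "imidazole_n", "azine_n", "pyridine_n",
             "morpholine_n", "cyclic_aliphatic_amine",
             "aliphatic_amine", "aniline_nh2"),
    kind = c("acid", "acid", "acid",
             "base", "base", "base",
             "base", "base", "base", "base"),
    pka = c(4.21, 10.10, 9.84,
            6.99, 0.60, 5.23,
            8.36, 11.10, 10.68, 4.60),
    stringsAsFactors = FALSE
  )
}

# Locate ionisable sites: data.frame(atom, rule, kind, pka).
.pka_sites <- function(mol) {
  a <- mol$atoms
  adj <- .mol_adj(mol)
  nh <- implicit_h(mol)
  rings <- .mol_rings(mol)
  arom <- .aromatic_rings(mol, rings)
  hyb <- .hybridization(mol)
  tbl <- pka_rules()
  claimed <- rep(FALSE, nrow(a))
  out <- data.frame(atom = integer(), rule = character(),
                    kind = character(), pka = numeric(),
                    stringsAsFactors = FALSE)
  claim <- function(i, rule) {
    r <- tbl[tbl$rule == rule, ]
    out <<- rbind(out, data.frame(atom = i, rule = rule, kind = r$kind,
                                  pka = r$pka, stringsAsFactors = FALSE))
    claimed[i] <<- TRUE
  }
  has_h <- function(i) nh[i] + sum(a$elem[adj[[i]]] == "H") > 0L
  heavy_nb <- function(i) adj[[i]][a$elem[adj[[i]]] != "H"]
  dbl_to <- function(i, el) {
    nb <- heavy_nb(i)
    nb[a$elem[nb] == el &
         vapply(nb, function(j) .bond_order(mol, i, j), 0L) == 2L]
  }
  ring_of <- function(i, rs) Filter(function(r) i %in% r, rs)
  # --- acids -----------------------------------------------------------
  for (i in seq_len(nrow(a))) {
    if (a$elem[i] == "O" && a$chg[i] == 0L && length(heavy_nb(i)) == 1L &&
          has_h(i)) {
      cnb <- heavy_nb(i)[1L]
      if (a$elem[cnb] == "C" && length(dbl_to(cnb, "O")) >= 1L) {
        claim(i, "carboxylic_acid"); next
      }
      if (a$elem[cnb] == "C" && length(ring_of(cnb, arom)) > 0L) {
        claim(i, "phenol"); next
      }
    }
    if (a$elem[i] == "N" && a$chg[i] == 0L && has_h(i)) {
      snb <- heavy_nb(i)[a$elem[heavy_nb(i)] == "S"]
      if (length(snb) >= 1L && length(dbl_to(snb[1L], "O")) >= 2L) {
        claim(i, "sulfonamide_nh"); next
      }
    }
  }
  # --- bases -----------------------------------------------------------
  for (i in seq_len(nrow(a))) {
    if (claimed[i] || a$elem[i] != "N" || a$chg[i] != 0L) next
    nb <- heavy_nb(i)
    my_arom <- ring_of(i, arom)
    if (length(my_arom) > 0L) {
      # pyridine-type lone pair: two ring bonds, no substituent, no H
      if (has_h(i) || length(nb) != 2L) next
      ring <- my_arom[[1L]]
      nN <- sum(a$elem[ring] == "N")
      if (length(ring) == 5L && nN >= 2L) { claim(i, "imidazole_n"); next }
      if (length(ring) == 6L && nN >= 2L) { claim(i, "azine_n"); next }
      if (length(ring) == 6L && nN == 1L) { claim(i, "pyridine_n"); next }
      next
    }
    # exocyclic / aliphatic nitrogens
    has_multiple_bond <- any(vapply(nb, function(j) {
      .bond_order(mol, i, j)
    }, 0L) >= 2L)
    if (hyb[i] != 3L || has_multiple_bond) next
    arom_c <- any(vapply(nb, function(j) {
      a$elem[j] == "C" && length(ring_of(j, arom)) > 0L
    }, TRUE))
    # conjugated neighbours (amide, sulfonamide, enamine, amidine, imine
    # alpha-N): not treated as basic by this rule set
    conj <- any(vapply(nb, function(j) {
      nb2 <- heavy_nb(j)
      any(vapply(nb2, function(k) .bond_order(mol, j, k), 0L) >= 2L)
    }, TRUE))
    if (conj) next
    if (arom_c) {
      if (has_h(i)) claim(i, "aniline_nh2")
      next
    }
    satur_rings <- ring_of(i, rings)
    if (length(satur_rings) > 0L) {
      ring <- satur_rings[[1L]]
      if (any(a$elem[ring] == "O")) claim(i, "morpholine_n")
      else claim(i, "cyclic_aliphatic_amine")
      next
    }
    claim(i, "aliphatic_amine")
  }
  out
}

#' Enumerate protonation states within the pH window
#'
#' @param structure SMILES string or `fl_mol` in neutral canonical form.
#' @param config a [state_config()].
#' @return character vector of canonical SMILES (deduplicated, sorted,
#'   truncated at `max_variants`); always at least one state.
#' @export
enumerate_protomers <- function(structure, config = state_config()) {
  mol <- if (inherits(structure, "fl_mol")) structure
         else mol_from_smiles(structure)
  .protomers_batch(list(mol), config)[[1]]
}

# Batched protomer enumeration over a list of fl_mol graphs.
.protomers_batch <- function(mols, config) {
  cand <- list()   # candidate graphs
  tag <- integer() # which input each candidate belongs to
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    sites <- .pka_sites(mol)
    opts <- lapply(seq_len(nrow(sites)), function(k) {
      s <- sites[k, ]
      lo <- s$pka - config$pka_precision
      hi <- s$pka + config$pka_precision
      delta <- if (s$kind == "acid") -1L else +1L
      if (hi >= config$ph_min && lo <= config$ph_max) {
        c(0L, delta)                       # window overlap: both forms
      } else if (s$kind == "acid") {
        if (hi < config$ph_min) delta else 0L   # fully deprotonated / neutral
      } else {
        if (lo > config$ph_max) delta else 0L   # fully protonated / neutral
      }
    })
    combos <- if (length(opts) == 0L) list(integer()) else {
      grid <- do.call(expand.grid, c(opts, KEEP.OUT.ATTRS = FALSE))
      lapply(seq_len(nrow(grid)), function(r) as.integer(grid[r, ]))
    }
    # keep combo count bounded before canonicalisation
    if (length(combos) > 4L * config$max_variants) {
      combos <- combos[seq_len(4L * config$max_variants)]
    }
    for (cmb in combos) {
      g <- mol
      if (length(cmb) > 0L) g$atoms$chg[sites$atom] <- g$atoms$chg[sites$atom] + cmb
      cand[[length(cand) + 1L]] <- g
      tag <- c(tag, i)
    }
  }
  smis <- mols_to_smiles(cand)
  out <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    s <- sort(unique(stats::na.omit(smis[tag == i])))
    if (length(s) == 0L) s <- mols_to_smiles(mols[i])
    out[[i]] <- utils::head(s, config$max_variants)
  }
  out
}

# All applicable 1,3 heteroatom proton shifts on a graph; list of edited
# graphs (possibly empty).
.taut_moves <- function(mol) {
  a <- mol$atoms
  adj <- .mol_adj(mol)
  nh <- implicit_h(mol)
  out <- list()
  for (ci in which(a$elem == "C")) {
    nb <- adj[[ci]]
    donors <- nb[a$elem[nb] %in% c("N", "O") & a$chg[nb] == 0L &
                   vapply(nb, function(j) .bond_order(mol, ci, j), 0L) == 1L]
    donors <- donors[vapply(donors, function(d) {
      nh[d] + sum(a$elem[adj[[d]]] == "H") > 0L
    }, TRUE)]
    acceptors <- nb[a$elem[nb] %in% c("N", "O") & a$chg[nb] == 0L &
                      vapply(nb, function(j) .bond_order(mol, ci, j),
                             0L) == 2L]
    for (d in donors) {
      for (acc in acceptors) {
        if (d == acc) next
        g <- mol
        k1 <- which((g$bonds$a1 == ci & g$bonds$a2 == d) |
                      (g$bonds$a1 == d & g$bonds$a2 == ci))
        k2 <- which((g$bonds$a1 == ci & g$bonds$a2 == acc) |
                      (g$bonds$a1 == acc & g$bonds$a2 == ci))
        g$bonds$order[k1] <- 2L
        g$bonds$order[k2] <- 1L
        out[[length(out) + 1L]] <- g
      }
    }
  }
  out
}

#' Enumerate tautomers
#'
#' Closure of the 1,3 heteroatom proton-shift rule set, canonically
#' deduplicated; always contains the input's canonical tautomer.
#'
#' @param structure SMILES string or `fl_mol`.
#' @param cap maximum number of tautomers returned.
#' @return character vector of canonical SMILES, sorted.
#' @export
enumerate_tautomers <- function(structure, cap = 8L) {
  mol <- if (inherits(structure, "fl_mol")) structure
         else mol_from_smiles(structure)
  sort(names(.tautomers_batch(list(mol), cap)[[1]]))
}

# Batched tautomer closure. Returns, per input, a named list mapping
# canonical SMILES -> representative graph (needed for later protonation).
.tautomers_batch <- function(mols, cap) {
  out <- vector("list", length(mols))
  base_smi <- mols_to_smiles(mols)
  frontier <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    out[[i]] <- stats::setNames(list(mols[[i]]), base_smi[i])
    frontier[[i]] <- list(mols[[i]])
  }
  repeat {
    cand <- list(); tag <- integer()
    for (i in seq_along(mols)) {
      if (length(out[[i]]) >= cap) next
      for (g in frontier[[i]]) {
        for (m in .taut_moves(g)) {
          cand[[length(cand) + 1L]] <- m
          tag <- c(tag, i)
        }
      }
      frontier[[i]] <- list()
    }
    if (length(cand) == 0L) break
    smis <- mols_to_smiles(cand)
    progressed <- FALSE
    for (k in seq_along(cand)) {
      i <- tag[k]
      s <- smis[k]
      if (is.na(s) || s %in% names(out[[i]])) next
      if (length(out[[i]]) >= cap) next
      out[[i]][[s]] <- cand[[k]]
      frontier[[i]] <- c(frontier[[i]], list(cand[[k]]))
      progressed <- TRUE
    }
    if (!progressed) break
  }
  out
}

#' Expand a product library into chemical species
#'
#' Tautomer enumeration runs first, then each tautomer is expanded into its
#' pH-window protonation states; the union is deduplicated per parent
#' product. Ordering is deterministic (by parent, then canonical species
#' structure).
#'
#' @param library an `fl_library` (or data.frame with `product_id`,
#'   `structure`).
#' @param config a [state_config()].
#' @return data.frame of class `fl_species` with columns `species_id`,
#'   `structure`, `parent_product_id`, `kind` (`parent`, `tautomer`,
#'   `protomer` or `protomer+tautomer`); attribute `manifest` records
#'   per-stage counts and the tautomer rule set.
#' @export
expand_library <- function(library, config = state_config()) {
  if (nrow(library) == 0L) {
    sp <- data.frame(species_id = character(), structure = character(),
                     parent_product_id = character(), kind = character(),
                     stringsAsFactors = FALSE)
    class(sp) <- c("fl_species", "data.frame")
    return(sp)
  }
  mols <- mols_from_smiles(library$structure)
  bad <- vapply(mols, is.null, TRUE)
  if (any(bad)) {
    stop("unparseable product record(s): ",
         paste(library$product_id[bad], collapse = ", "), call. = FALSE)
  }
  taut <- if (config$enumerate_tautomers) {
    .tautomers_batch(mols, config$tautomer_cap)
  } else {
    lapply(seq_along(mols), function(i) {
      stats::setNames(list(mols[[i]]), library$structure[i])
    })
  }
  # flatten: all tautomer graphs, tagged by product and tautomer identity
  graphs <- list(); gtag <- integer(); gtaut <- character()
  for (i in seq_along(mols)) {
    for (s in names(taut[[i]])) {
      graphs[[length(graphs) + 1L]] <- taut[[i]][[s]]
      gtag <- c(gtag, i)
      gtaut <- c(gtaut, s)
    }
  }
  prot <- .protomers_batch(graphs, config)
  rows <- list()
  for (k in seq_along(graphs)) {
    i <- gtag[k]
    t_changed <- gtaut[k] != library$structure[i]
    for (s in prot[[k]]) {
      p_changed <- s != gtaut[k]
      kind <- if (t_changed && p_changed) "protomer+tautomer"
              else if (t_changed) "tautomer"
              else if (p_changed) "protomer"
              else "parent"
      rows[[length(rows) + 1L]] <- data.frame(
        structure = s, parent_product_id = library$product_id[i],
        kind = kind, stringsAsFactors = FALSE)
    }
  }
  sp <- do.call(rbind, rows)
  # global dedup on (parent, structure); prefer the least-derived kind
  kind_rank <- c(parent = 0L, protomer = 1L, tautomer = 2L,
                 `protomer+tautomer` = 3L)
  sp <- sp[order(sp$parent_product_id, sp$structure,
                 kind_rank[sp$kind]), , drop = FALSE]
  sp <- sp[!duplicated(sp[, c("parent_product_id", "structure")]), ,
           drop = FALSE]
  rownames(sp) <- NULL
  sp$species_id <- vapply(seq_len(nrow(sp)), function(r) {
    paste0("S", substr(digest::digest(
      paste0(sp$parent_product_id[r], "|", sp$structure[r]),
      algo = "sha256", serialize = FALSE), 1L, 16L))
  }, "")
  sp <- sp[, c("species_id", "structure", "parent_product_id", "kind")]
  attr(sp, "manifest") <- list(
    products_in = nrow(library),
    species_out = nrow(sp),
    tautomer_ruleset = .TAUTOMER_RULESET,
    order = "tautomers-then-protomers",
    config = unclass(config)
  )
  class(sp) <- c("fl_species", "data.frame")
  sp
}

#' Write / read a species table
#'
#' Tab-separated SMILES (`structure species_id parent_product_id kind`)
#' plus a JSON stage-count manifest.
#'
#' @param species an `fl_species`.
#' @param path output path; manifest goes to `<path>.manifest.json`.
#' @return (invisibly) the manifest.
#' @export
write_species <- function(species, path) {
  lines <- sprintf("%s\t%s\t%s\t%s", species$structure, species$species_id,
                   species$parent_product_id, species$kind)
  writeLines(c("#structure\tspecies_id\tparent_product_id\tkind", lines),
             path)
  manifest <- c(attr(species, "manifest"),
                list(sha256 = digest::digest(file = path, algo = "sha256")))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_species
#' @export
read_species <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 0L) != 4L)) {
    stop("malformed species record in ", path, call. = FALSE)
  }
  sp <- data.frame(
    species_id = vapply(parts, `[[`, "", 2L),
    structure = vapply(parts, `[[`, "", 1L),
    parent_product_id = vapply(parts, `[[`, "", 3L),
    kind = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
  class(sp) <- c("fl_species", "data.frame")
  sp
}
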