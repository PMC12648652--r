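# Virtual N-sulfonylation: exhaustive coupling of amine x sulfonyl-chloride
# building blocks into a deduplicated, provenance-tracked product library.
#
# The transform is applied as a graph edit: the amine N-H is replaced by an
# N-S bond to the sulfonyl sulfur, the S-Cl chlorine leaves (HCl loss), and
# the product is sanitised and canonicalised by OpenBabel. Every distinct
# reactive-site combination is enumerated; canonical duplicates collapse,
# keeping every contributing (amine, sulfonyl) provenance pair.

#' The amine N-sulfonylation reaction template
#'
#' @return a `fl_reaction` descriptor.
#' @export
reaction_template <- function() {
  structure(list(
    name = "amine_N_sulfonylation",
    description = paste("primary azine amine N-H + Cl-S(=O)(=O)-aryl ->",
                        "sulfonamide N-S bond, HCl loss")
  ), class = "fl_reaction")
}

# Graph-level coupling of parsed block molecules. Returns a list of product
# fl_mol, one per (amine site x sulfonyl site) combination.
.couple_graphs <- function(amol, smol) {
  n_sites <- find_amine_sites(amol)
  s_sites <- find_sulfonyl_sites(smol)
  out <- list()
  for (ni in n_sites) {
    for (si in s_sites) {
      # drop the chlorine bonded to this sulfur
      adj_s <- .mol_adj(smol)[[si]]
      cl <- adj_s[smol$atoms$elem[adj_s] == "Cl"][1L]
      keep_atoms <- setdiff(seq_len(nrow(smol$atoms)), cl)
      sfrag <- .subgraph(smol, keep_atoms)
      si_new <- match(si, sort(keep_atoms))
      # merge: amine atoms first, then sulfonyl fragment
      off <- nrow(amol$atoms)
      atoms <- rbind(amol$atoms, sfrag$atoms)
      bonds <- rbind(
        amol$bonds,
        data.frame(a1 = sfrag$bonds$a1 + off, a2 = sfrag$bonds$a2 + off,
                   order = sfrag$bonds$order),
        data.frame(a1 = ni, a2 = si_new + off, order = 1L)
      )
      out[[length(out) + 1L]] <- .fl_mol(atoms, bonds)
    }
  }
  out
}

#' Couple one amine with one sulfonyl chloride
#'
#' @param amine,sulfonyl single-row `fl_blocks` entries (or SMILES strings)
#'   with roles `amino_heteroarene` and `sulfonyl_chloride` respectively.
#' @param template the [reaction_template()].
#' @param patterns a [pattern_set()] used for role checks on raw SMILES.
#' @return data.frame with columns `structure` (canonical product SMILES);
#'   zero rows when the transform does not apply.
#' @export
couple <- function(amine, sulfonyl, template = reaction_template(),
                   patterns = pattern_set()) {
  get1 <- function(x, role) {
    if (is.character(x)) {
      smi <- canon_smiles(x)
      if (is.na(smi)) stop("unparseable structure: ", x, call. = FALSE)
      r <- classify_structures(smi, patterns)
      list(structure = smi, role = r)
    } else {
      list(structure = x$structure, role = x$role)
    }
  }
  am <- get1(amine); su <- get1(sulfonyl)
  if (!identical(am$role, "amino_heteroarene")) {
    stop("amine argument does not classify as 'amino_heteroarene' (got '",
         am$role, "')", call. = FALSE)
  }
  if (!identical(su$role, "sulfonyl_chloride")) {
    stop("sulfonyl argument does not classify as 'sulfonyl_chloride' ",
         "(got '", su$role, "')", call. = FALSE)
  }
  prods <- .couple_graphs(mol_from_smiles(am$structure),
                          mol_from_smiles(su$structure))
  if (length(prods) == 0L) {
    return(data.frame(structure = character(), stringsAsFactors = FALSE))
  }
  smis <- unique(stats::na.omit(mols_to_smiles(prods)))
  data.frame(structure = sort(smis), stringsAsFactors = FALSE)
}

#' Exhaustively enumerate the coupling library
#'
#' Applies the reaction to the full Cartesian product of amine and
#' sulfonyl-chloride blocks, deduplicates products on canonical structure,
#' and keeps every contributing block pair as provenance. Output order is
#' deterministic (sorted by canonical structure).
#'
#' @param amines,sulfonyls `fl_blocks` data.frames (rows with other roles
#'   are ignored with a warning).
#' @param template the [reaction_template()].
#' @return data.frame of class `fl_library` with columns `product_id`,
#'   `structure`, `amine_id`, `sulfonyl_id` (semicolon-joined lists for
#'   duplicate-provenance products) and attribute `provenance` (data.frame
#'   with one row per contributing pair).
#' @export
enumerate_library <- function(amines, sulfonyls,
                              template = reaction_template()) {
  sel_a <- amines[amines$role == "amino_heteroarene", , drop = FALSE]
  sel_s <- sulfonyls[sulfonyls$role == "sulfonyl_chloride", , drop = FALSE]
  if (nrow(sel_a) < nrow(amines)) {
    warning(nrow(amines) - nrow(sel_a),
            " non-amine block(s) ignored in the amine list")
  }
  if (nrow(sel_s) < nrow(sulfonyls)) {
    warning(nrow(sulfonyls) - nrow(sel_s),
            " non-sulfonyl block(s) ignored in the sulfonyl list")
  }
  if (nrow(sel_a) == 0L) {
    stop("empty role class: no 'amino_heteroarene' blocks", call. = FALSE)
  }
  if (nrow(sel_s) == 0L) {
    stop("empty role class: no 'sulfonyl_chloride' blocks", call. = FALSE)
  }
  amols <- mols_from_smiles(sel_a$structure)
  smols <- mols_from_smiles(sel_s$structure)
  prods <- list()
  prov_a <- character(); prov_s <- character()
  for (i in seq_len(nrow(sel_a))) {
    for (j in seq_len(nrow(sel_s))) {
      if (is.null(amols[[i]]) || is.null(smols[[j]])) next
      pg <- .couple_graphs(amols[[i]], smols[[j]])
      for (p in pg) {
        prods[[length(prods) + 1L]] <- p
        prov_a <- c(prov_a, sel_a$id[i])
        prov_s <- c(prov_s, sel_s$id[j])
      }
    }
  }
  if (length(prods) == 0L) {
    stop("the reaction produced no products from the given blocks",
         call. = FALSE)
  }
  smis <- mols_to_smiles(prods)
  ok <- !is.na(smis)
  prov <- data.frame(structure = smis[ok], amine_id = prov_a[ok],
                     sulfonyl_id = prov_s[ok], stringsAsFactors = FALSE)
  prov <- unique(prov)
  prov <- prov[order(prov$structure, prov$amine_id, prov$sulfonyl_id), ,
               drop = FALSE]
  rownames(prov) <- NULL
  structures <- sort(unique(prov$structure))
  fac <- factor(prov$structure, levels = structures)
  join <- function(x) vapply(split(x, fac), paste, "", collapse = ";")
  lib <- data.frame(
    product_id = product_id(structures),
    structure = structures,
    amine_id = unname(join(prov$amine_id)),
    sulfonyl_id = unname(join(prov$sulfonyl_id)),
    stringsAsFactors = FALSE
  )
  attr(lib, "provenance") <- prov
  attr(lib, "template") <- template$name
  class(lib) <- c("fl_library", "data.frame")
  lib
}

#' Stable product identifiers
#'
#' SHA-256 of the canonical structure, truncated to 16 hex characters, so
#' identifiers are reproducible across runs and machines.
#'
#' @param structures canonical SMILES vector.
#' @return character vector of ids (`P` + 16 hex digits).
#' @export
product_id <- function(structures) {
  vapply(structures, function(s) {
    paste0("P", substr(digest::digest(s, algo = "sha256", serialize = FALSE),
                       1L, 16L))
  }, "", USE.NAMES = FALSE)
}

#' Write / read a product library
#'
#' The library file is tab-separated SMILES
#' (`structure product_id amine_id sulfonyl_id`); the JSON manifest records
#' counts, the template name and input digests for provenance.
#'
#' @param library an `fl_library`.
#' @param path output library file path (`.smi`); the manifest is written
#'   next to it as `<path>.manifest.json`.
#' @return (invisibly) the manifest list.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "fl_library"))
  lines <- sprintf("%s\t%s\t%s\t%s", library$structure, library$product_id,
                   library$amine_id, library$sulfonyl_id)
  writeLines(c("#structure\tproduct_id\tamine_id\tsulfonyl_id", lines), path)
  manifest <- list(
    count = nrow(library),
    template = attr(library, "template"),
    file = basename(path),
    sha256 = digest::digest(file = path, algo = "sha256")
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 0L)
  if (any(nf != 4L)) {
    stop("malformed library record at line ", which(nf != 4L)[1L], " of ",
         path, call. = FALSE)
  }
  lib <- data.frame(
    product_id = vapply(parts, `[[`, "", 2L),
    structure = vapply(parts, `[[`, "", 1L),
    amine_id = vapply(parts, `[[`, "", 3L),
    sulfonyl_id = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
  mpath <- paste0(path, ".manifest.json")
  if (file.exists(mpath)) {
    man <- jsonlite::read_json(mpath)
    if (!is.null(man$count) && man$count != nrow(lib)) {
      stop("library file ", path, " is truncated: manifest records ",
           man$count, " products but ", nrow(lib), " were read",
           call. = FALSE)
    }
    attr(lib, "template") <- man$template
  }
  class(lib) <- c("fl_library", "data.frame")
  lib
}
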