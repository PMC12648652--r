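# Hit triage: score ranking, required-contact filtering, motif frequency
# among top hits, and fingerprint novelty against a reference set.

#' Triage configuration
#'
#' @param top_n number of top-ranked species examined for motifs.
#' @param required_contacts list of predicate functions over `fl_profile`s
#'   (see [pred_contacts_to()]); all must hold for a species to pass.
#' @param motif_patterns named character vector of SMARTS motifs.
#' @param fp_radius,fp_bits circular fingerprint parameters for novelty
#'   (radius 2, 1024 bits by default).
#' @param reference_set character vector of reference SMILES for novelty.
#' @return a `fl_triage_config`.
#' @export
triage_config <- function(top_n = 25L, required_contacts = list(),
                          motif_patterns = default_motifs(),
                          fp_radius = 2L, fp_bits = 1024L,
                          reference_set = character()) {
  stopifnot(top_n >= 1L)
  for (p in motif_patterns) {
    if (!smarts_ok(p)) stop("motif pattern does not compile: ", p,
                            call. = FALSE)
  }
  structure(list(top_n = as.integer(top_n),
                 required_contacts = required_contacts,
                 motif_patterns = motif_patterns,
                 fp_radius = as.integer(fp_radius),
                 fp_bits = as.integer(fp_bits),
                 reference_set = reference_set),
            class = "fl_triage_config")
}

#' Default structural motifs observed among top-scoring hits
#'
#' Methyl or fluorine on the benzene ring of the sulfonyl side, and an
#' extra hydrogen-bond acceptor adjacent to or fused with the pyrazine.
#'
#' @return named character vector of SMARTS.
#' @export
default_motifs <- function() {
  c(methyl_on_aryl = "[CH3][c;R]",
    fluoro_on_aryl = "F[c;R]",
    acceptor_near_azine = "[#7,#8;!$([NH,NH2,OH]);!$([n;R])][c;R]")
}

#' Rank a scored table
#'
#' Ascending by best score (more negative first); ties break on canonical
#' structure order so ranking is stable and permutation-invariant. Skip
#' rows (NA scores) sink to the bottom.
#'
#' @param scored an `fl_scores` table from [screen()].
#' @return the table reordered, with a `rank` column.
#' @export
rank_hits <- function(scored) {
  stopifnot(nrow(scored) >= 1L)
  ord <- order(is.na(scored$best_score), scored$best_score,
               scored$structure)
  out <- scored[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Filter ranked species on required contacts
#'
#' Keeps species whose interaction profiles satisfy every predicate; the
#' per-species, per-predicate report is kept in the `predicate_report`
#' attribute. Never reorders.
#'
#' @param ranked output of [rank_hits()].
#' @param profiles named list of `fl_profile`s keyed by `species_id`.
#' @param required_contacts list of predicates (possibly empty = identity
#'   filter).
#' @return the filtered table.
#' @export
filter_contacts <- function(ranked, profiles, required_contacts) {
  if (length(required_contacts) == 0L) {
    attr(ranked, "predicate_report") <-
      data.frame(species_id = ranked$species_id, stringsAsFactors = FALSE)
    return(ranked)
  }
  missing <- setdiff(ranked$species_id, names(profiles))
  if (length(missing) > 0L) {
    stop("no interaction profile for species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rep <- matrix(FALSE, nrow(ranked), length(required_contacts))
  for (i in seq_len(nrow(ranked))) {
    prof <- profiles[[ranked$species_id[i]]]
    rep[i, ] <- vapply(required_contacts, function(p) isTRUE(p(prof)),
                       TRUE)
  }
  keep <- apply(rep, 1L, all)
  report <- data.frame(species_id = ranked$species_id,
                       stringsAsFactors = FALSE)
  for (j in seq_along(required_contacts)) {
    report[[paste0("predicate_", j)]] <- rep[, j]
  }
  out <- ranked[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "predicate_report") <- report
  out
}

#' Motif frequency among top hits
#'
#' @param top_hits data.frame with a `structure` column (already limited
#'   to the top-n of interest).
#' @param motif_patterns named SMARTS vector.
#' @return data.frame `motif`, `pattern`, `count`, `fraction`.
#' @export
motif_table <- function(top_hits, motif_patterns = default_motifs()) {
  n <- nrow(top_hits)
  counts <- vapply(motif_patterns, function(p) {
    if (n == 0L) 0L else sum(smarts_match(top_hits$structure, p))
  }, 0L)
  data.frame(
    motif = names(motif_patterns),
    pattern = unname(motif_patterns),
    count = unname(counts),
    fraction = if (n == 0L) 0 else unname(counts) / n,
    stringsAsFactors = FALSE
  )
}

#' Fingerprint novelty against a reference set
#'
#' Maximum (and mean) Tanimoto similarity of a molecule to a reference
#' set on hashed circular fingerprints.
#'
#' @param smiles a single SMILES.
#' @param reference_set character vector of reference SMILES (non-empty).
#' @param fp_radius,fp_bits fingerprint parameters.
#' @return list with `max_similarity`, `mean_similarity`,
#'   `nearest_reference` (index).
#' @export
novelty <- function(smiles, reference_set, fp_radius = 2L,
                    fp_bits = 1024L) {
  if (length(reference_set) == 0L) {
    stop("reference set is empty", call. = FALSE)
  }
  fps <- circular_fp(c(smiles, reference_set), radius = fp_radius,
                     nbits = fp_bits)
  sims <- vapply(seq_along(reference_set), function(i) {
    tanimoto(fps[1L, ], fps[i + 1L, ])
  }, 0)
  list(max_similarity = max(sims), mean_similarity = mean(sims),
       nearest_reference = which.max(sims))
}

#' Assemble and write the triage report
#'
#' @param hits data.frame of triaged hits (ranked/filtered scores, with
#'   any annotation columns).
#' @param dir output directory (created if needed).
#' @param config the `fl_triage_config` used.
#' @param extra named list merged into the run manifest (e.g. seeds,
#'   upstream config digests).
#' @return (invisibly) the manifest list. Writes `hits.csv`, `hits.json`
#'   and `manifest.json` under `dir`.
#' @export
write_report <- function(hits, dir, config = NULL, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "hits.csv")
  json <- file.path(dir, "hits.json")
  utils::write.csv(hits, csv, row.names = FALSE)
  jsonlite::write_json(hits, json, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  manifest <- c(list(
    n_hits = nrow(hits),
    config_digest = if (!is.null(config)) config_digest(config) else NA,
    files = list(
      hits_csv = digest::digest(file = csv, algo = "sha256"),
      hits_json = digest::digest(file = json, algo = "sha256")
    )
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read back a triage report
#'
#' @param dir report directory.
#' @return the hits data.frame.
#' @export
read_report <- function(dir) {
  utils::read.csv(file.path(dir, "hits.csv"), stringsAsFactors = FALSE)
}
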