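# End-to-end orchestration: blocks -> enumerate -> expand -> embed/dock ->
# profile -> triage, with per-stage manifests (counts, config snapshot,
# file digests). With the mock engine, re-running an identical
# configuration reproduces byte-identical outputs: all randomness fans out
# deterministically from the single top-level seed, and no output file
# embeds a timestamp (wall-clock details go to the log stream only).

#' Validate a pipeline configuration
#'
#' @param config list (or YAML file path) with fields `seed`, `blocks`
#'   (either `n_amines`/`n_sulfonyls` for synthetic blocks or
#'   `amine_file`/`sulfonyl_file`), optional `receptor` (path; default
#'   toy pocket), `expansion` (see [state_config()]), `docking`
#'   (`engine`, optional `box_center`/`box_size`), `triage` (`top_n`),
#'   optional `workers`.
#' @return the normalised config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  problems <- character()
  if (is.null(config$seed)) problems <- c(problems, "seed")
  b <- config$blocks
  if (is.null(b) ||
        !((!is.null(b$n_amines) && !is.null(b$n_sulfonyls)) ||
            (!is.null(b$amine_file) && !is.null(b$sulfonyl_file)))) {
    problems <- c(problems,
                  "blocks.n_amines/n_sulfonyls or blocks.*_file")
  }
  engine <- config$docking$engine %||% "mock"
  if (!engine %in% c("mock", "external_vina")) {
    problems <- c(problems, "docking.engine")
  }
  if (engine == "external_vina" &&
        (is.null(config$docking$box_center) ||
           is.null(config$docking$box_size))) {
    problems <- c(problems,
                  "docking.box_center/box_size (required for external_vina)")
  }
  if (length(problems) > 0L) {
    stop("invalid pipeline configuration; missing or invalid fields: ",
         paste(problems, collapse = ", "), call. = FALSE)
  }
  config$docking$engine <- engine
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage_manifest <- function(dir, stage, counts, config, files = character()) {
  man <- list(
    stage = stage,
    counts = counts,
    config = config,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      digest::digest(file = f, algo = "sha256")
    })
  )
  jsonlite::write_json(man,
                       file.path(dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  man
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full screening pipeline
#'
#' Executes the stages in order, writing per-stage outputs and manifests
#' under `out_dir`. Any stage failure halts the run with the stage named.
#'
#' @param config list or YAML path, see [validate_config()].
#' @param out_dir report directory (created).
#' @return (invisibly) list of stage manifests.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifests <- list()
  stage <- "blocks"
  result <- tryCatch({
    # ---- blocks --------------------------------------------------------
    b <- config$blocks
    if (!is.null(b$n_amines)) {
      fx <- gen_blocks(b$n_amines, b$n_sulfonyls, dir = out_dir,
                       seed = seed)
      amine_file <- fx$amine_file; sulfonyl_file <- fx$sulfonyl_file
    } else {
      amine_file <- b$amine_file; sulfonyl_file <- b$sulfonyl_file
    }
    amines <- load_blocks(amine_file, role_hint = "amino_heteroarene")
    sulfonyls <- load_blocks(sulfonyl_file,
                             role_hint = "sulfonyl_chloride")
    .log_stage(stage, nrow(amines), " amines, ", nrow(sulfonyls),
               " sulfonyl chlorides (",
               attr(amines, "n_rejected") + attr(sulfonyls, "n_rejected"),
               " rejected)")
    manifests$blocks <- .stage_manifest(
      out_dir, "blocks",
      list(amines = nrow(amines), sulfonyls = nrow(sulfonyls),
           rejected = attr(amines, "n_rejected") +
             attr(sulfonyls, "n_rejected")),
      b, c(amine_file, sulfonyl_file))

    # ---- enumerate -----------------------------------------------------
    stage <- "enumerate"
    lib <- enumerate_library(amines, sulfonyls)
    lib_file <- file.path(out_dir, "library.smi")
    write_library(lib, lib_file)
    .log_stage(stage, nrow(lib), " unique products")
    manifests$enumerate <- .stage_manifest(
      out_dir, "enumerate", list(products = nrow(lib)),
      list(template = attr(lib, "template")), lib_file)

    # ---- expand --------------------------------------------------------
    stage <- "expand"
    sc <- do.call(state_config, config$expansion %||% list())
    species <- expand_library(lib, sc)
    sp_file <- file.path(out_dir, "species.smi")
    write_species(species, sp_file)
    .log_stage(stage, nrow(species), " species from ", nrow(lib),
               " products")
    manifests$expand <- .stage_manifest(
      out_dir, "expand",
      list(products_in = nrow(lib), species_out = nrow(species)),
      unclass(sc), sp_file)

    # ---- receptor / box ------------------------------------------------
    stage <- "dock"
    if (!is.null(config$receptor)) {
      receptor <- read_receptor(config$receptor)
    } else {
      pocket <- gen_pocket(dir = out_dir)
      receptor <- pocket$receptor
    }
    dk <- config$docking
    if (is.null(dk$box_center)) {
      box <- pocket_box(receptor,
                        resno = unique(receptor$atoms$resno))
      dk$box_center <- box$box_center
      dk$box_size <- box$box_size
    }
    dcfg <- dock_config(box_center = dk$box_center,
                        box_size = dk$box_size,
                        exhaustiveness = dk$exhaustiveness %||% 8L,
                        seed = seed,
                        engine = dk$engine)
    workers <- config$workers %||% 1L
    scores <- screen(species, receptor, dcfg, workers = workers)
    score_file <- file.path(out_dir, "scores.csv")
    utils::write.csv(scores, score_file, row.names = FALSE)
    .log_stage(stage, sum(scores$status == "ok"), " scored, ",
               sum(scores$status != "ok"), " skipped")
    manifests$dock <- .stage_manifest(
      out_dir, "dock",
      list(species_in = nrow(species), rows_out = nrow(scores),
           scored = sum(scores$status == "ok"),
           skipped = sum(scores$status != "ok")),
      list(engine = dcfg$engine, seed = dcfg$seed,
           exhaustiveness = dcfg$exhaustiveness,
           digest = dcfg$digest), score_file)

    # ---- profile + triage ----------------------------------------------
    stage <- "triage"
    tr <- config$triage %||% list()
    tcfg <- triage_config(top_n = tr$top_n %||% 10L)
    ranked <- rank_hits(scores)
    topn <- utils::head(ranked, tcfg$top_n)
    motifs <- motif_table(topn, tcfg$motif_patterns)
    motif_file <- file.path(out_dir, "motifs.csv")
    utils::write.csv(motifs, motif_file, row.names = FALSE)
    report_dir <- file.path(out_dir, "report")
    man <- write_report(ranked, report_dir, config = tcfg,
                        extra = list(seed = seed,
                                     dock_digest = dcfg$digest))
    .log_stage(stage, nrow(ranked), " ranked, top-", tcfg$top_n,
               " motif table written")
    manifests$triage <- .stage_manifest(
      out_dir, "triage",
      list(rows_in = nrow(scores), rows_ranked = nrow(ranked)),
      list(top_n = tcfg$top_n),
      c(motif_file, file.path(report_dir, "hits.csv")))
    manifests
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
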