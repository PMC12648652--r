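# Docking: receptor handling, engine-ready input preparation, a pluggable
# scoring backend and batch screening.
#
# Two engines are provided. `external_vina` drives an AutoDock Vina
# executable with the configured exhaustiveness and random seed and parses
# its pose output. `mock` is an exact, fully specified geometric scorer
# used for testing and pipeline determinism: the embedded conformer is
# placed at the box centre unrotated and scored as
#   score = -0.1 * C + 1.0 * K
# where C is the number of ligand heavy atoms with at least one receptor
# heavy atom within 4.0 A and K the number of ligand-receptor heavy-atom
# pairs closer than 2.0 A (a clash penalty). The mock score is bit-exact
# reproducible and recomputable by brute force.

#' Load a receptor structure
#'
#' @param path PDB file.
#' @param residue_map optional data.frame (`resno`, `bw`) or named vector
#'   mapping residue numbers to Ballesteros-Weinstein labels; every key
#'   must exist in the structure.
#' @return a `fl_receptor`: bio3d pdb plus an atom table (`elem`, `x`,
#'   `y`, `z`, `chain`, `resno`, `resid`, `name`).
#' @export
read_receptor <- function(path, residue_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- trimws(at$elesy)
  blank <- is.na(elem) | !nzchar(elem)
  # fall back to the first letter of the atom name when the element
  # column is absent
  elem[blank] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety[blank])
  elem <- paste0(toupper(substr(elem, 1L, 1L)),
                 tolower(substr(elem, 2L, 2L)))
  atoms <- data.frame(
    elem = trimws(elem), x = at$x, y = at$y, z = at$z,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, resid = at$resid, name = trimws(at$elety),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("receptor has non-finite coordinates", call. = FALSE)
  }
  rec <- structure(list(pdb = pdb, atoms = atoms, source = path,
                        residue_map = NULL), class = "fl_receptor")
  if (!is.null(residue_map)) rec <- set_residue_map(rec, residue_map)
  rec
}

#' @rdname read_receptor
#' @param receptor a `fl_receptor`.
#' @export
set_residue_map <- function(receptor, residue_map) {
  if (is.data.frame(residue_map)) {
    map <- stats::setNames(as.character(residue_map$bw),
                           as.character(residue_map$resno))
  } else {
    map <- stats::setNames(as.character(residue_map),
                           names(residue_map))
  }
  missing <- setdiff(names(map), as.character(receptor$atoms$resno))
  if (length(missing) > 0L) {
    stop("residue_map keys absent from the structure: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  receptor$residue_map <- map
  receptor
}

#' @export
print.fl_receptor <- function(x, ...) {
  cat("<fl_receptor> ", x$source, ": ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues\n",
      sep = "")
  invisible(x)
}

#' Docking configuration
#'
#' Defaults follow the screening protocol: exhaustiveness 8, random seed
#' 42, nine poses kept (only rank 1 flows to triage).
#'
#' @param box_center,box_size numeric length-3 vectors (Angstrom).
#' @param exhaustiveness search effort (external engine).
#' @param seed engine random seed; also seeds conformer embedding.
#' @param n_poses_kept poses requested from the engine.
#' @param engine `"mock"` or `"external_vina"`.
#' @param vina_bin path to the Vina executable (external engine only).
#' @return a `fl_dock_config`.
#' @export
dock_config <- function(box_center, box_size, exhaustiveness = 8L,
                        seed = 42L, n_poses_kept = 9L, engine = "mock",
                        vina_bin = "vina") {
  stopifnot(length(box_center) == 3L, length(box_size) == 3L,
            all(box_size > 0), exhaustiveness >= 1L)
  engine <- match.arg(engine, c("mock", "external_vina"))
  cfg <- structure(list(
    box_center = as.numeric(box_center), box_size = as.numeric(box_size),
    exhaustiveness = as.integer(exhaustiveness), seed = as.integer(seed),
    n_poses_kept = as.integer(n_poses_kept), engine = engine,
    vina_bin = vina_bin
  ), class = "fl_dock_config")
  cfg$digest <- config_digest(cfg)
  cfg
}

#' Digest of a configuration object
#'
#' @param config any list-like configuration.
#' @return 16-hex-character SHA-256 prefix; changes iff any field changes.
#' @export
config_digest <- function(config) {
  x <- unclass(config)
  x$digest <- NULL
  substr(digest::digest(x, algo = "sha256"), 1L, 16L)
}

#' Default docking box from a receptor residue selection
#'
#' Axis-aligned bounding box of the named residues plus a margin per side.
#'
#' @param receptor a `fl_receptor`.
#' @param resno integer vector of pocket residue numbers.
#' @param margin margin added on each side (Angstrom).
#' @return list with `box_center` and `box_size`.
#' @export
pocket_box <- function(receptor, resno, margin = 5) {
  sel <- receptor$atoms[receptor$atoms$resno %in% resno &
                          receptor$atoms$elem != "H", , drop = FALSE]
  if (nrow(sel) == 0L) stop("no atoms in the residue selection",
                            call. = FALSE)
  lo <- c(min(sel$x), min(sel$y), min(sel$z)) - margin
  hi <- c(max(sel$x), max(sel$y), max(sel$z)) + margin
  list(box_center = (lo + hi) / 2, box_size = hi - lo)
}

#' Prepare engine-ready PDBQT inputs
#'
#' Converts the receptor (rigid) and the 3D ligand to PDBQT with partial
#' charges and rotatable-bond annotation via OpenBabel; heavy-atom counts
#' are checked to be conserved.
#'
#' @param receptor a `fl_receptor`.
#' @param molecule3d an embedded `fl_mol`.
#' @param dir output directory.
#' @return list with `receptor_pdbqt` and `ligand_pdbqt` paths and the
#'   preparation tool tag.
#' @export
prepare_inputs <- function(receptor, molecule3d, dir = tempdir()) {
  .ob_assert()
  rec_out <- file.path(dir, "receptor.pdbqt")
  lig_out <- file.path(dir, "ligand.pdbqt")
  lig_sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(lig_sdf), add = TRUE)
  writeLines(mol_to_sdf_text(molecule3d, title = "ligand"), lig_sdf)
  out1 <- suppressWarnings(system2(
    "obabel", shQuote(c(receptor$source, "-opdbqt", "-xr", "-O", rec_out)),
    stdout = FALSE, stderr = TRUE))
  out2 <- suppressWarnings(system2(
    "obabel", shQuote(c(lig_sdf, "-opdbqt", "-O", lig_out)),
    stdout = FALSE, stderr = TRUE))
  for (f in c(rec_out, lig_out)) {
    if (!file.exists(f) || length(readLines(f, warn = FALSE)) == 0L) {
      stop("PDBQT conversion failed for ", f, call. = FALSE)
    }
  }
  n_in <- sum(molecule3d$atoms$elem != "H")
  lig_lines <- readLines(lig_out, warn = FALSE)
  atom_lines <- grep("^(ATOM|HETATM)", lig_lines, value = TRUE)
  types <- trimws(substr(atom_lines, 78L, 79L))
  n_out <- sum(!types %in% c("H", "HD", "HS"))
  if (n_out != n_in) {
    stop("heavy-atom count changed during PDBQT conversion (", n_in,
         " -> ", n_out, ")", call. = FALSE)
  }
  list(receptor_pdbqt = rec_out, ligand_pdbqt = lig_out,
       tool = "openbabel")
}

#' Dock one embedded species
#'
#' @param species3d an embedded `fl_mol` (explicit hydrogens, coordinates).
#' @param receptor a `fl_receptor`.
#' @param config a [dock_config()].
#' @return a `fl_dock_result`: `species_id`, `poses` (list of poses with
#'   `rank`, `score`, `xyz`), `config_digest`, `engine`.
#' @export
dock <- function(species3d, receptor, config) {
  stopifnot(inherits(config, "fl_dock_config"))
  res <- if (config$engine == "mock") {
    .dock_mock(species3d, receptor, config)
  } else {
    .dock_vina(species3d, receptor, config)
  }
  res$config_digest <- config$digest
  res$species_id <- species3d$title
  structure(res, class = "fl_dock_result")
}

.dock_mock <- function(species3d, receptor, config) {
  lig <- .mol_xyz(species3d)[species3d$atoms$elem != "H", , drop = FALSE]
  rec <- as.matrix(receptor$atoms[receptor$atoms$elem != "H",
                                  c("x", "y", "z")])
  # place the conformer at the box centre, unrotated
  lig <- sweep(lig, 2L, colMeans(lig))
  lig <- sweep(lig, 2L, config$box_center, `+`)
  score <- mock_score(lig, rec)
  list(poses = list(list(rank = 1L, score = score, xyz = lig)),
       engine = "mock")
}

#' The mock engine scoring function
#'
#' Exposed so tests can recompute scores by brute force.
#'
#' @param lig_xyz,rec_xyz heavy-atom coordinate matrices (n x 3).
#' @param contact_dist contact radius (4.0 A).
#' @param clash_dist clash radius (2.0 A).
#' @return numeric score (lower is better).
#' @export
mock_score <- function(lig_xyz, rec_xyz, contact_dist = 4.0,
                       clash_dist = 2.0) {
  if (nrow(lig_xyz) == 0L || nrow(rec_xyz) == 0L) return(0)
  d2 <- outer(rowSums(lig_xyz^2), rowSums(rec_xyz^2), `+`) -
    2 * lig_xyz %*% t(rec_xyz)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  contacts <- sum(apply(d <= contact_dist, 1L, any))
  clashes <- sum(d < clash_dist)
  -0.1 * contacts + 1.0 * clashes
}

.dock_vina <- function(species3d, receptor, config) {
  bin <- config$vina_bin
  if (!nzchar(Sys.which(bin))) {
    stop("the external docking engine '", bin, "' was not found on the ",
         "PATH. Install AutoDock Vina (>= 1.2) or use engine = 'mock'.",
         call. = FALSE)
  }
  dir <- tempfile("vina")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  prep <- prepare_inputs(receptor, species3d, dir)
  out_pdbqt <- file.path(dir, "out.pdbqt")
  args <- c("--receptor", prep$receptor_pdbqt,
            "--ligand", prep$ligand_pdbqt,
            "--center_x", config$box_center[1],
            "--center_y", config$box_center[2],
            "--center_z", config$box_center[3],
            "--size_x", config$box_size[1],
            "--size_y", config$box_size[2],
            "--size_z", config$box_size[3],
            "--exhaustiveness", config$exhaustiveness,
            "--seed", config$seed,
            "--num_modes", config$n_poses_kept,
            "--out", out_pdbqt)
  err <- tempfile()
  status <- suppressWarnings(system2(bin, shQuote(args), stdout = FALSE,
                                     stderr = err))
  if (status != 0L) {
    stop("docking engine exited with status ", status, ":\n",
         paste(readLines(err, warn = FALSE), collapse = "\n"),
         call. = FALSE)
  }
  lines <- readLines(out_pdbqt, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  poses <- lapply(seq_along(starts), function(k) {
    blk <- lines[starts[k]:ends[k]]
    sc <- as.numeric(sub("^REMARK VINA RESULT:\\s+(\\S+).*$", "\\1",
                         grep("^REMARK VINA RESULT", blk, value = TRUE)[1]))
    al <- grep("^(ATOM|HETATM)", blk, value = TRUE)
    xyz <- cbind(as.numeric(substr(al, 31L, 38L)),
                 as.numeric(substr(al, 39L, 46L)),
                 as.numeric(substr(al, 47L, 54L)))
    list(rank = k, score = sc, xyz = xyz)
  })
  list(poses = poses, engine = paste0("vina:", bin))
}

#' Select the best pose of a docking result
#'
#' Minimal score wins; ties break to the lowest engine rank, so the
#' selection is invariant under pose-list permutation.
#'
#' @param result a `fl_dock_result`.
#' @return the winning pose (list with `rank`, `score`, `xyz`).
#' @export
select_best_pose <- function(result) {
  poses <- result$poses
  if (is.null(poses) || length(poses) == 0L) {
    stop("docking result contains no poses", call. = FALSE)
  }
  scores <- vapply(poses, function(p) p$score, 0)
  ranks <- vapply(poses, function(p) p$rank, 0L)
  best <- order(scores, ranks)[1L]
  poses[[best]]
}

#' Screen a species list
#'
#' Embeds one conformer per species (seeded from the docking config),
#' docks it, and reports the best-pose score. Per-species failures are
#' recorded as skip rows; the output is identical for any worker count and
#' any input order.
#'
#' @param species a `fl_species` (or data.frame with `species_id`,
#'   `structure`).
#' @param receptor a `fl_receptor`.
#' @param config a [dock_config()].
#' @param workers parallel workers (forked; results are order-stable).
#' @return data.frame of class `fl_scores`: `species_id`, `structure`,
#'   `best_score`, `status` (`ok` or the failure reason).
#' @export
screen <- function(species, receptor, config, workers = 1L) {
  stopifnot(nrow(species) >= 1L)
  run1 <- function(i) {
    tryCatch({
      m3d <- embed_conformer(species$structure[i], seed = config$seed)
      m3d$title <- species$species_id[i]
      res <- dock(m3d, receptor, config)
      best <- select_best_pose(res)
      list(score = best$score, status = "ok")
    }, error = function(e) {
      list(score = NA_real_, status = paste0("skip: ", conditionMessage(e)))
    })
  }
  idx <- seq_len(nrow(species))
  results <- if (workers > 1L) {
    parallel::mclapply(idx, run1, mc.cores = workers)
  } else {
    lapply(idx, run1)
  }
  out <- data.frame(
    species_id = species$species_id,
    structure = species$structure,
    best_score = vapply(results, function(r) r$score, 0),
    status = vapply(results, function(r) r$status, ""),
    stringsAsFactors = FALSE
  )
  # deterministic row order regardless of input permutation
  out <- out[order(out$species_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fl_scores", "data.frame")
  out
}
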