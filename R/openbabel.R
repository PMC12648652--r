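# Interop with the OpenBabel command-line toolkit (obabel).
#
# All chemistry I/O that needs a real cheminformatics engine -- SMILES
# canonicalisation, SMILES <-> SDF conversion, SMARTS substructure matching,
# circular fingerprints, PDBQT preparation -- is delegated to obabel in
# *batch* calls: one subprocess per vector of molecules, never one per
# molecule. Records are tracked by synthetic titles so that per-record
# failures are reported, not silently dropped.

#' Is the OpenBabel executable available?
#'
#' @return `TRUE` if `obabel` is on the PATH.
#' @export
ob_available <- function() nzchar(Sys.which("obabel"))

.ob_assert <- function() {
  if (!ob_available()) {
    stop("OpenBabel ('obabel') was not found on the PATH; it is required ",
         "for structure handling. Install OpenBabel 3.x and retry.",
         call. = FALSE)
  }
}

# Run obabel with an input file written from `input` (character vector of
# lines, or NULL), returning the lines of the output file. Non-zero exit
# with empty output is an error; per-record failures are tolerated (-e).
.ob_run <- function(args, input = NULL, in_ext = "smi", out_ext = "smi") {
  .ob_assert()
  fin <- tempfile(fileext = paste0(".", in_ext))
  fout <- tempfile(fileext = paste0(".", out_ext))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  if (!is.null(input)) writeLines(input, fin)
  full <- c(if (!is.null(input)) fin, args, "-O", fout, "-e")
  err <- tempfile()
  on.exit(unlink(err), add = TRUE)
  status <- suppressWarnings(
    system2("obabel", shQuote(full), stdout = FALSE, stderr = err)
  )
  out <- if (file.exists(fout)) readLines(fout, warn = FALSE) else character()
  if (status != 0L && length(out) == 0L) {
    msg <- paste(readLines(err, warn = FALSE), collapse = "\n")
    stop("obabel failed (exit ", status, "):\n", msg, call. = FALSE)
  }
  out
}

# Internal record titles: "flr<i>" tags survive conversion and let us map
# outputs back to inputs even when some records fail to parse.
.ob_titles <- function(n) sprintf("flr%d", seq_len(n))

# Parse "smiles\ttitle" lines into a named character vector.
.ob_parse_smi <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[ \t]+")
  smi <- vapply(parts, `[[`, "", 1L)
  ttl <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", "")
  stats::setNames(smi, ttl)
}

#' Canonicalise SMILES strings
#'
#' Converts each input to OpenBabel canonical SMILES. Unparseable records
#' yield `NA` (they are counted by callers, never dropped silently).
#'
#' @param smiles character vector of SMILES.
#' @param neutralize also neutralise +1/-1 formal charges.
#' @return character vector, same length as `smiles`, `NA` where invalid.
#' @export
canon_smiles <- function(smiles, neutralize = FALSE) {
  if (length(smiles) == 0L) return(character())
  ok <- !is.na(smiles) & nzchar(trimws(smiles)) &
    !grepl("[ \t]", trimws(smiles))
  res <- rep(NA_character_, length(smiles))
  if (any(ok)) {
    ttl <- .ob_titles(length(smiles))
    inp <- paste(trimws(smiles[ok]), ttl[ok])
    args <- c("-ismi", "-ocan")
    if (neutralize) args <- c(args, "--neutralize")
    out <- .ob_parse_smi(.ob_run(args, inp))
    idx <- match(names(out), ttl)
    res[idx[!is.na(idx)]] <- unname(out[!is.na(idx)])
  }
  res
}

#' Strip salts/solvents from SMILES
#'
#' Keeps the largest connected component (most heavy-atom tokens) of each
#' dot-disconnected SMILES.
#'
#' @param smiles character vector.
#' @return character vector of the retained fragments.
#' @export
strip_salts <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !grepl(".", s, fixed = TRUE)) return(s)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    # heavy-atom token count: bracket atoms, two-letter halogens, organic
    # subset symbols (aromatic included); hydrogens excluded
    n_heavy <- vapply(frags, function(f) {
      f2 <- gsub("\\[[^]]*\\]", "X", f)
      length(gregexpr("Cl|Br|Si|[BCNOPSFIX]|[bcnops]", f2)[[1]])
    }, 0L)
    frags[which.max(n_heavy)]
  }, "", USE.NAMES = FALSE)
}

# SMILES -> V2000 SDF text, batched. Returns a list of character vectors
# (one per input; NULL where conversion failed), matched by title.
.smiles_to_sdf <- function(smiles, gen2d = FALSE) {
  n <- length(smiles)
  if (n == 0L) return(list())
  ttl <- .ob_titles(n)
  ok <- !is.na(smiles) & nzchar(smiles)
  out <- rep(list(NULL), n)
  if (any(ok)) {
    inp <- paste(smiles[ok], ttl[ok])
    args <- c("-ismi", "-osdf")
    if (gen2d) args <- c(args, "--gen2d")
    lines <- .ob_run(args, inp, out_ext = "sdf")
    recs <- .split_sdf(lines)
    for (r in recs) {
      i <- match(trimws(r[[1L]]), ttl)
      if (!is.na(i)) out[[i]] <- r
    }
  }
  out
}

# Split SDF lines into records on "$$$$".
.split_sdf <- function(lines) {
  if (length(lines) == 0L) return(list())
  ends <- grep("^\\${4}", lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- Map(function(s, e) lines[s:(e - 1L)], starts, ends)
  recs[vapply(recs, length, 0L) >= 4L]
}

# Multi-record SDF text (character vector of lines, records already
# terminated by $$$$) -> canonical SMILES named by record title.
.sdf_to_canon <- function(sdf_lines) {
  if (length(sdf_lines) == 0L) return(character())
  .ob_parse_smi(.ob_run(c("-isdf", "-ocan"), sdf_lines, in_ext = "sdf"))
}

#' SMARTS substructure match over a set of molecules
#'
#' @param smiles character vector of valid SMILES.
#' @param smarts a single SMARTS pattern.
#' @return logical vector: does each molecule contain the pattern?
#' @export
smarts_match <- function(smiles, smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1L)
  if (length(smiles) == 0L) return(logical())
  ttl <- .ob_titles(length(smiles))
  ok <- !is.na(smiles)
  hit <- rep(FALSE, length(smiles))
  if (any(ok)) {
    inp <- paste(smiles[ok], ttl[ok])
    out <- .ob_parse_smi(.ob_run(c("-ismi", "-osmi", "-s", smarts), inp))
    hit[match(names(out), ttl)] <- TRUE
  }
  hit
}

#' Does a SMARTS pattern compile?
#'
#' @param smarts pattern to check.
#' @return `TRUE` if obabel accepts the pattern.
#' @export
smarts_ok <- function(smarts) {
  if (!is.character(smarts) || length(smarts) != 1L || !nzchar(smarts)) {
    return(FALSE)
  }
  .ob_assert()
  fin <- tempfile(fileext = ".smi")
  err <- tempfile()
  on.exit(unlink(c(fin, err)), add = TRUE)
  writeLines("C probe", fin)
  suppressWarnings(
    system2("obabel", shQuote(c(fin, "-onul", "-s", smarts)),
            stdout = FALSE, stderr = err)
  )
  msg <- paste(readLines(err, warn = FALSE), collapse = " ")
  !grepl("Invalid SMARTS|Error", msg, ignore.case = FALSE)
}

#' Hashed circular (ECFP) fingerprints
#'
#' Extended-connectivity fingerprints folded to a fixed bit length,
#' computed by OpenBabel. `radius` is the ECFP radius (2 corresponds to
#' ECFP4).
#'
#' @param smiles character vector of valid SMILES.
#' @param radius circular radius (default 2).
#' @param nbits folded length (default 1024).
#' @return logical matrix, one row per molecule, `nbits` columns.
#' @export
circular_fp <- function(smiles, radius = 2L, nbits = 1024L) {
  stopifnot(radius >= 0L, nbits >= 32L, nbits %% 32L == 0L)
  n <- length(smiles)
  mat <- matrix(FALSE, n, nbits)
  if (n == 0L) return(mat)
  fptype <- paste0("ECFP", 2L * radius)
  ttl <- .ob_titles(n)
  inp <- paste(smiles, ttl)
  lines <- .ob_run(c("-ismi", "-ofpt", paste0("-xf", fptype),
                     paste0("-xN", nbits), "-xh"), inp, out_ext = "fpt")
  # fpt output: ">title   k bits set" header then hex words
  hdr <- grep("^>", lines)
  bounds <- c(hdr, length(lines) + 1L)
  for (j in seq_along(hdr)) {
    name <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr[j]])
    i <- match(name, ttl)
    if (is.na(i)) next
    body <- lines[(hdr[j] + 1L):(bounds[j + 1L] - 1L)]
    words <- unlist(strsplit(trimws(paste(body, collapse = " ")), "\\s+"))
    words <- words[grepl("^[0-9a-fA-F]{8}$", words)]
    if (length(words) * 32L != nbits) next
    bits <- unlist(lapply(words, function(w) {
      dv <- strtoi(strsplit(w, "")[[1]], 16L)
      unlist(lapply(dv, function(d) bitwAnd(d, c(8L, 4L, 2L, 1L)) > 0L))
    }))
    mat[i, ] <- bits[seq_len(nbits)]
  }
  mat
}

#' Tanimoto similarity between two bit vectors
#'
#' @param a,b logical vectors of equal length.
#' @return |intersection| / |union|, with 0 for two empty fingerprints.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}
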