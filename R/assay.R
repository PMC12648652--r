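# Assay mathematics: radioligand displacement / functional inhibition
# normalisation, four-parameter logistic (4PL) dose-response fitting,
# EC-fraction derivation and Cheng-Prusoff Ki conversion.

#' Assay constants used in the study
#'
#' Radioligand concentration ~6 nM with KD 6.3 nM; agonist challenge at
#' its EC80 (5.15 nM). Exposed as defaults only -- both Cheng-Prusoff
#' parameters are required explicit arguments in [cheng_prusoff_ki()].
#'
#' @return list with `radioligand_conc_nM`, `radioligand_kd_nM`,
#'   `ec80_agonist_conc_nM`.
#' @export
assay_constants <- function() {
  list(radioligand_conc_nM = 6.0, radioligand_kd_nM = 6.3,
       ec80_agonist_conc_nM = 5.15)
}

#' Percent displacement of a radioligand
#'
#' `100 * (total - sample) / (total - nsb)`: 0% when the sample equals
#' total binding, 100% at non-specific binding (NSB).
#'
#' @param total_counts,nsb_counts,sample_counts counts (total binding,
#'   non-specific binding, sample).
#' @return percent displacement; attribute `clamped` flags values outside
#'   [0, 100].
#' @export
percent_displacement <- function(total_counts, nsb_counts, sample_counts) {
  if (any(total_counts <= nsb_counts)) {
    stop("degenerate assay window: total counts must exceed NSB counts",
         call. = FALSE)
  }
  pct <- 100 * (total_counts - sample_counts) / (total_counts - nsb_counts)
  structure(pct, clamped = pct < 0 | pct > 100)
}

#' Percent inhibition of an agonist-stimulated response
#'
#' `100 * (stimulated - sample) / (stimulated - basal)`; 50% is the hit
#' cut-off used in single-point screens.
#'
#' @param stimulated,basal,sample response values.
#' @return percent inhibition; attribute `clamped` as in
#'   [percent_displacement()].
#' @export
percent_inhibition <- function(stimulated, basal, sample) {
  if (any(stimulated <= basal)) {
    stop("degenerate assay window: stimulated response must exceed basal",
         call. = FALSE)
  }
  pct <- 100 * (stimulated - sample) / (stimulated - basal)
  structure(pct, clamped = pct < 0 | pct > 100)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Model: `response = bottom + (top - bottom) /
#' (1 + 10^((log_ic50 - log10(c)) * hill))`. Initialisation: bottom/top
#' from the data extremes, midpoint from the concentration nearest the
#' half-maximal response, `hill = +1` for rising curves
#' (`direction = "increasing"`) and `-1` for falling ones. Deterministic
#' given the data.
#'
#' @param concentrations molar concentrations (> 0), at least 4 distinct.
#' @param responses observed responses, same length.
#' @param direction `"auto"`, `"increasing"` or `"decreasing"`.
#' @return a `fl_4pl` list: `bottom`, `top`, `hill`, `log_ic50`, `pic50`,
#'   `ic50`, standard errors, `n_points`, `converged`.
#' @export
fit_4pl <- function(concentrations, responses,
                    direction = c("auto", "increasing", "decreasing")) {
  direction <- match.arg(direction)
  stopifnot(length(concentrations) == length(responses))
  if (any(concentrations <= 0)) {
    stop("concentrations must be positive (molar)", call. = FALSE)
  }
  if (length(unique(concentrations)) < 4L) {
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  }
  logc <- log10(concentrations)
  if (direction == "auto") {
    slope <- stats::coef(stats::lm(responses ~ logc))[2L]
    direction <- if (slope >= 0) "increasing" else "decreasing"
  }
  bottom0 <- min(responses); top0 <- max(responses)
  half <- (bottom0 + top0) / 2
  mid0 <- logc[which.min(abs(responses - half))]
  hill0 <- if (direction == "increasing") 1 else -1
  dat <- data.frame(logc = logc, y = responses)
  fit <- minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + 10^((logmid - logc) * hill)),
    data = dat,
    start = list(bottom = bottom0, top = top0, logmid = mid0,
                 hill = hill0),
    control = minpack.lm::nls.lm.control(maxiter = 200L)
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4L))
  if (!is.finite(cf[["hill"]]) || cf[["hill"]] == 0) {
    stop("4PL fit degenerate: Hill slope is zero or non-finite",
         call. = FALSE)
  }
  bottom <- unname(cf[["bottom"]]); top <- unname(cf[["top"]])
  hill <- unname(cf[["hill"]])
  # orient so bottom <= top; negating the Hill slope keeps the curve
  # identical under the swap
  if (bottom > top) {
    tmp <- bottom; bottom <- top; top <- tmp
    hill <- -hill
  }
  structure(list(
    bottom = bottom, top = top, hill = hill,
    log_ic50 = unname(cf[["logmid"]]),
    pic50 = -unname(cf[["logmid"]]),
    ic50 = 10^unname(cf[["logmid"]]),
    se = se, n_points = length(responses),
    direction = direction, converged = TRUE
  ), class = "fl_4pl")
}

#' @export
print.fl_4pl <- function(x, ...) {
  cat(sprintf(
    "<4PL fit> pIC50/pEC50 %.3f (IC50 %.3g M), Hill %.2f, range [%.3g, %.3g], n = %d\n",
    x$pic50, x$ic50, x$hill, x$bottom, x$top, x$n_points))
  invisible(x)
}

#' Convert IC50 (molar) to pIC50
#'
#' @param ic50 molar IC50.
#' @return `-log10(ic50)`.
#' @export
ic50_to_pic50 <- function(ic50) {
  stopifnot(all(ic50 > 0))
  -log10(ic50)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + [L] / KD)` for a competitive radioligand at
#' concentration `[L]` with affinity `KD`.
#'
#' @param ic50 molar IC50 (> 0).
#' @param radioligand_conc molar radioligand concentration (>= 0).
#' @param kd molar radioligand KD (> 0).
#' @return list with `ki` (molar) and `pki`.
#' @export
cheng_prusoff_ki <- function(ic50, radioligand_conc, kd) {
  stopifnot(ic50 > 0, radioligand_conc >= 0)
  if (kd <= 0) stop("radioligand KD must be positive", call. = FALSE)
  ki <- ic50 / (1 + radioligand_conc / kd)
  list(ki = ki, pki = -log10(ki))
}

#' Concentration producing a response fraction on a logistic curve
#'
#' `ECf = EC50 * (f / (1 - f))^(1 / hill)`; e.g. the EC80 at Hill 1 is
#' four times the EC50.
#'
#' @param ec50 molar EC50 (> 0).
#' @param hill Hill slope (non-zero).
#' @param fraction response fraction in (0, 1).
#' @return molar concentration.
#' @export
ec_fraction <- function(ec50, hill, fraction) {
  stopifnot(ec50 > 0, fraction > 0, fraction < 1)
  if (hill == 0) stop("Hill slope must be non-zero", call. = FALSE)
  ec50 * (fraction / (1 - fraction))^(1 / hill)
}
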