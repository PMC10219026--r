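#' Dinucleotide step property tables
#'
#' Loads the shipped dinucleotide table used by the sliding and bending
#' terms of the three-stage binding model. The `slide` column is a
#' nonspecific TBP-DNA affinity weight (A/T content of the step), the
#' `bend` column a relative minor-groove bendability. Both are config data:
#' alternative tables are drop-in replacements.
#'
#' @param path optional TSV with columns `step`, `slide`, `bend`.
#' @return list with named numeric vectors `slide` and `bend` (16 steps).
#' @export
dinucleotide_properties <- function(path = NULL) {
  if (is.null(path)) {
    return(cache_get("default_dinuc", dinucleotide_properties(
      system.file("extdata", "dinucleotide_properties.tsv", package = "snptata"))))
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("step", "slide", "bend") %in% names(tab)), nrow(tab) == 16L)
  list(slide = stats::setNames(tab$slide, tab$step),
       bend = stats::setNames(tab$bend, tab$step))
}

dinucleotide_steps <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) < 2L) stop("sequence shorter than 2 nt")
  steps <- paste0(chars[-length(chars)], chars[-1L])
  # steps touching an ambiguous base carry no information; drop them
  ok <- chars[-length(chars)] %in% BASES & chars[-1L] %in% BASES
  if (!any(ok)) stop("no valid dinucleotide step in sequence")
  steps[ok]
}

#' Sliding and bending terms of the three-stage binding model
#'
#' `slide_term` summarizes the whole region's dinucleotide composition as
#' the mean nonspecific TBP affinity encountered while TBP slides along the
#' helix; being a mean, it is comparable across promoters of different
#' length. `bend_term` sums the dinucleotide bend propensity over a
#' candidate site window, reflecting the ~90 degree bend the helix adopts
#' in the final TBP-promoter complex. Both are pure functions of their
#' input.
#'
#' @param sequence,window nucleotide string (at least 2 nt).
#' @param props dinucleotide property tables, see
#'   [dinucleotide_properties()].
#' @return numeric scalar.
#' @export
slide_term <- function(sequence, props = dinucleotide_properties()) {
  mean(props$slide[dinucleotide_steps(sequence)])
}

#' @rdname slide_term
#' @export
bend_term <- function(window, props = dinucleotide_properties()) {
  sum(props$bend[dinucleotide_steps(window)])
}

#' Construct a coefficient set for the three-stage binding model
#'
#' The model predicts `-ln(Kd)` (Kd in mol/L) as
#' `intercept + w_slide * slide_term + w_stop * best_site_score +
#' w_bend * bend_term(best window)`.
#'
#' @param intercept,w_slide,w_stop,w_bend finite model coefficients.
#' @param se_model standard-error model: `list(type = "relative", value)`
#'   applies `value * Kd` as the SE in nM (default 0.10), matching the
#'   roughly constant SE/Kd ratio of the calibration estimates;
#'   `list(type = "absolute_ln", value)` uses a fixed SE in ln units.
#' @param provenance free-text origin tag (recorded in outputs).
#' @param residuals optional calibration residuals, kept for inspection.
#' @return object of class `model_coefficients`.
#' @export
model_coefficients <- function(intercept, w_slide, w_stop, w_bend,
                               se_model = list(type = "relative", value = 0.10),
                               provenance = "unspecified",
                               residuals = NULL) {
  co <- c(intercept = intercept, w_slide = w_slide, w_stop = w_stop,
          w_bend = w_bend)
  if (!all(is.finite(co))) stop("model coefficients must be finite")
  stopifnot(se_model$type %in% c("relative", "absolute_ln"),
            is.numeric(se_model$value), se_model$value > 0)
  structure(list(intercept = intercept, w_slide = w_slide, w_stop = w_stop,
                 w_bend = w_bend, se_model = se_model,
                 provenance = provenance, residuals = residuals),
            class = "model_coefficients")
}

#' @export
print.model_coefficients <- function(x, ...) {
  cat(sprintf(paste0("<model_coefficients> -ln(Kd) = %.4f + %.4f*slide + ",
                     "%.4f*stop + %.4f*bend\n  SE model: %s %.3g  [%s]\n"),
              x$intercept, x$w_slide, x$w_stop, x$w_bend,
              x$se_model$type, x$se_model$value, x$provenance))
  invisible(x)
}

model_terms <- function(sequence, pwm, props, masked = integer()) {
  scores <- pwm_scan(sequence, pwm, masked = masked)
  if (all(is.na(scores))) stop("no unmasked window available")
  best <- which.max(scores)  # ties broken toward the most-upstream window
  win <- substr(sequence, best, best + pwm$width - 1L)
  c(slide = slide_term(sequence, props), stop = scores[best],
    bend = bend_term(win, props), best_start = best)
}

#' Estimate TBP-promoter binding affinity from sequence
#'
#' Scans every window of PWM width on the given strand, takes the
#' highest-scoring (highest-affinity, lowest-Kd) window -- ties broken
#' deterministically toward the most-upstream window -- and evaluates the
#' three-stage binding model there. The model output is `-ln(Kd)` with Kd
#' in mol/L; the nM rendering is attached for presentation.
#'
#' @param p a `promoter`.
#' @param pwm a `tata_pwm` (default: the shipped TATA matrix).
#' @param coef a `model_coefficients` (default: calibrated coefficients,
#'   see [default_coefficients()]).
#' @param props dinucleotide property tables.
#' @return object of class `affinity_estimate` with fields `minus_ln_kd`,
#'   `se_ln`, `kd_nM`, `se_nM`, `best_site_start` (TSS-relative),
#'   `best_site_sequence` and `best_site_score`.
#' @examples
#' p <- promoter("CRP", "CRP-201", "tgctttggatataaatccagg")
#' estimate_affinity(p)
#' @export
estimate_affinity <- function(p, pwm = default_tata_pwm(),
                              coef = default_coefficients(),
                              props = dinucleotide_properties()) {
  stopifnot(inherits(p, "promoter"), inherits(pwm, "tata_pwm"),
            inherits(coef, "model_coefficients"))
  if (p$length < pwm$width) stop("promoter shorter than PWM width")
  tm <- model_terms(p$sequence, pwm, props, masked = p$masked)
  mlk <- coef$intercept + coef$w_slide * tm[["slide"]] +
    coef$w_stop * tm[["stop"]] + coef$w_bend * tm[["bend"]]
  se_ln <- if (coef$se_model$type == "relative") coef$se_model$value else
    coef$se_model$value
  kd_nM <- exp(-mlk) * 1e9
  best <- as.integer(tm[["best_start"]])
  structure(list(
    minus_ln_kd = mlk, se_ln = se_ln,
    kd_nM = kd_nM, se_nM = kd_nM * se_ln,
    best_site_start = index_to_tss(best, p$length),
    best_site_sequence = substr(p$sequence, best, best + pwm$width - 1L),
    best_site_score = tm[["stop"]],
    gene_symbol = p$gene_symbol, transcript_id = p$transcript_id),
    class = "affinity_estimate")
}

#' Build an affinity estimate directly from a printed Kd value
#'
#' Used when comparing published estimates: the ln-scale SE is obtained by
#' the delta method, `se_ln = se_nM / kd_nM`.
#'
#' @param kd_nM equilibrium dissociation constant in nM.
#' @param se_nM its standard error in nM.
#' @return an `affinity_estimate` (site fields empty).
#' @export
affinity_from_kd <- function(kd_nM, se_nM) {
  stopifnot(kd_nM > 0, se_nM > 0)
  structure(list(minus_ln_kd = -log(kd_nM * 1e-9), se_ln = se_nM / kd_nM,
                 kd_nM = kd_nM, se_nM = se_nM,
                 best_site_start = NA_integer_,
                 best_site_sequence = NA_character_,
                 best_site_score = NA_real_,
                 gene_symbol = NA_character_, transcript_id = NA_character_),
            class = "affinity_estimate")
}

#' @export
print.affinity_estimate <- function(x, ...) {
  cat(sprintf("<affinity_estimate> Kd = %.2f +/- %.2f nM (-ln Kd = %.3f)\n",
              x$kd_nM, x$se_nM, x$minus_ln_kd))
  if (!is.na(x$best_site_start)) {
    cat(sprintf("  best site at %d: %s (score %.3f)\n",
                x$best_site_start, x$best_site_sequence, x$best_site_score))
  }
  invisible(x)
}

#' Calibrate model coefficients against worked examples
#'
#' Least-squares fit of (intercept, w_slide, w_stop, w_bend) to `-ln(Kd)`
#' of a set of (sequence, Kd) examples. This is the defined fallback when a
#' transcribed coefficient set is not available; the fit residuals are kept
#' on the returned object for inspection.
#'
#' The three stage weights are constrained non-negative: sliding over
#' A/T-rich DNA, recognition of a TATA-like site and bending of the helix
#' each favor complex formation, so a negative weight can only be a fitting
#' artifact of a small calibration set. The constraint is enforced by an
#' active-set scheme (terms whose unconstrained weight is negative are
#' pinned to zero and the rest refitted); a zero weight therefore means the
#' calibration set cannot separate that stage's contribution.
#'
#' @param examples data frame with columns `sequence` and `kd_nM` (at least
#'   4 rows spanning at least 2 distinct promoter contexts).
#' @param pwm a `tata_pwm`.
#' @param props dinucleotide property tables.
#' @param se_model SE model to attach, see [model_coefficients()].
#' @return a `model_coefficients` with `residuals` (in ln units) and
#'   attribute `fitted_kd_nM`.
#' @export
calibrate_coefficients <- function(examples, pwm = default_tata_pwm(),
                                   props = dinucleotide_properties(),
                                   se_model = list(type = "relative",
                                                   value = 0.10)) {
  stopifnot(is.data.frame(examples),
            all(c("sequence", "kd_nM") %in% names(examples)))
  if (nrow(examples) < 4L) {
    stop("calibration needs at least 4 examples (rank-deficient otherwise)")
  }
  if (length(unique(toupper(examples$sequence))) < 2L) {
    stop("calibration examples must span at least 2 distinct sequences")
  }
  tm <- t(vapply(examples$sequence,
                 function(s) model_terms(toupper(s), pwm, props),
                 numeric(4)))
  df <- data.frame(y = -log(examples$kd_nM * 1e-9),
                   slide = tm[, "slide"], stop = tm[, "stop"],
                   bend = tm[, "bend"])
  full <- stats::lm(y ~ slide + stop + bend, data = df)
  if (any(is.na(stats::coef(full))) || full$rank < 4L) {
    stop("rank-deficient calibration design: examples not varied enough")
  }
  terms <- c("slide", "stop", "bend")
  repeat {
    fit <- stats::lm(stats::reformulate(if (length(terms)) terms else "1",
                                        "y"), data = df)
    co <- stats::coef(fit)
    neg <- names(co)[-1][co[-1] < 0]
    if (!length(neg)) break
    terms <- setdiff(terms, neg)
  }
  co <- stats::coef(fit)
  pick <- function(nm) if (nm %in% names(co)) co[[nm]] else 0
  out <- model_coefficients(co[["(Intercept)"]], pick("slide"), pick("stop"),
                            pick("bend"), se_model = se_model,
                            provenance = "calibrated",
                            residuals = stats::residuals(fit))
  attr(out, "fitted_kd_nM") <- exp(-stats::fitted(fit)) * 1e9
  out
}

#' Load the shipped calibration examples
#'
#' Six printed (sequence, Kd) pairs: ancestral and minor alleles of the CRP
#' and SERPINF1 promoter contexts.
#' @return data frame with columns `id`, `gene`, `transcript`, `allele`,
#'   `sequence`, `kd_nM`, `se_nM`.
#' @export
worked_examples <- function() {
  utils::read.delim(
    system.file("extdata", "worked_examples.tsv", package = "snptata"),
    comment.char = "#", stringsAsFactors = FALSE)
}

#' Default coefficients: calibration on the shipped worked examples
#'
#' No transcribed coefficient set ships with the package, so the default
#' path calibrates against the six printed Kd values (see
#' [calibrate_coefficients()]); the result is cached for the session.
#' @return a `model_coefficients` with provenance `"calibrated"`.
#' @export
default_coefficients <- function() {
  cache_get("default_coef", calibrate_coefficients(worked_examples()))
}
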