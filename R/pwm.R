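#' Construct a TATA-box position weight matrix
#'
#' A PWM is a width x 4 matrix of position-specific scores over A, C, G, T.
#' Scores are additive over positions; any real-valued matrix is accepted as
#' long as it is non-degenerate (every position discriminates between at
#' least two bases).
#'
#' @param weights numeric matrix, one row per position, columns A, C, G, T.
#' @param provenance free-text tag recording where the matrix came from.
#' @return object of class `tata_pwm`.
#' @export
tata_pwm <- function(weights, provenance = "unspecified") {
  weights <- as.matrix(weights)
  stopifnot(ncol(weights) == 4L)
  if (nrow(weights) < 6L) stop("PWM width must be at least 6 positions")
  if (!all(is.finite(weights))) stop("PWM entries must be finite")
  colnames(weights) <- BASES
  degenerate <- apply(weights, 1L, function(r) length(unique(r)) < 2L)
  if (any(degenerate)) {
    stop("degenerate PWM row(s): ", paste(which(degenerate), collapse = ", "))
  }
  structure(list(width = nrow(weights), weights = weights,
                 provenance = provenance),
            class = "tata_pwm")
}

#' Read a PWM from a tab-separated config file
#'
#' Expected columns: `position`, `A`, `C`, `G`, `T`. Entries may be either
#' ready-made scores or base frequencies; frequencies (rows summing to 1,
#' all entries in (0,1)) are converted to log-odds against a uniform
#' background.
#'
#' @param path TSV path; `#` lines are comments.
#' @param provenance tag stored on the returned object (default: file name).
#' @return a `tata_pwm`.
#' @export
read_pwm <- function(path, provenance = basename(path)) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("position", BASES) %in% names(tab)))
  tab <- tab[order(tab$position), ]
  w <- as.matrix(tab[, BASES])
  looks_freq <- all(w > 0 & w < 1) && all(abs(rowSums(w) - 1) < 1e-6)
  if (looks_freq) w <- log(w / 0.25)
  tata_pwm(w, provenance = provenance)
}

#' The package's default TATA-box matrix
#'
#' A 15-position matrix derived from canonical TATAWAWR core consensus
#' frequencies with weakly G/C-preferring flanks, shipped as config data so
#' alternative matrices are drop-in replacements.
#' @return a `tata_pwm`.
#' @export
default_tata_pwm <- function() {
  cache_get("default_pwm", read_pwm(
    system.file("extdata", "tata_pwm.tsv", package = "snptata"),
    provenance = "tata_pwm.tsv (synthetic TATAWAWR consensus compilation)"))
}

#' Score one window against a PWM
#'
#' The score is the sum over positions of the weight of the observed base;
#' it is deterministic and linear in positions.
#'
#' @param window nucleotide string of exactly the PWM width, A/C/G/T only.
#' @param pwm a `tata_pwm`.
#' @return numeric score.
#' @export
pwm_site_score <- function(window, pwm) {
  stopifnot(inherits(pwm, "tata_pwm"))
  chars <- strsplit(toupper(window), "")[[1]]
  if (length(chars) != pwm$width) {
    stop(sprintf("window length %d != PWM width %d", length(chars), pwm$width))
  }
  idx <- match(chars, BASES)
  if (anyNA(idx)) stop("window contains non-ACGT base: ", window)
  sum(pwm$weights[cbind(seq_len(pwm$width), idx)])
}

#' Per-position argmax string and score range of a PWM
#'
#' `pwm_consensus` returns the string attaining the maximum achievable
#' score; `pwm_score_range` returns the minimum and maximum achievable
#' scores (per-position minima/maxima summed).
#'
#' @param pwm a `tata_pwm`.
#' @return `pwm_consensus`: a string; `pwm_score_range`: numeric length-2.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$weights, 1L, which.max)], collapse = "")
}

#' @rdname pwm_consensus
#' @export
pwm_score_range <- function(pwm) {
  c(min = sum(apply(pwm$weights, 1L, min)),
    max = sum(apply(pwm$weights, 1L, max)))
}

#' Score every window of a sequence
#'
#' @param sequence nucleotide string at least as long as the PWM.
#' @param pwm a `tata_pwm`.
#' @param masked integer offsets of ambiguous bases; windows covering a
#'   masked offset score `NA` and are excluded from the best-site search.
#' @return numeric vector of window scores, one per start offset.
#' @export
pwm_scan <- function(sequence, pwm, masked = integer()) {
  n <- nchar(sequence)
  if (n < pwm$width) stop("sequence shorter than PWM width")
  starts <- seq_len(n - pwm$width + 1L)
  vapply(starts, function(s) {
    if (length(masked) && any(masked >= s & masked < s + pwm$width)) {
      return(NA_real_)
    }
    pwm_site_score(substr(sequence, s, s + pwm$width - 1L), pwm)
  }, numeric(1))
}
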