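PROCESSES <- c("atherogenesis", "atherosclerosis", "atheroprotection")

#' Fisher Z comparison of two affinity estimates
#'
#' Compares ancestral (`a`) and minor-allele (`b`) estimates on the ln(Kd)
#' scale. SEs reported in nM are propagated to ln units by the delta method
#' (`se_ln = se_nM / kd_nM`). The statistic is
#' `z = |ln Kd_b - ln Kd_a| / sqrt(se_ln_a^2 + se_ln_b^2)` with a two-sided
#' normal tail probability.
#'
#' Direction semantics follow the affinity model: a significant Kd increase
#' (`delta_ln_kd > 0`, lower affinity) is a predicted protein *deficiency*;
#' a significant decrease is an *excess*.
#'
#' @param a,b `affinity_estimate` objects (ancestral, minor).
#' @param alpha two-sided significance level (default 0.05).
#' @return object of class `comparison_result` with fields `z`, `p`,
#'   `delta_ln_kd` and `direction` in
#'   `c("deficiency", "excess", "nonsignificant")`.
#' @examples
#' fisher_z_compare(affinity_from_kd(2.26, 0.23), affinity_from_kd(7.64, 0.76))
#' @export
fisher_z_compare <- function(a, b, alpha = 0.05) {
  stopifnot(inherits(a, "affinity_estimate"), inherits(b, "affinity_estimate"))
  if (!is.finite(a$se_ln) || !is.finite(b$se_ln) || a$se_ln <= 0 || b$se_ln <= 0) {
    stop("both estimates need a finite positive SE")
  }
  delta <- a$minus_ln_kd - b$minus_ln_kd  # = ln(Kd_b) - ln(Kd_a)
  z <- abs(delta) / sqrt(a$se_ln^2 + b$se_ln^2)
  p <- 2 * stats::pnorm(z, lower.tail = FALSE)
  direction <- if (p > alpha) "nonsignificant" else if (delta > 0) "deficiency" else "excess"
  structure(list(z = z, p = p, delta_ln_kd = delta, alpha = alpha,
                 direction = direction),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> z = %.3f, p = %.3g, delta ln(Kd) = %+.3f -> %s\n",
              x$z, x$p, x$delta_ln_kd, x$direction))
  invisible(x)
}

#' Translate an affinity direction into an expression call
#'
#' TBP affinity for a promoter and the expression of the downstream gene
#' move together: a significant affinity loss (Kd up, "deficiency")
#' predicts underexpression, a gain predicts overexpression.
#'
#' @param direction `"deficiency"`, `"excess"` or `"nonsignificant"`
#'   (a `comparison_result` is also accepted).
#' @return `"underexpression"`, `"overexpression"` or `"none"`.
#' @export
classify_expression <- function(direction) {
  if (inherits(direction, "comparison_result")) direction <- direction$direction
  switch(match.arg(direction, c("deficiency", "excess", "nonsignificant")),
         deficiency = "underexpression",
         excess = "overexpression",
         nonsignificant = "none")
}

parse_effect_triple <- function(x) {
  if (is.na(x) || x == "." || !nzchar(x)) {
    return(stats::setNames(rep(NA_character_, 3L), PROCESSES))
  }
  parts <- trimws(strsplit(x, ",")[[1]])
  stopifnot(length(parts) == 3L, all(parts %in% c("worsen", "relief", ".")))
  parts[parts == "."] <- NA_character_
  stats::setNames(parts, PROCESSES)
}

#' Attach per-process health effects to a marker
#'
#' Looks the marker's gene up in the annotation table and maps its
#' expression call (under-/overexpression) to the annotated health effect
#' (`worsen`/`relief`) for each of the three processes. Unannotated genes
#' yield empty effects with a warning rather than an error.
#'
#' @param marker a one-row marker data frame or list with fields
#'   `gene_symbol` and `expression` (the expression call).
#' @param annotations annotation table from [read_gene_annotations()].
#' @return the marker with `health_atherogenesis`, `health_atherosclerosis`
#'   and `health_atheroprotection` filled (NA when undefined).
#' @export
annotate_health <- function(marker, annotations) {
  gene <- marker$gene_symbol
  call <- marker$expression
  eff <- stats::setNames(rep(NA_character_, 3L), PROCESSES)
  row <- match(gene, annotations$gene)
  if (is.na(row)) {
    warning("gene without health annotation: ", gene)
  } else if (call %in% c("underexpression", "overexpression")) {
    col <- if (call == "underexpression") "effect_under" else "effect_over"
    eff <- parse_effect_triple(annotations[[col]][row])
  }
  marker$health_atherogenesis <- eff[["atherogenesis"]]
  marker$health_atherosclerosis <- eff[["atherosclerosis"]]
  marker$health_atheroprotection <- eff[["atheroprotection"]]
  marker
}
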