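#' Screen all SNPs over all promoters for candidate markers
#'
#' Runs one ancestral-vs-minor affinity comparison per (promoter
#' transcript, SNP) pair. A SNP carrying a `transcript_id` is compared on
#' that promoter only; a SNP without one is tried on every promoter whose
#' window contains its position with a matching reference base. The
#' counting unit throughout is the (transcript, SNP) pair; unique-rsID
#' tallies are available from [tally_directions()].
#'
#' @param promoters a `promoter_set`.
#' @param snps list of `snp_variant` objects.
#' @param pwm,coef,props model configuration, see [estimate_affinity()].
#' @param alpha per-comparison two-sided significance level (the screen
#'   applies no multiplicity correction itself; corrections belong to the
#'   downstream summary tests). Set `bonferroni_screen = TRUE` to divide
#'   alpha by the number of comparisons for sensitivity analysis.
#' @param annotations optional annotation table; when supplied, markers are
#'   annotated with per-process health effects.
#' @param strict error (rather than warn and skip) on unresolvable SNPs.
#' @param keep_all also return nonsignificant comparisons (attribute
#'   `"comparisons"`).
#' @param bonferroni_screen apply screen-time Bonferroni to alpha.
#' @return data frame of candidate markers (class `marker_table`), one row
#'   per significant (transcript, SNP) comparison: identifiers, alleles,
#'   both Kd estimates with SEs, `z`, `p`, `direction`, `expression` and
#'   (when annotated) per-process health effects.
#' @export
screen <- function(promoters, snps, pwm = default_tata_pwm(),
                   coef = default_coefficients(),
                   props = dinucleotide_properties(), alpha = 0.05,
                   annotations = NULL, strict = FALSE, keep_all = FALSE,
                   bonferroni_screen = FALSE) {
  stopifnot(inherits(promoters, "promoter_set") || is.list(promoters))
  rows <- list()
  skipped <- character()
  for (v in snps) {
    targets <- if (!is.na(v$transcript_id) && nzchar(v$transcript_id) &&
                   v$transcript_id != "NA") {
      if (!v$transcript_id %in% names(promoters)) {
        msg <- sprintf("%s: transcript %s not in promoter set", v$rsid,
                       v$transcript_id)
        if (strict) stop(msg)
        skipped <- c(skipped, msg)
        next
      }
      promoters[v$transcript_id]
    } else {
      Filter(function(p) {
        v$position >= -p$length &&
          substr(p$sequence, tss_to_index(v$position, p$length),
                 tss_to_index(v$position, p$length)) == v$ref
      }, promoters)
    }
    if (!length(targets)) {
      msg <- sprintf("%s: no promoter matches position %d ref %s", v$rsid,
                     v$position, v$ref)
      if (strict) stop(msg)
      skipped <- c(skipped, msg)
      next
    }
    for (p in targets) {
      minor <- tryCatch(apply_variant(p, v), error = function(e) e)
      if (inherits(minor, "error")) {
        if (strict) stop(conditionMessage(minor))
        skipped <- c(skipped, conditionMessage(minor))
        next
      }
      a <- estimate_affinity(p, pwm, coef, props)
      b <- estimate_affinity(minor, pwm, coef, props)
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = v$rsid, gene_symbol = p$gene_symbol,
        transcript_id = p$transcript_id, position = v$position,
        ref = v$ref, alt = v$alt,
        kd_ancestral_nM = a$kd_nM, se_ancestral_nM = a$se_nM,
        kd_minor_nM = b$kd_nM, se_minor_nM = b$se_nM,
        z = NA_real_, p = NA_real_, delta_ln_kd = NA_real_,
        direction = NA_character_, stringsAsFactors = FALSE)
      cmp <- fisher_z_compare(a, b, alpha = alpha)
      k <- length(rows)
      rows[[k]]$z <- cmp$z; rows[[k]]$p <- cmp$p
      rows[[k]]$delta_ln_kd <- cmp$delta_ln_kd
      rows[[k]]$direction <- cmp$direction
    }
  }
  comparisons <- if (length(rows)) do.call(rbind, rows) else
    utils::read.csv(text = paste0("rsid,gene_symbol,transcript_id,position,",
                                  "ref,alt,kd_ancestral_nM,se_ancestral_nM,",
                                  "kd_minor_nM,se_minor_nM,z,p,delta_ln_kd,",
                                  "direction"))
  eff_alpha <- if (bonferroni_screen && nrow(comparisons) > 0)
    alpha / nrow(comparisons) else alpha
  comparisons$direction[comparisons$p > eff_alpha] <- "nonsignificant"
  comparisons <- comparisons[order(comparisons$transcript_id, comparisons$rsid,
                                   comparisons$alt), , drop = FALSE]
  rownames(comparisons) <- NULL
  markers <- comparisons[comparisons$direction != "nonsignificant", ,
                         drop = FALSE]
  if (nrow(markers)) {
    markers$expression <- vapply(markers$direction, classify_expression, "")
    if (!is.null(annotations)) {
      ann_rows <- lapply(seq_len(nrow(markers)), function(i) {
        suppressWarnings(annotate_health(markers[i, ], annotations))
      })
      markers <- do.call(rbind, ann_rows)
    }
  } else {
    markers$expression <- character(0)
  }
  rownames(markers) <- NULL
  if (length(skipped)) warning("skipped SNPs:\n", paste(skipped, collapse = "\n"))
  class(markers) <- c("marker_table", "data.frame")
  attr(markers, "n_comparisons") <- nrow(comparisons)
  attr(markers, "alpha") <- eff_alpha
  attr(markers, "skipped") <- skipped
  if (keep_all) attr(markers, "comparisons") <- comparisons
  markers
}

#' Tally marker directions
#'
#' Counts affinity-increasing (`excess`, Kd down) against
#' affinity-decreasing (`deficiency`, Kd up) markers. The default counting
#' unit is the (transcript, SNP) comparison; `unit = "rsid"` counts each
#' rsID once (a SNP attached to several transcripts contributes once, by
#' the direction of its most significant comparison).
#'
#' @param markers a `marker_table` from [screen()].
#' @param unit `"comparison"` or `"rsid"`.
#' @return a `count_split` (k_a = increase, k_b = decrease).
#' @export
tally_directions <- function(markers, unit = c("comparison", "rsid")) {
  unit <- match.arg(unit)
  df <- as.data.frame(markers)
  if (unit == "rsid" && nrow(df)) {
    df <- df[order(df$p), ]
    df <- df[!duplicated(df$rsid), ]
  }
  count_split(paste0("affinity direction (per ", unit, ")"),
              sum(df$direction == "excess"),
              sum(df$direction == "deficiency"),
              side_a = "increase", side_b = "decrease")
}

#' Tally per-process health effects of markers
#'
#' @param markers an annotated `marker_table`.
#' @return named list of three `count_split`s (worsen vs relief), one per
#'   process; row sums equal the number of markers with a defined effect
#'   for that process.
#' @export
tally_health <- function(markers) {
  df <- as.data.frame(markers)
  out <- lapply(PROCESSES, function(pr) {
    col <- df[[paste0("health_", pr)]]
    if (is.null(col)) col <- character(0)
    count_split(pr, sum(col == "worsen", na.rm = TRUE),
                sum(col == "relief", na.rm = TRUE),
                side_a = "worsen", side_b = "relief")
  })
  names(out) <- PROCESSES
  out
}

#' Summarize a screen run per gene
#'
#' @param markers a `marker_table` produced with `keep_all = TRUE`.
#' @return data frame with per-gene transcript, comparison and marker
#'   counts and the direction split.
#' @export
screen_summary <- function(markers) {
  comparisons <- attr(markers, "comparisons")
  if (is.null(comparisons)) stop("run screen() with keep_all = TRUE")
  genes <- unique(comparisons$gene_symbol)
  do.call(rbind, lapply(genes, function(g) {
    cg <- comparisons[comparisons$gene_symbol == g, ]
    mg <- markers[markers$gene_symbol == g, , drop = FALSE]
    data.frame(gene_symbol = g,
               n_transcripts = length(unique(cg$transcript_id)),
               n_comparisons = nrow(cg), n_markers = nrow(mg),
               n_increase = sum(mg$direction == "excess"),
               n_decrease = sum(mg$direction == "deficiency"),
               stringsAsFactors = FALSE)
  }))
}
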