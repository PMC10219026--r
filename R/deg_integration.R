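#' Load domestic-versus-wild DEG tables
#'
#' Accepts two tab-separated shapes. Per-gene records carry columns
#' `domestic`, `wild`, `tissue`, `gene`, `direction`
#' (`up_in_domestic`/`down_in_domestic`) and `ref`; per-comparison counts
#' are then derived from the rows, with duplicated (comparison, gene) rows
#' deduplicated under a warning. Summary tables carry an `n_deg` column
#' (one row per species pair x tissue) and are used as published count
#' inputs.
#'
#' @param paths one or more TSV paths; records are concatenated.
#' @return list with `records` (data frame, empty for summary input),
#'   `comparisons` (per-comparison counts with `n_deg`) and `total`
#'   (total DEG count).
#' @export
load_deg_tables <- function(paths) {
  tabs <- lapply(paths, utils::read.delim, comment.char = "#",
                 stringsAsFactors = FALSE)
  tab <- do.call(rbind, tabs)
  if (is.null(tab) || nrow(tab) == 0L) {
    return(list(records = data.frame(), comparisons = data.frame(),
                total = 0L))
  }
  stopifnot(all(c("domestic", "wild", "tissue") %in% names(tab)))
  if (any(tab$domestic == tab$wild)) stop("domestic and wild taxa must differ")
  if ("n_deg" %in% names(tab)) {
    comparisons <- tab
    total <- sum(tab$n_deg)
    records <- data.frame()
  } else {
    stopifnot(all(c("gene", "direction") %in% names(tab)))
    bad <- !tab$direction %in% c("up_in_domestic", "down_in_domestic")
    if (any(bad)) stop("invalid direction value(s): ",
                       paste(unique(tab$direction[bad]), collapse = ", "))
    key <- paste(tab$domestic, tab$wild, tab$tissue, tab$gene, sep = "\r")
    if (anyDuplicated(key)) {
      warning("deduplicated ", sum(duplicated(key)),
              " repeated (comparison, gene) row(s)")
      tab <- tab[!duplicated(key), ]
    }
    agg <- stats::aggregate(list(n_deg = tab$gene),
                            by = tab[, c("domestic", "wild", "tissue")],
                            FUN = length)
    comparisons <- agg
    total <- nrow(tab)
    records <- tab
  }
  list(records = records, comparisons = comparisons, total = as.integer(total))
}

#' Read an animal-to-human homology map
#'
#' @param path TSV with columns `animal_gene`, `human_gene`
#'   (many animal genes may map to one human gene).
#' @return data frame.
#' @export
read_homology_map <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("animal_gene", "human_gene") %in% names(tab)))
  tab
}

#' Concordance counts between animal DEGs and human hub-gene health effects
#'
#' Maps each animal DEG to its human homolog, takes the health effect of
#' the same-direction expression change of that homolog (the `effect_over`
#' map for DEGs up in the domestic animal, `effect_under` for DEGs down),
#' and counts worsen against relief per process. Each DEG record counts
#' once per occurrence by default; `unique_genes = TRUE` collapses to one
#' record per human homolog (first occurrence).
#'
#' @param degs per-gene DEG records (the `records` element of
#'   [load_deg_tables()] or an equivalent data frame).
#' @param homology homology map from [read_homology_map()].
#' @param annotations annotation table with `effect_under`/`effect_over`.
#' @param unique_genes collapse multiple occurrences of a homolog.
#' @return named list of three `count_split`s (worsen vs relief) with
#'   attributes `n_unmapped` and `n_unannotated`.
#' @export
concordance_counts <- function(degs, homology, annotations,
                               unique_genes = FALSE) {
  stopifnot(is.data.frame(degs))
  human <- homology$human_gene[match(degs$gene, homology$animal_gene)]
  n_unmapped <- sum(is.na(human))
  keep <- !is.na(human)
  degs <- degs[keep, , drop = FALSE]
  human <- human[keep]
  ann_row <- match(human, annotations$gene)
  n_unannotated <- sum(is.na(ann_row))
  keep <- !is.na(ann_row)
  degs <- degs[keep, , drop = FALSE]
  ann_row <- ann_row[keep]
  if (unique_genes && nrow(degs)) {
    first <- !duplicated(human[keep])
    degs <- degs[first, , drop = FALSE]
    ann_row <- ann_row[first]
  }
  eff <- t(vapply(seq_len(nrow(degs)), function(i) {
    col <- if (degs$direction[i] == "up_in_domestic") "effect_over" else
      "effect_under"
    parse_effect_triple(annotations[[col]][ann_row[i]])
  }, stats::setNames(character(3), PROCESSES)))
  out <- lapply(PROCESSES, function(pr) {
    col <- if (nrow(degs)) eff[, pr] else character(0)
    count_split(pr, sum(col == "worsen", na.rm = TRUE),
                sum(col == "relief", na.rm = TRUE),
                side_a = "worsen", side_b = "relief")
  })
  names(out) <- PROCESSES
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_unannotated") <- n_unannotated
  out
}
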