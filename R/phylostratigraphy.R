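#' The 29-rank phylostratigraphic age scale
#'
#' Ordered ranks 0..28 from Cellular organisms to Homo; a gene's
#' phylostratigraphic age index (PAI) is the rank of the most recent common
#' ancestor in which its sequence is detectable. PAI values are inputs to
#' this package (they come from BLAST-based orthology scans), never
#' computed here.
#'
#' @return data frame with columns `rank` (0..28) and `name`.
#' @export
pai_scale <- function() {
  cache_get("pai_scale", {
    tab <- utils::read.delim(
      system.file("extdata", "pai_scale.tsv", package = "snptata"),
      comment.char = "#", stringsAsFactors = FALSE)
    stopifnot(nrow(tab) == 29L, identical(tab$rank, 0:28),
              !anyDuplicated(tab$name))
    tab
  })
}

#' Read a gene annotation table
#'
#' Expected tab-separated columns: `gene`, the 0/1 membership columns
#' `atherogenesis`, `atherosclerosis`, `atheroprotection`, `pai` (0..28 or
#' `NA`/`.`), and the health-effect maps `effect_under`, `effect_over`
#' (comma-separated worsen/relief triples in process order, `.` for
#' undefined).
#'
#' @param path TSV path.
#' @return validated annotation data frame.
#' @export
read_gene_annotations <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", na.strings = c("NA", "."),
                           stringsAsFactors = FALSE)
  need <- c("gene", PROCESSES, "pai", "effect_under", "effect_over")
  stopifnot(all(need %in% names(tab)))
  memb <- as.matrix(tab[, PROCESSES]) > 0
  if (any(rowSums(memb) == 0)) {
    stop("genes with empty process membership: ",
         paste(tab$gene[rowSums(memb) == 0], collapse = ", "))
  }
  ok <- is.na(tab$pai) | (tab$pai >= 0 & tab$pai <= 28)
  if (!all(ok)) stop("PAI outside scale for: ", paste(tab$gene[!ok], collapse = ", "))
  tab
}

#' Partition three gene sets into the seven Venn regions
#'
#' @param genesA,genesB,genesC character vectors of gene symbols.
#' @param labels names of the three sets (defaults to the three processes).
#' @return object of class `venn_partition`: a named list of the seven
#'   pairwise-disjoint regions (`A_only`, `B_only`, `C_only`, `AB`, `AC`,
#'   `BC`, `ABC`) whose union equals the union of the inputs, with a
#'   `sizes` attribute.
#' @export
venn_partition <- function(genesA, genesB, genesC,
                           labels = PROCESSES) {
  A <- unique(as.character(genesA)); B <- unique(as.character(genesB))
  C <- unique(as.character(genesC))
  inA <- function(g) g %in% A; inB <- function(g) g %in% B; inC <- function(g) g %in% C
  all_genes <- union(union(A, B), C)
  key <- paste0(ifelse(inA(all_genes), "A", ""),
                ifelse(inB(all_genes), "B", ""),
                ifelse(inC(all_genes), "C", ""))
  regions <- list(
    A_only = all_genes[key == "A"], B_only = all_genes[key == "B"],
    C_only = all_genes[key == "C"], AB = all_genes[key == "AB"],
    AC = all_genes[key == "AC"], BC = all_genes[key == "BC"],
    ABC = all_genes[key == "ABC"])
  sizes <- vapply(regions, length, integer(1))
  stopifnot(sum(sizes) == length(all_genes))  # conservation, by construction
  structure(regions, sizes = sizes, labels = labels,
            class = c("venn_partition", "list"))
}

#' @export
print.venn_partition <- function(x, ...) {
  s <- attr(x, "sizes")
  cat("<venn_partition>", paste(names(s), s, sep = "=", collapse = ", "),
      sprintf(" (total %d)\n", sum(s)))
  invisible(x)
}

#' Summarize PAI over one gene region
#'
#' @param genes character vector of gene symbols (one Venn region).
#' @param annotations annotation table with `gene` and `pai` columns.
#' @return list with `mean`, `sem`, `n` (genes with a PAI) and `n_missing`.
#' @export
region_pai_summary <- function(genes, annotations) {
  if (!length(genes)) stop("empty region")
  pai <- annotations$pai[match(genes, annotations$gene)]
  present <- pai[!is.na(pai)]
  if (!length(present)) stop("all PAIs missing in region")
  ms <- mean_sem(present)
  list(mean = ms$mean, sem = if (ms$sem_defined) ms$sem else NA_real_,
       n = ms$n, n_missing = sum(is.na(pai)))
}

#' Compare the PAI distributions of two gene regions
#'
#' Runs both the nonparametric Mann-Whitney U test and the parametric
#' two-sample z test on means, with method tags, as complementary evidence
#' on whether one region is older (lower PAI) than the other.
#'
#' @param regionX,regionY character vectors of gene symbols.
#' @param annotations annotation table with PAI values.
#' @param alternative passed to both tests (`"less"` tests X older than Y).
#' @return list with elements `mannwhitney` and `mean_z` (both
#'   `test_result`s) and the two summaries.
#' @export
compare_regions <- function(regionX, regionY, annotations,
                            alternative = "two.sided") {
  px <- annotations$pai[match(regionX, annotations$gene)]
  py <- annotations$pai[match(regionY, annotations$gene)]
  px <- px[!is.na(px)]; py <- py[!is.na(py)]
  if (length(px) < 2L || length(py) < 2L) {
    stop("both regions need at least 2 annotated genes")
  }
  list(mannwhitney = mannwhitney_u(px, py, alternative = alternative),
       mean_z = mean_z_test(px, py, alternative = alternative),
       summary_x = mean_sem(px), summary_y = mean_sem(py))
}
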