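BASES <- c("A", "C", "G", "T")

#' Convert TSS-relative positions to string indices and back
#'
#' Promoters are anchored at the transcription start site (TSS): the TSS is
#' position +1, the last promoter base is position -1 and there is no
#' position 0. A promoter of length L covers positions -L..-1, mapped
#' bijectively onto 1-based string indices 1..L.
#'
#' @param pos TSS-relative position(s) in -length..-1.
#' @param length promoter length in nucleotides.
#' @return `tss_to_index` returns 1-based string indices; `index_to_tss`
#'   returns TSS-relative positions.
#' @examples
#' tss_to_index(-90, 90)  # 1
#' index_to_tss(90, 90)   # -1
#' @export
tss_to_index <- function(pos, length) {
  stopifnot(all(pos >= -length), all(pos <= -1))
  pos + length + 1L
}

#' @rdname tss_to_index
#' @param i 1-based string index.
#' @export
index_to_tss <- function(i, length) {
  stopifnot(all(i >= 1), all(i <= length))
  i - length - 1L
}

#' Construct a TSS-anchored promoter sequence
#'
#' @param gene_symbol gene symbol.
#' @param transcript_id transcript identifier (unique key for the record).
#' @param sequence nucleotide string; lower case is canonicalized to upper.
#' @param ambiguity `"strict"` rejects any non-ACGT base; `"lenient"` keeps
#'   the sequence but records ambiguous offsets so that site search can mask
#'   windows containing them.
#' @return an object of class `promoter` with fields `gene_symbol`,
#'   `transcript_id`, `sequence`, `length` and `masked` (integer offsets of
#'   ambiguous bases, empty under strict policy).
#' @export
promoter <- function(gene_symbol, transcript_id, sequence,
                     ambiguity = c("strict", "lenient")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  seq <- toupper(sequence)
  bad <- which(!strsplit(seq, "")[[1]] %in% BASES)
  if (length(bad) && ambiguity == "strict") {
    stop(sprintf("promoter '%s': ambiguity code at offset %s under strict policy",
                 transcript_id, paste(bad, collapse = ",")))
  }
  structure(
    list(gene_symbol = as.character(gene_symbol),
         transcript_id = as.character(transcript_id),
         sequence = seq,
         length = nchar(seq),
         masked = as.integer(bad)),
    class = "promoter")
}

#' @export
print.promoter <- function(x, ...) {
  cat(sprintf("<promoter> %s (%s), %d nt, positions %d..-1\n",
              x$transcript_id, x$gene_symbol, x$length, -x$length))
  invisible(x)
}

#' Read promoters from FASTA plus a metadata table
#'
#' FASTA records are keyed by transcript id; the metadata TSV must contain
#' columns `transcript_id` and `gene_symbol` (optionally `length` for an
#' explicit length check). Record order follows the FASTA file.
#'
#' @param fasta_path path to a FASTA file of promoter sequences.
#' @param metadata_path path to a tab-separated metadata table.
#' @inheritParams promoter
#' @return a named list of `promoter` objects (class `promoter_set`).
#' @export
read_promoters <- function(fasta_path, metadata_path,
                           ambiguity = c("strict", "lenient")) {
  ambiguity <- match.arg(ambiguity)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- utils::read.delim(metadata_path, comment.char = "#",
                            stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "gene_symbol") %in% names(meta)))
  ids <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(ids, meta$transcript_id)
  if (length(missing)) {
    stop("FASTA records without metadata row: ", paste(missing, collapse = ", "))
  }
  out <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    row <- meta[match(ids[k], meta$transcript_id), ]
    s <- as.character(seqs[[k]])
    if (!is.null(row$length) && !is.na(row$length) && nchar(s) != row$length) {
      stop(sprintf("record '%s': sequence length %d != declared %d",
                   ids[k], nchar(s), row$length))
    }
    out[[k]] <- promoter(row$gene_symbol, ids[k], s, ambiguity = ambiguity)
  }
  names(out) <- ids
  class(out) <- c("promoter_set", "list")
  out
}

#' Construct a single-nucleotide variant
#'
#' @param rsid variant identifier.
#' @param position TSS-relative position (negative; -1 is adjacent to TSS).
#' @param ref,alt single reference/alternate nucleotides, `ref != alt`.
#' @param transcript_id optional transcript the variant is annotated on.
#' @return object of class `snp_variant`.
#' @export
snp_variant <- function(rsid, position, ref, alt, transcript_id = NA_character_) {
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(ref %in% BASES, alt %in% BASES)
  if (ref == alt) stop("ref and alt alleles must differ: ", rsid)
  position <- as.integer(position)
  if (is.na(position) || position >= 0L) {
    stop("position must be a negative TSS-relative integer: ", rsid)
  }
  structure(list(rsid = as.character(rsid), position = position,
                 ref = ref, alt = alt,
                 transcript_id = as.character(transcript_id)),
            class = "snp_variant")
}

#' Read SNPs from a TSV table or a minimal VCF dialect
#'
#' The TSV dialect requires columns `rsid`, `position`, `ref`, `alt`
#' (optionally `transcript_id`); positions are TSS-relative. The VCF dialect
#' accepts single-nucleotide REF/ALT only; POS is interpreted through
#' `offset`, a named vector mapping CHROM to the genomic position of the TSS
#' (TSS-relative position = POS - offset[CHROM] - 1 for upstream variants),
#' or POS is taken as already TSS-relative when `offset` is `NULL` and
#' positions are negative.
#'
#' @param table_path input path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param promoters optional `promoter_set`; variants carrying a
#'   `transcript_id` are validated against their promoter window.
#' @param offset named numeric vector of per-CHROM TSS coordinates (VCF only).
#' @return list of `snp_variant` objects.
#' @export
read_snps <- function(table_path, dialect = c("tsv", "vcf"),
                      promoters = NULL, offset = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- utils::read.delim(table_path, comment.char = "#",
                             stringsAsFactors = FALSE)
    stopifnot(all(c("rsid", "position", "ref", "alt") %in% names(tab)))
    tid <- if ("transcript_id" %in% names(tab)) tab$transcript_id else NA
    vars <- lapply(seq_len(nrow(tab)), function(i) {
      snp_variant(tab$rsid[i], tab$position[i], tab$ref[i], tab$alt[i],
                  transcript_id = if (all(is.na(tid))) NA else tid[i])
    })
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("the VCF dialect requires the vcfR package")
    }
    v <- vcfR::read.vcfR(table_path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(fix)  # single-record files
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    bad <- nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L |
      !toupper(fix$REF) %in% BASES | !toupper(fix$ALT) %in% BASES
    if (any(bad)) {
      stop("VCF dialect accepts single-nucleotide REF/ALT only; offending: ",
           paste(fix$ID[bad], collapse = ", "))
    }
    pos <- as.integer(fix$POS)
    if (!is.null(offset)) {
      if (!all(fix$CHROM %in% names(offset))) {
        stop("no TSS offset supplied for CHROM: ",
             paste(setdiff(fix$CHROM, names(offset)), collapse = ", "))
      }
      pos <- pos - as.integer(offset[fix$CHROM]) - 1L
    }
    vars <- lapply(seq_len(nrow(fix)), function(i) {
      snp_variant(fix$ID[i], pos[i], fix$REF[i], fix$ALT[i])
    })
  }
  if (!is.null(promoters)) {
    for (v in vars) {
      if (!is.na(v$transcript_id) && v$transcript_id %in% names(promoters)) {
        p <- promoters[[v$transcript_id]]
        if (v$position < -p$length) {
          stop(sprintf("%s: position %d outside promoter window [-%d, -1] of %s",
                       v$rsid, v$position, p$length, p$transcript_id))
        }
      }
    }
  }
  vars
}

#' Apply a variant to a promoter, producing the minor-allele sequence
#'
#' The returned promoter differs from the input at exactly one position;
#' applying the allele-swapped variant to the result restores the input.
#'
#' @param p a `promoter`.
#' @param v a `snp_variant`; the promoter base at `v$position` must equal
#'   `v$ref` (a mismatch signals stale coordinates or wrong strand and is an
#'   error, leaving the input unchanged).
#' @return a new `promoter` carrying the alternate allele.
#' @export
apply_variant <- function(p, v) {
  stopifnot(inherits(p, "promoter"), inherits(v, "snp_variant"))
  if (v$position < -p$length) {
    stop(sprintf("%s: position %d outside promoter window [-%d, -1]",
                 v$rsid, v$position, p$length))
  }
  i <- tss_to_index(v$position, p$length)
  have <- substr(p$sequence, i, i)
  if (have != v$ref) {
    stop(sprintf("%s: promoter %s has '%s' at position %d, expected ref '%s'",
                 v$rsid, p$transcript_id, have, v$position, v$ref))
  }
  s <- p$sequence
  substr(s, i, i) <- v$alt
  promoter(p$gene_symbol, p$transcript_id, s)
}

#' Write promoters to FASTA
#'
#' @param promoters a `promoter_set` or list of `promoter` objects.
#' @param path output path.
#' @export
write_promoters_fasta <- function(promoters, path) {
  lines <- unlist(lapply(promoters, function(p) {
    c(sprintf(">%s %s", p$transcript_id, p$gene_symbol), p$sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}
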