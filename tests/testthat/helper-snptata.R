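# Shared fixtures and independent oracles.

# A promoter set wrapping plain promoter objects.
as_promoter_set <- function(...) {
  ps <- list(...)
  names(ps) <- vapply(ps, `[[`, "", "transcript_id")
  structure(ps, class = c("promoter_set", "list"))
}

random_sequence <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Write a FASTA + metadata pair for read_promoters().
write_promoter_fixture <- function(seqs, genes = names(seqs)) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(unlist(mapply(function(id, s) c(paste0(">", id), s),
                           names(seqs), seqs, SIMPLIFY = FALSE)), fa)
  meta <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(transcript_id = names(seqs), gene_symbol = genes,
               length = nchar(unlist(seqs))),
    meta, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fa, metadata = meta)
}

# Exact binomial tail by explicit enumeration of outcome counts.
oracle_binom_tail <- function(k, n, theta, side = "le") {
  ks <- if (side == "le") 0:k else k:n
  sum(choose(n, ks) * theta^ks * (1 - theta)^(n - ks))
}

# Exact binomial tail by full enumeration of the 2^n outcome space
# (theta = 0.5 only; feasible for small n).
oracle_binom_tail_2n <- function(k, n, side = "le") {
  counts <- vapply(0:(2^n - 1), function(x) sum(bitwAnd(x, 2^(0:(n - 1))) > 0),
                   numeric(1))
  if (side == "le") mean(counts <= k) else mean(counts >= k)
}

# Exact Mann-Whitney p by enumeration of all group labelings.
oracle_mannwhitney <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_null <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  u_obs <- u_of(x, y)
  switch(alternative,
         less = mean(u_null <= u_obs),
         greater = mean(u_null >= u_obs),
         two.sided = min(1, 2 * min(mean(u_null <= u_obs),
                                    mean(u_null >= u_obs))))
}

shipped <- function(name) system.file("extdata", name, package = "snptata")

# Coefficients with only the stop term active: isolates the PWM-score
# dependence of Kd for monotonicity checks.
stop_only_coefficients <- function(w_stop = 0.25) {
  model_coefficients(15, 0, w_stop, 0, provenance = "test")
}
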