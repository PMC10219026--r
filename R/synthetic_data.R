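#' Configuration for the synthetic-data generator
#'
#' One seeded configuration drives every sub-generator; each sub-generator
#' draws from its own stream (derived from the seed and a stable label), so
#' outputs are byte-identical under a fixed seed and adding one generator
#' never perturbs another.
#'
#' @param seed global integer seed.
#' @param n_genes number of genes with promoters.
#' @param transcripts_per_gene promoter-bearing transcripts per gene.
#' @param promoter_length promoter length in nt (TSS-anchored).
#' @param base_composition named A/C/G/T background probabilities; the
#'   default is mildly G/C-rich, as human proximal promoters are.
#' @param box_fraction fraction of transcripts receiving an embedded
#'   TATA box.
#' @param tata_strength embedded box strength in [0, 1]: the target PWM
#'   score as a fraction of the achievable score range (1 = consensus).
#' @param box_start TSS-relative start position of the embedded box; the
#'   default places the core element around -30..-24.
#' @param n_snps number of SNPs to plant.
#' @param in_box_fraction fraction of SNPs planted inside embedded boxes.
#' @param direction_bias fraction of in-box SNPs planted toward the
#'   consensus (expected affinity increase); the rest are planted away
#'   from it (expected decrease).
#' @param venn_sizes named integer vector of the seven region sizes for
#'   the annotation generator.
#' @param n_annotation_genes total genes in the annotation universe (must
#'   be at least `sum(venn_sizes)`).
#' @param pai_region_means named per-region mean PAI ranks (in
#'   expectation; draws are binomial on the 0..28 scale).
#' @param deg_n number of mapped animal DEG records.
#' @param deg_concordance planted concordance rate for the focal process
#'   (atheroprotection); the discordant COUNT `round((1 - rate) * deg_n)`
#'   is realized exactly, randomizing only which records are discordant.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 16L, transcripts_per_gene = 2L,
                       promoter_length = 90L,
                       base_composition = c(A = 0.22, C = 0.28, G = 0.28,
                                            T = 0.22),
                       box_fraction = 1.0, tata_strength = 0.8,
                       box_start = -34L,
                       n_snps = 100L, in_box_fraction = 0.5,
                       direction_bias = 0.5,
                       venn_sizes = c(A_only = 58L, B_only = 856L,
                                      C_only = 10L, AB = 106L, AC = 0L,
                                      BC = 21L, ABC = 16L),
                       n_annotation_genes = NULL,
                       pai_region_means = c(A_only = 10, B_only = 12,
                                            C_only = 10, AB = 7, AC = 10,
                                            BC = 8, ABC = 4),
                       deg_n = 26L, deg_concordance = 24 / 26) {
  probs <- c(box_fraction, tata_strength, in_box_fraction, direction_bias,
             deg_concordance, base_composition)
  stopifnot(all(probs >= 0), all(probs <= 1),
            abs(sum(base_composition) - 1) < 1e-8,
            identical(sort(names(base_composition)), BASES))
  if (is.null(n_annotation_genes)) n_annotation_genes <- sum(venn_sizes)
  if (sum(venn_sizes) > n_annotation_genes) {
    stop("venn_sizes sum exceeds n_annotation_genes")
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 transcripts_per_gene = as.integer(transcripts_per_gene),
                 promoter_length = as.integer(promoter_length),
                 base_composition = base_composition[BASES],
                 box_fraction = box_fraction, tata_strength = tata_strength,
                 box_start = as.integer(box_start),
                 n_snps = as.integer(n_snps),
                 in_box_fraction = in_box_fraction,
                 direction_bias = direction_bias,
                 venn_sizes = venn_sizes,
                 n_annotation_genes = as.integer(n_annotation_genes),
                 pai_region_means = pai_region_means,
                 deg_n = as.integer(deg_n),
                 deg_concordance = deg_concordance),
            class = "sim_config")
}

# Degrade the consensus string to the target score
# min + strength * (max - min): while above target, apply a random
# single-base demotion among those that stay at or above the target; when
# none exists, take the demotion with the smallest overshoot and stop. The
# realized score therefore sits tightly at the target (recorded in the
# truth table); strength = 1 leaves the consensus untouched.
sample_box <- function(pwm, strength) {
  rng <- pwm_score_range(pwm)
  target <- rng[["min"]] + strength * (rng[["max"]] - rng[["min"]])
  chars <- strsplit(pwm_consensus(pwm), "")[[1]]
  score <- pwm_site_score(paste(chars, collapse = ""), pwm)
  guard <- 0L
  while (score > target + 1e-9 && guard < 1000L) {
    guard <- guard + 1L
    moves <- do.call(rbind, lapply(seq_len(pwm$width), function(i) {
      w <- pwm$weights[i, ]
      drop <- w[[chars[i]]] - w[w < w[[chars[i]]]]
      if (!length(drop)) return(NULL)
      data.frame(i = i, base = names(w)[w < w[[chars[i]]]], drop = drop)
    }))
    if (is.null(moves)) break
    feasible <- moves[score - moves$drop >= target - 1e-9, , drop = FALSE]
    if (nrow(feasible)) {
      mv <- feasible[sample.int(nrow(feasible), 1L), ]
    } else {
      mv <- moves[which.min(moves$drop), ]  # minimal overshoot, then stop
    }
    chars[mv$i] <- mv$base
    score <- score - mv$drop
    if (!nrow(feasible)) break
  }
  paste(chars, collapse = "")
}

#' Generate promoters with embedded TATA boxes of known strength
#'
#' Background bases are sampled from the configured composition; for the
#' flagged fraction of transcripts a PWM-sampled box of the requested
#' strength replaces the background bases at the configured position
#' (promoter length is preserved). The returned truth table records every
#' embedded box.
#'
#' @param cfg a `sim_config`.
#' @param pwm the PWM boxes are sampled from.
#' @return list with `promoters` (a `promoter_set`) and `truth` (data
#'   frame: transcript, box flag, box start, realized box string and
#'   score).
#' @export
gen_promoters <- function(cfg, pwm = default_tata_pwm()) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$promoter_length
  if (pwm$width > L) stop("box longer than promoter")
  box_i <- tss_to_index(cfg$box_start, L)
  if (box_i + pwm$width - 1L > L) stop("embedded box extends past the promoter")
  with_stream(cfg$seed, "promoters", {
    proms <- list(); truth <- list()
    for (g in seq_len(cfg$n_genes)) {
      gene <- sprintf("GENE%03d", g)
      for (t in seq_len(cfg$transcripts_per_gene)) {
        tid <- sprintf("%s-T%02d", gene, t)
        seq <- paste(sample(BASES, L, replace = TRUE,
                            prob = cfg$base_composition), collapse = "")
        has_box <- stats::runif(1) < cfg$box_fraction
        box <- NA_character_
        if (has_box) {
          box <- sample_box(pwm, cfg$tata_strength)
          substr(seq, box_i, box_i + pwm$width - 1L) <- box
        }
        proms[[tid]] <- promoter(gene, tid, seq)
        truth[[tid]] <- data.frame(
          transcript_id = tid, gene_symbol = gene, has_box = has_box,
          box_start = if (has_box) cfg$box_start else NA_integer_,
          box_sequence = box,
          box_score = if (has_box) pwm_site_score(box, pwm) else NA_real_,
          strength = if (has_box) cfg$tata_strength else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    class(proms) <- c("promoter_set", "list")
    list(promoters = proms, truth = do.call(rbind, truth))
  })
}

# PWM positions whose score range is in the upper half across positions:
# substitutions there move the site score far enough to matter.
high_info_positions <- function(pwm) {
  rng <- apply(pwm$weights, 1L, function(w) max(w) - min(w))
  which(rng >= stats::median(rng))
}

#' Generate a SNP set with known expected affinity-change directions
#'
#' In-box SNPs hit high-information PWM positions: substitutions away from
#' the consensus base are labelled `expected = "deficiency"` (affinity
#' loss), substitutions toward it `"excess"`. Out-of-box SNPs land outside
#' every window overlapping the embedded box and are labelled `"neutral"`.
#' At most one SNP is planted per (transcript, position).
#'
#' @param promoters,truth output of [gen_promoters()].
#' @param cfg the `sim_config`.
#' @param pwm PWM used for the box (defines position information content).
#' @return data frame with columns `rsid`, `transcript_id`, `position`,
#'   `ref`, `alt`, `expected`.
#' @export
gen_snps <- function(promoters, truth, cfg, pwm = default_tata_pwm()) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$promoter_length
  n_in <- round(cfg$n_snps * cfg$in_box_fraction)
  n_out <- cfg$n_snps - n_in
  boxed <- truth$transcript_id[truth$has_box]
  hi <- high_info_positions(pwm)
  avail_in <- length(boxed) * length(hi)
  box_lo <- tss_to_index(cfg$box_start, L)
  box_hi <- box_lo + pwm$width - 1L
  # positions whose windows never overlap the box
  out_idx <- setdiff(seq_len(L), seq(max(1L, box_lo - pwm$width + 1L),
                                     min(L, box_hi + pwm$width - 1L)))
  avail_out <- length(promoters) * length(out_idx)
  if (n_in > avail_in || n_out > avail_out) {
    stop("SNP density exceeds available positions")
  }
  with_stream(cfg$seed, "snps", {
    rows <- list()
    used <- character()
    # Plant the wanted direction first (excess with probability
    # direction_bias), then look for a (transcript, box position) that can
    # host it: toward-consensus needs a degraded position, away-from needs
    # a base that is not already the weakest. Falls back to the other
    # direction when the wanted one has no free host left.
    plant_in_box <- function(want_excess) {
      for (try in seq_len(500L)) {
        tid <- sample(boxed, 1L)
        pos_in_box <- sample(hi, 1L)
        i <- box_lo + pos_in_box - 1L
        keyu <- paste(tid, i)
        if (keyu %in% used) next
        ref <- substr(promoters[[tid]]$sequence, i, i)
        w <- pwm$weights[pos_in_box, ]
        consensus_base <- names(w)[which.max(w)]
        if (want_excess) {
          if (ref == consensus_base) next
          alt <- consensus_base; expected <- "excess"
        } else {
          lower <- names(w)[w < w[[ref]]]
          if (!length(lower)) next
          alt <- lower[which.min(w[lower])]; expected <- "deficiency"
        }
        used <<- c(used, keyu)
        return(data.frame(rsid = NA_character_, transcript_id = tid,
                          position = index_to_tss(i, L), ref = ref,
                          alt = alt, expected = expected,
                          stringsAsFactors = FALSE))
      }
      NULL
    }
    for (k in seq_len(n_in)) {
      want_excess <- stats::runif(1) < cfg$direction_bias
      row <- plant_in_box(want_excess)
      if (is.null(row)) row <- plant_in_box(!want_excess)
      if (is.null(row)) stop("SNP density exceeds available in-box positions")
      row$rsid <- sprintf("sim_in_%04d", k)
      rows[[length(rows) + 1L]] <- row
    }
    k <- 0L
    attempts <- 0L
    while (k < n_out) {
      attempts <- attempts + 1L
      if (attempts > 50L * n_out + 1000L) {
        stop("SNP density exceeds available out-of-box positions")
      }
      tid <- sample(names(promoters), 1L)
      i <- sample(out_idx, 1L)
      keyu <- paste(tid, i)
      if (keyu %in% used) next
      used <- c(used, keyu)
      p <- promoters[[tid]]
      ref <- substr(p$sequence, i, i)
      alt <- sample(setdiff(BASES, ref), 1L)
      k <- k + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = sprintf("sim_out_%04d", k), transcript_id = tid,
        position = index_to_tss(i, L), ref = ref, alt = alt,
        expected = "neutral", stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Generate an annotation table with planted Venn structure and PAI means
#'
#' Region sizes are realized exactly; PAI ranks are drawn per gene from a
#' binomial on the 0..28 scale whose mean equals the configured region
#' mean. Health-effect maps are drawn uniformly (worsen/relief per
#' process) with `effect_under` the flip of `effect_over`.
#'
#' @param cfg a `sim_config`.
#' @return annotation data frame in the format of
#'   [read_gene_annotations()], with a `region` column recording the truth.
#' @export
gen_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sizes <- cfg$venn_sizes
  need <- c("A_only", "B_only", "C_only", "AB", "AC", "BC", "ABC")
  stopifnot(all(need %in% names(sizes)))
  with_stream(cfg$seed, "annotations", {
    region <- rep(need, times = sizes[need])
    n <- length(region)
    gene <- sprintf("SGENE%04d", seq_len(n))
    inA <- region %in% c("A_only", "AB", "AC", "ABC")
    inB <- region %in% c("B_only", "AB", "BC", "ABC")
    inC <- region %in% c("C_only", "AC", "BC", "ABC")
    pai <- vapply(region, function(r) {
      stats::rbinom(1L, 28L, cfg$pai_region_means[[r]] / 28)
    }, integer(1))
    over <- replicate(n, paste(sample(c("worsen", "relief"), 3L,
                                      replace = TRUE), collapse = ","))
    under <- vapply(strsplit(over, ","), function(x) {
      paste(ifelse(x == "worsen", "relief", "worsen"), collapse = ",")
    }, "")
    data.frame(gene = gene, atherogenesis = as.integer(inA),
               atherosclerosis = as.integer(inB),
               atheroprotection = as.integer(inC), pai = pai,
               effect_under = under, effect_over = over, region = region,
               stringsAsFactors = FALSE)
  })
}

#' Generate DEG records and a homology map with a planted concordance rate
#'
#' Selects `deg_n` annotated human genes and emits one up-in-domestic DEG
#' record per gene through a constructed animal-to-human homology map. For
#' the focal process (atheroprotection) exactly
#' `round((1 - deg_concordance) * deg_n)` records map to a `worsen` effect;
#' which records are discordant is randomized.
#'
#' @param cfg a `sim_config`.
#' @param annotations annotation table (e.g. from [gen_annotations()]).
#' @return list with `degs` (DEG records), `homology` (map) and
#'   `n_discordant` (the planted worsen count).
#' @export
gen_deg_tables <- function(cfg, annotations) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stream(cfg$seed, "degs", {
    eff <- vapply(annotations$effect_over,
                  function(x) parse_effect_triple(x)[["atheroprotection"]], "")
    relief_pool <- annotations$gene[eff == "relief"]
    worsen_pool <- annotations$gene[eff == "worsen"]
    n_disc <- round((1 - cfg$deg_concordance) * cfg$deg_n)
    n_conc <- cfg$deg_n - n_disc
    if (length(relief_pool) < n_conc || length(worsen_pool) < n_disc) {
      stop("annotation table too small for the requested concordance split")
    }
    human <- sample(c(sample(relief_pool, n_conc),
                      sample(worsen_pool, n_disc)))
    animal <- paste0(tolower(human), "_anim")
    species <- data.frame(
      domestic = c("dogs", "pigs", "tame rats", "domestic rabbits"),
      wild = c("wolves", "boars", "aggressive rats", "wild rabbits"))
    pick <- sample.int(nrow(species), cfg$deg_n, replace = TRUE)
    degs <- data.frame(domestic = species$domestic[pick],
                       wild = species$wild[pick],
                       tissue = sample(c("frontal cortex", "blood",
                                         "hypothalamus", "pituitary"),
                                       cfg$deg_n, replace = TRUE),
                       gene = animal, direction = "up_in_domestic",
                       ref = "synthetic", stringsAsFactors = FALSE)
    list(degs = degs,
         homology = data.frame(animal_gene = animal, human_gene = human,
                               stringsAsFactors = FALSE),
         n_discordant = n_disc)
  })
}

#' Write a full synthetic dataset to disk
#'
#' Emits exactly the formats the readers consume (promoter FASTA +
#' metadata, SNP TSV, annotation TSV, DEG and homology TSVs) plus a
#' manifest JSON recording the configuration, seed and per-file MD5
#' hashes.
#'
#' @param cfg a `sim_config`.
#' @param dir output directory (created if missing).
#' @param pwm PWM used for boxes.
#' @return invisibly, the manifest as a list.
#' @export
write_synthetic_dataset <- function(cfg, dir, pwm = default_tata_pwm()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- gen_promoters(cfg, pwm)
  snps <- gen_snps(gp$promoters, gp$truth, cfg, pwm)
  ann <- gen_annotations(cfg)
  deg <- gen_deg_tables(cfg, ann)
  paths <- file.path(dir, c(fasta = "promoters.fasta",
                            meta = "promoter_metadata.tsv",
                            snps = "snps.tsv", truth = "box_truth.tsv",
                            ann = "annotations.tsv", degs = "degs.tsv",
                            hom = "homology.tsv"))
  names(paths) <- c("fasta", "meta", "snps", "truth", "ann", "degs", "hom")
  write_promoters_fasta(gp$promoters, paths[["fasta"]])
  meta <- data.frame(
    transcript_id = vapply(gp$promoters, `[[`, "", "transcript_id"),
    gene_symbol = vapply(gp$promoters, `[[`, "", "gene_symbol"),
    length = vapply(gp$promoters, `[[`, 0L, "length"))
  wt <- function(x, f) utils::write.table(x, f, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(meta, paths[["meta"]])
  wt(snps, paths[["snps"]])
  wt(gp$truth, paths[["truth"]])
  wt(ann, paths[["ann"]])
  wt(deg$degs, paths[["degs"]])
  wt(deg$homology, paths[["hom"]])
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(paths)), names(paths))),
                   n_discordant = deg$n_discordant)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
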