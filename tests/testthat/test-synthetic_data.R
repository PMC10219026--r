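test_that("the full generator surface is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 101, n_genes = 4, transcripts_per_gene = 2,
                    n_snps = 30)
  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic_dataset(cfg, d1)
  write_synthetic_dataset(cfg, d2)
  for (f in c("promoters.fasta", "snps.tsv", "annotations.tsv", "degs.tsv",
              "homology.tsv", "box_truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the promoters
  d3 <- tempfile()
  write_synthetic_dataset(sim_config(seed = 102, n_genes = 4,
                                     transcripts_per_gene = 2, n_snps = 30),
                          d3)
  expect_false(identical(readLines(file.path(d1, "promoters.fasta")),
                         readLines(file.path(d3, "promoters.fasta"))))
})

test_that("strength-1 boxes are the consensus string, embedded in place", {
  pwm <- default_tata_pwm()
  cfg <- sim_config(seed = 103, n_genes = 3, transcripts_per_gene = 1,
                    tata_strength = 1)
  gp <- gen_promoters(cfg)
  for (tid in names(gp$promoters)) {
    p <- gp$promoters[[tid]]
    expect_identical(p$length, 90L)
    i <- tss_to_index(-34L, 90L)
    expect_identical(substr(p$sequence, i, i + 14), pwm_consensus(pwm))
    expect_identical(gp$truth$box_sequence[gp$truth$transcript_id == tid],
                     pwm_consensus(pwm))
  }
})

test_that("weaker boxes land near the requested score fraction", {
  pwm <- default_tata_pwm()
  rng <- pwm_score_range(pwm)
  for (s in c(0.5, 0.8)) {
    cfg <- sim_config(seed = 105, n_genes = 5, transcripts_per_gene = 1,
                      tata_strength = s)
    realized <- gen_promoters(cfg)$truth$box_score
    target <- rng[["min"]] + s * (rng[["max"]] - rng[["min"]])
    expect_true(all(realized <= target + 1e-9))
    # within one worst-case single-base demotion of the target
    expect_true(all(realized > target - max(apply(pwm$weights, 1, max) -
                                              apply(pwm$weights, 1, min))))
  }
})

test_that("boxes longer than the promoter are rejected", {
  expect_error(gen_promoters(sim_config(seed = 1, promoter_length = 10)),
               "longer than promoter")
})

test_that("planted SNP labels follow the consensus geometry", {
  pwm <- default_tata_pwm()
  cfg <- sim_config(seed = 107, n_genes = 6, transcripts_per_gene = 2,
                    n_snps = 60, in_box_fraction = 0.5)
  gp <- gen_promoters(cfg)
  snps <- gen_snps(gp$promoters, gp$truth, cfg)
  expect_identical(nrow(snps), 60L)
  box_lo <- -34L; box_hi <- -34L + 14L
  in_box <- snps$position >= box_lo & snps$position <= box_hi
  expect_true(all(snps$expected[!in_box] == "neutral"))
  expect_true(all(snps$expected[in_box] %in% c("deficiency", "excess")))
  cons <- strsplit(pwm_consensus(pwm), "")[[1]]
  for (i in which(in_box)) {
    pos_in_box <- snps$position[i] - box_lo + 1L
    if (snps$expected[i] == "excess") {
      expect_identical(snps$alt[i], cons[pos_in_box])
    } else {
      w <- pwm$weights[pos_in_box, ]
      expect_lt(w[[snps$alt[i]]], w[[snps$ref[i]]])
    }
  }
  # no two SNPs share a (transcript, position) slot
  expect_false(anyDuplicated(snps[, c("transcript_id", "position")]) > 0)
})

test_that("excessive SNP density is rejected", {
  cfg <- sim_config(seed = 1, n_genes = 1, transcripts_per_gene = 1,
                    n_snps = 500, in_box_fraction = 1)
  gp <- gen_promoters(cfg)
  expect_error(gen_snps(gp$promoters, gp$truth, cfg), "density")
})

test_that("strong-box promoters always bind better than no-box promoters", {
  wins <- 0L
  for (seed in 1:100) {
    strong <- gen_promoters(sim_config(seed = seed, n_genes = 1,
                                       transcripts_per_gene = 1,
                                       tata_strength = 1))$promoters[[1]]
    none <- gen_promoters(sim_config(seed = seed, n_genes = 1,
                                     transcripts_per_gene = 1,
                                     box_fraction = 0))$promoters[[1]]
    wins <- wins + (estimate_affinity(strong)$kd_nM <
                      estimate_affinity(none)$kd_nM)
  }
  expect_identical(wins, 100L)
})

test_that("annotation generation realizes sizes exactly and means in expectation", {
  cfg <- sim_config(seed = 109)
  ann <- gen_annotations(cfg)
  expect_identical(nrow(ann), 1067L)
  expect_false(anyDuplicated(ann$gene) > 0)
  for (r in unique(ann$region)) {
    pai <- ann$pai[ann$region == r]
    m <- cfg$pai_region_means[[r]]
    sem <- max(stats::sd(pai) / sqrt(length(pai)), 0.5)
    expect_lt(abs(mean(pai) - m), 3 * sem + 0.5)
  }
  # under/over effect maps are exact flips
  set.seed(1)
  pick <- sample(nrow(ann), 20)
  u <- strsplit(ann$effect_under[pick], ",")
  o <- strsplit(ann$effect_over[pick], ",")
  for (k in seq_along(u)) {
    expect_true(all((u[[k]] == "worsen") == (o[[k]] == "relief")))
  }
})

test_that("oversized region requests are rejected", {
  expect_error(sim_config(venn_sizes = c(A_only = 10L, B_only = 10L,
                                         C_only = 10L, AB = 0L, AC = 0L,
                                         BC = 0L, ABC = 0L),
                          n_annotation_genes = 20L),
               "exceeds")
})

test_that("DEG generation plants the discordant count exactly", {
  cfg <- sim_config(seed = 111)
  ann <- gen_annotations(cfg)
  deg <- gen_deg_tables(cfg, ann)
  expect_identical(deg$n_discordant, 2)
  conc <- concordance_counts(deg$degs, deg$homology, ann)
  expect_identical(c(conc$atheroprotection$k_a, conc$atheroprotection$k_b),
                   c(2L, 24L))
})
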