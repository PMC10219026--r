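test_that("slide and bend terms are pure lookup statistics", {
  props <- dinucleotide_properties()
  set.seed(21)
  for (rep in 1:15) {
    s <- random_sequence(sample(10:90, 1))
    chars <- strsplit(s, "")[[1]]
    steps <- paste0(chars[-length(chars)], chars[-1])
    expect_equal(slide_term(s), mean(props$slide[steps]))
    expect_equal(bend_term(s), sum(props$bend[steps]))
    expect_equal(slide_term(s), slide_term(s))  # deterministic
  }
  expect_error(slide_term("A"), "shorter than 2")
})

test_that("TA-rich windows are more bendable than GC-rich windows", {
  expect_gt(bend_term(strrep("TA", 8)), bend_term(strrep("GC", 8)))
  expect_gt(bend_term("TATAAATA"), bend_term("GCGCGCGC"))
})

test_that("Kd and -ln(Kd) renderings are mutually consistent", {
  ps <- gen_promoters(sim_config(seed = 3, n_genes = 4,
                                 transcripts_per_gene = 1))$promoters
  for (p in ps) {
    a <- estimate_affinity(p)
    expect_lt(abs(a$minus_ln_kd + log(a$kd_nM * 1e-9)), 1e-9)
    expect_gt(a$kd_nM, 0)
    expect_gt(a$se_nM, 0)
    idx <- tss_to_index(a$best_site_start, p$length)
    expect_identical(substr(p$sequence, idx, idx + 14), a$best_site_sequence)
  }
})

test_that("the default SE model reproduces the observed SE/Kd band", {
  ex <- worked_examples()
  # the published estimates show SE/Kd between 0.07 and 0.11
  expect_true(all(ex$se_nM / ex$kd_nM >= 0.07 & ex$se_nM / ex$kd_nM <= 0.11))
  p <- promoter(ex$gene[1], ex$transcript[1], ex$sequence[1])
  a <- estimate_affinity(p)
  expect_gte(a$se_nM / a$kd_nM, 0.07)
  expect_lte(a$se_nM / a$kd_nM, 0.11)
})

test_that("Kd is monotone non-increasing in the best-window score", {
  # stop-only coefficients isolate the site-recognition term
  coef <- stop_only_coefficients()
  pwm <- default_tata_pwm()
  set.seed(31)
  for (rep in 1:20) {
    p <- promoter("G", "T1", random_sequence(60))
    a <- estimate_affinity(p, pwm, coef)
    i <- sample(60, 1)
    ref <- substr(p$sequence, i, i)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    q <- apply_variant(p, snp_variant("rs", index_to_tss(i, 60), ref, alt))
    b <- estimate_affinity(q, pwm, coef)
    if (b$best_site_score > a$best_site_score) {
      expect_lte(b$kd_nM, a$kd_nM)
    } else if (b$best_site_score < a$best_site_score) {
      expect_gte(b$kd_nM, a$kd_nM)
    } else {
      expect_equal(b$kd_nM, a$kd_nM)
    }
  }
})

test_that("substitutions outside the best-attaining windows leave the site score unchanged", {
  coef <- stop_only_coefficients()
  cfg <- sim_config(seed = 5, n_genes = 3, transcripts_per_gene = 1,
                    tata_strength = 1)
  ps <- gen_promoters(cfg)$promoters
  for (p in ps) {
    a <- estimate_affinity(p, coef = coef)
    # mutate the promoter's last base: the embedded box ends at -20,
    # so no window attaining the best score covers position -1
    ref <- substr(p$sequence, p$length, p$length)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    q <- apply_variant(p, snp_variant("rs", -1L, ref, alt))
    b <- estimate_affinity(q, coef = coef)
    expect_equal(b$best_site_score, a$best_site_score)
  }
})

test_that("a homopolymer promoter binds far worse than one with a consensus box", {
  cfg <- sim_config(seed = 9, n_genes = 1, transcripts_per_gene = 1,
                    tata_strength = 1)
  with_box <- gen_promoters(cfg)$promoters[[1]]
  poly_g <- promoter("G", "TG", strrep("G", 90))
  expect_gt(estimate_affinity(poly_g)$kd_nM,
            estimate_affinity(with_box)$kd_nM)
})

test_that("calibration recovers known coefficients from noiseless examples", {
  pwm <- default_tata_pwm()
  truth <- model_coefficients(14, 3, 0.2, 0.05, provenance = "truth")
  set.seed(51)
  seqs <- c(vapply(1:6, function(i) random_sequence(90), ""),
            gen_promoters(sim_config(seed = 6, n_genes = 2,
                                     transcripts_per_gene = 1))$promoters |>
              vapply(`[[`, "", "sequence"))
  kd <- vapply(seqs, function(s) {
    estimate_affinity(promoter("G", "T", s), coef = truth)$kd_nM
  }, numeric(1))
  fit <- calibrate_coefficients(data.frame(sequence = seqs, kd_nM = kd), pwm)
  expect_equal(fit$intercept, truth$intercept, tolerance = 1e-6)
  expect_equal(fit$w_slide, truth$w_slide, tolerance = 1e-6)
  expect_equal(fit$w_stop, truth$w_stop, tolerance = 1e-6)
  expect_equal(fit$w_bend, truth$w_bend, tolerance = 1e-6)
})

test_that("underdetermined calibration sets are rejected", {
  ex <- worked_examples()
  expect_error(calibrate_coefficients(ex[1:2, ]), "at least 4")
  same <- data.frame(sequence = rep(ex$sequence[1], 4), kd_nM = 1:4)
  expect_error(calibrate_coefficients(same), "distinct")
})

test_that("calibrated coefficients reproduce the worked-example structure", {
  co <- default_coefficients()
  expect_identical(co$provenance, "calibrated")
  expect_gte(co$w_slide, 0); expect_gte(co$w_stop, 0); expect_gte(co$w_bend, 0)
  ex <- worked_examples()
  pred <- vapply(seq_len(nrow(ex)), function(i) {
    estimate_affinity(promoter(ex$gene[i], ex$transcript[i],
                               ex$sequence[i]))$kd_nM
  }, numeric(1))
  # all within 20% of the published estimates ...
  expect_true(all(abs(pred - ex$kd_nM) / ex$kd_nM < 0.2))
  # ... and every allele effect points the published way
  expect_gt(pred[2], pred[1])  # CRP minor alleles lose affinity
  expect_gt(pred[3], pred[1])
  expect_lt(pred[5], pred[4])  # SERPINF1 minor alleles gain affinity
  expect_lt(pred[6], pred[4])
})
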