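#' Read a pipeline configuration file
#'
#' YAML key-value schema. Recognized keys (all optional unless a stage
#' needs them): `promoters_fasta`, `promoter_metadata`, `snps` (+
#' `snp_dialect`), `annotations`, `degs` (vector of DEG tables),
#' `homology`, `alpha`, `theta0` (whole-genome reference ratio for the
#' neutral-drift test; no default), `bonferroni_m` (defaults to the number
#' of candidate markers in the run), `pwm`, `dinucleotides`, `seed`, and a
#' `simulate` block holding [sim_config()] fields.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

splits_to_df <- function(splits) {
  do.call(rbind, lapply(splits, function(s) {
    data.frame(label = s$label, side_a = s$side_a, k_a = s$k_a,
               side_b = s$side_b, k_b = s$k_b, n = s$n,
               stringsAsFactors = FALSE)
  }))
}

tests_to_df <- function(tests) {
  do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(test = nm, statistic = unname(t$statistic), p_raw = t$p_raw,
               m = t$m, p_adj = t$p_adj, method = t$method,
               stringsAsFactors = FALSE)
  }))
}

#' Run the full promoter-SNP analysis pipeline
#'
#' Mirrors the end-to-end study order: load (or simulate) promoters, SNPs
#' and annotations; screen all (transcript, SNP) pairs for significant
#' TBP-affinity changes; tally directions and per-process health effects;
#' run the directional binomial tests; summarize PAI by Venn region; and
#' test DEG concordance. All outputs are Excel-compatible TSV/JSON flat
#' files plus a manifest with content hashes.
#'
#' @param config list from [read_pipeline_config()] (or built in code).
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- config$alpha %||% 0.05
  pwm <- if (!is.null(config$pwm)) read_pwm(config$pwm) else default_tata_pwm()
  props <- if (!is.null(config$dinucleotides))
    dinucleotide_properties(config$dinucleotides) else dinucleotide_properties()
  coef <- default_coefficients()

  if (!is.null(config$simulate)) {
    sim_dir <- file.path(out_dir, "simulated_inputs")
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed %||% 1L
    cfg <- do.call(sim_config, sim_args)
    write_synthetic_dataset(cfg, sim_dir, pwm)
    config$promoters_fasta <- file.path(sim_dir, "promoters.fasta")
    config$promoter_metadata <- file.path(sim_dir, "promoter_metadata.tsv")
    config$snps <- file.path(sim_dir, "snps.tsv")
    config$annotations <- config$annotations %||%
      file.path(sim_dir, "annotations.tsv")
    config$degs <- config$degs %||% file.path(sim_dir, "degs.tsv")
    config$homology <- config$homology %||% file.path(sim_dir, "homology.tsv")
  }
  for (need in c("promoters_fasta", "promoter_metadata", "snps")) {
    if (is.null(config[[need]])) stop("config key missing: ", need)
    if (!file.exists(config[[need]])) stop("input not found: ", config[[need]])
  }
  if (!is.null(config$annotations) && !file.exists(config$annotations)) {
    stop("input not found: ", config$annotations)
  }

  promoters <- read_promoters(config$promoters_fasta, config$promoter_metadata)
  snps <- read_snps(config$snps, dialect = config$snp_dialect %||% "tsv",
                    promoters = promoters)
  annotations <- if (!is.null(config$annotations))
    read_gene_annotations(config$annotations) else NULL

  markers <- screen(promoters, snps, pwm, coef, props, alpha = alpha,
                    annotations = annotations, keep_all = TRUE)
  m_mult <- config$bonferroni_m %||% max(1L, nrow(markers))
  dirs <- tally_directions(markers)
  health <- tally_health(markers)
  tests <- list()
  if (!is.null(config$theta0)) {
    tests$neutral_drift <- direction_bias_test(dirs, theta0 = config$theta0,
                                               m = m_mult)
  }
  for (pr in names(health)) {
    if (health[[pr]]$n > 0) {
      tests[[paste0("health_", pr)]] <-
        direction_bias_test(health[[pr]], theta0 = 0.5, m = m_mult)
    }
  }

  pai_report <- NULL
  if (!is.null(annotations)) {
    vp <- venn_partition(annotations$gene[annotations$atherogenesis > 0],
                         annotations$gene[annotations$atherosclerosis > 0],
                         annotations$gene[annotations$atheroprotection > 0])
    pai_report <- do.call(rbind, lapply(names(vp), function(r) {
      if (!length(vp[[r]])) return(NULL)
      s <- tryCatch(region_pai_summary(vp[[r]], annotations),
                    error = function(e) NULL)
      if (is.null(s)) return(NULL)
      data.frame(region = r, n_genes = length(vp[[r]]), mean_pai = s$mean,
                 sem_pai = s$sem, n_with_pai = s$n, n_missing = s$n_missing,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(pai_report) && nrow(pai_report) >= 2L) {
      by_region <- lapply(stats::setNames(pai_report$region,
                                          pai_report$region), function(r) {
        pai <- annotations$pai[match(vp[[r]], annotations$gene)]
        pai[!is.na(pai)]
      })
      tests$lowest_bar <- lowest_bar_sign_test(
        by_region, which.min(vapply(by_region, mean, numeric(1))))
    }
  }

  deg_report <- NULL
  if (!is.null(config$degs) && !is.null(config$homology) &&
      !is.null(annotations)) {
    degs <- load_deg_tables(config$degs)
    hom <- read_homology_map(config$homology)
    if (nrow(degs$records)) {
      conc <- concordance_counts(degs$records, hom, annotations)
      deg_report <- splits_to_df(conc)
      for (pr in names(conc)) {
        if (conc[[pr]]$n > 0) {
          tests[[paste0("deg_concordance_", pr)]] <-
            deg_concordance_test(conc[[pr]], m = length(conc))
        }
      }
    }
  }

  files <- character()
  files["markers.tsv"] <- write_tsv(as.data.frame(markers),
                                    file.path(out_dir, "markers.tsv"))
  summ <- list(alpha = alpha, n_comparisons = attr(markers, "n_comparisons"),
               n_markers = nrow(markers),
               n_marker_rsids = length(unique(markers$rsid)),
               per_gene = screen_summary(markers),
               directions = list(per_comparison = unclass(dirs),
                                 per_rsid = unclass(tally_directions(
                                   markers, unit = "rsid"))))
  jsonlite::write_json(summ, file.path(out_dir, "screen_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  files["screen_summary.json"] <- file.path(out_dir, "screen_summary.json")
  if (length(tests)) {
    files["selection_tests.tsv"] <- write_tsv(
      tests_to_df(tests), file.path(out_dir, "selection_tests.tsv"))
  }
  if (!is.null(pai_report)) {
    files["pai_report.tsv"] <- write_tsv(pai_report,
                                         file.path(out_dir, "pai_report.tsv"))
  }
  if (!is.null(deg_report)) {
    files["deg_concordance.tsv"] <- write_tsv(
      deg_report, file.path(out_dir, "deg_concordance.tsv"))
  }
  manifest <- list(
    config = config, alpha = alpha, bonferroni_m = m_mult,
    versions = list(snptata = as.character(utils::packageVersion("snptata")),
                    r = R.version.string),
    inputs = as.list(tools::md5sum(unlist(config[c(
      "promoters_fasta", "promoter_metadata", "snps")]))),
    row_counts = list(promoters = length(promoters), snps = length(snps),
                      comparisons = attr(markers, "n_comparisons"),
                      markers = nrow(markers)),
    warnings = attr(markers, "skipped"),
    outputs = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(markers = markers, directions = dirs, health = health,
                 tests = tests, pai_report = pai_report,
                 deg_report = deg_report, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
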