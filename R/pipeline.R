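#' Default pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one list: the
#' Bonferroni cutoff, the 18-30 h period window, the two promoter windows
#' (-1500..+500 for acetylation signal, -900..+100 for motif sites), the
#' acetylation amplitude cutoff 0.466, the kappa threshold 0.4 and the
#' PWM likelihood-ratio threshold 500, plus the simulation sizes used when
#' the pipeline generates its own synthetic inputs.
#'
#' @param ... overrides for any field.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(alpha = 0.05,
              period_window = c(18, 30),
              promoter_window = c(1500, 500),
              motif_window = c(900, 100),
              acetyl_cutoff = 0.466,
              kappa_threshold = 0.4,
              lr_threshold = 500,
              k_max = 8,
              seed = 1L,
              outdir = NULL,
              n_per_group = 100,
              n_null = 700,
              n_chip_genes = 100,
              n_null_motifs = 50)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

.validate_config <- function(cfg) {
  if (!(cfg$alpha > 0 && cfg$alpha <= 1)) stop("alpha must lie in (0, 1]")
  if (cfg$period_window[1] > cfg$period_window[2])
    stop("period window low bound exceeds high bound")
  for (f in c("acetyl_cutoff", "kappa_threshold", "lr_threshold"))
    if (cfg[[f]] <= 0) stop(f, " must be positive")
  if (is.null(cfg$seed)) stop("config must carry a seed")
  invisible(cfg)
}

.config_hash <- function(cfg) {
  cfg$outdir <- NULL                 # analysis-relevant fields only
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[order(names(cfg))]), f)
  unname(tools::md5sum(f))
}

.write_stage <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epirhythm %s\tconfig_hash=%s\tseed=%s",
                     as.character(utils::packageVersion("epirhythm")),
                     hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates the four-condition benchmark, scans each condition for
#' rhythms, classifies shared/condition-only genes and the A/B/C
#' attribution funnel, compares phase and amplitude between conditions,
#' clusters rhythmic temporal profiles, quantifies synthetic promoter
#' acetylation signal and splits it at the amplitude cutoff, tests motif
#' enrichment in the deacetylase-dependent gene group, and runs gene-set
#' over-representation with a kappa network.  All randomness derives from
#' `config$seed`; rerunning with the same config writes byte-identical
#' tables (each stamped with the config hash).
#'
#' @param config list from [pipeline_config()], or a path to a YAML file
#'   of overrides.
#' @return invisible list with every stage's result; TSVs are written to
#'   `config$outdir` when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config))
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  .validate_config(config)
  hash <- .config_hash(config)
  out <- list(config = config, config_hash = hash)
  emit <- function(df, name) {
    if (!is.null(config$outdir)) {
      if (!dir.exists(config$outdir))
        dir.create(config$outdir, recursive = TRUE)
      .write_stage(df, file.path(config$outdir, paste0(name, ".tsv")),
                   hash, config$seed)
    }
  }

  message("stage simulate: four-condition benchmark")
  sim <- simulate_funnel_benchmark(n_per_group = config$n_per_group,
                                   n_null = config$n_null,
                                   seed = config$seed)
  out$truth <- sim$truth

  message("stage jtk: rhythm scans per condition")
  scans <- lapply(sim$matrices[c("CV", "GF", "KO")], jtk_scan,
                  alpha = config$alpha,
                  period_window = config$period_window)
  scans$WT <- scans$CV
  out$scans <- scans
  for (cond in c("CV", "GF", "KO"))
    emit(scans[[cond]]$results, paste0("rhythm_", cond))

  message("stage compare: pair classification and funnel")
  out$pair <- classify_pair(scans$CV, scans$GF, alpha = config$alpha,
                            name_a = "CV", name_b = "GF")
  emit(out$pair, "pair_CV_GF")
  out$funnel <- funnel_groups(scans$CV, scans$GF, scans$WT, scans$KO,
                              alpha = config$alpha)
  emit(out$funnel, "funnel")
  out$phase_diff <- phase_amp_diff(scans$GF, scans$CV)
  emit(out$phase_diff, "phase_amp_diff_GF_vs_CV")

  message("stage cluster: elbow K-means on CV rhythmic genes")
  rh <- scans$CV$results$gene_id[scans$CV$results$rhythmic]
  cvm <- sim$matrices$CV
  keep <- match(rh, cvm$gene_ids)
  sub <- time_course_matrix(cvm$values[keep, , drop = FALSE], rh, cvm$samples)
  out$clusters <- elbow_kmeans(sub, k_max = config$k_max, seed = config$seed)
  emit(out$clusters$assignments, "clusters")
  emit(data.frame(k = seq_along(out$clusters$wss), wss = out$clusters$wss),
       "wss_curve")

  message("stage chip: promoter acetylation signal")
  models <- simulate_gene_models(config$n_chip_genes, seed = config$seed)
  chip <- simulate_chip(models,
                        rhythmic_genes = models$gene_id[
                          seq_len(config$n_chip_genes %/% 2)],
                        seed = config$seed)
  win <- make_promoter_windows(models, config$promoter_window[1],
                               config$promoter_window[2])
  sig <- count_promoter_signal(chip$reads, win)
  out$promoter <- sig
  out$amp_split <- amp_cutoff_split(sig, cutoff = config$acetyl_cutoff)
  emit(data.frame(gene_id = sig$gene_id, sig$signal,
                  rel_amp = promoter_rel_amp(sig), check.names = FALSE),
       "promoter_signal")

  message("stage motif: enrichment in the planted gene list")
  planted <- models$gene_id[seq_len(config$n_chip_genes %/% 4)]
  msim <- simulate_motifs(models, planted,
                          n_null_motifs = config$n_null_motifs,
                          seed = config$seed)
  mwin <- make_promoter_windows(models, config$motif_window[1],
                                config$motif_window[2])
  hits <- genes_with_motif(msim$sites, mwin)
  out$motif_enrich <- fisher_enrichment(planted, models$gene_id, hits)
  emit(out$motif_enrich, "motif_enrichment")

  message("stage enrich: ORA and kappa network")
  gs <- simulate_gene_sets(sim$truth$gene_id, seed = config$seed)
  listB <- out$funnel$gene_id[out$funnel$funnel_group == "B"]
  # make one block's terms genuinely enriched by seeding its pool with B genes
  spiked <- gs$collection
  spiked$sets <- lapply(spiked$sets, function(s) s)
  take <- min(length(listB), 30)
  for (id in gs$truth$term_id[gs$truth$block == 1])
    spiked$sets[[id]] <- unique(c(utils::head(listB, take),
                                  utils::head(spiked$sets[[id]], 10)))
  out$ora <- ora(listB, sim$truth$gene_id, spiked)
  emit(out$ora, "ora")
  out$network <- kappa_network(out$ora, spiked, sim$truth$gene_id,
                               kappa_threshold = config$kappa_threshold)
  emit(out$network$nodes, "kappa_components")
  emit(out$network$edges, "kappa_edges")

  invisible(out)
}
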