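#' Specification for a synthetic multi-condition circadian experiment
#'
#' The generator plants cosine-shaped 24-h rhythms with known phase and
#' relative amplitude on top of log-normal baseline expression, with
#' condition-specific rhythmic blocks, optional phase shifts between
#' conditions and an arrhythmic background, so every downstream stage can
#' be scored against ground truth.
#'
#' Rhythmic genes follow `y = M (1 + a cos(2 pi (t - phi)/period))` plus
#' noise, with `a` chosen so the noiseless relative amplitude (cosinor
#' amplitude over series maximum) equals the block target:
#' `a = rel_amp / (1 - rel_amp)`.
#'
#' @param n_genes total genes.
#' @param zts timepoints in hours (default 0,3,...,21: 8 per cycle).
#' @param replicates replicates per timepoint (default 2).
#' @param conditions condition labels.
#' @param blocks list of blocks; each a list with `name`, `n`,
#'   `rhythmic_in` (character vector of conditions; empty = arrhythmic),
#'   optional `rel_amp` (scalar or named per condition, default 0.35) and
#'   `phase_shift` (named per condition, hours added to the gene's base
#'   peak phase in that condition).  Unassigned genes form an `arrhythmic`
#'   background block.
#' @param period true period in hours (default 24).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline level
#'   parameters (FPKM-like right-skewed levels).
#' @param noise "lognormal" (multiplicative, default) or "gaussian"
#'   (additive, clipped at 0).
#' @param cv noise coefficient of variation relative to the gene's level
#'   (default 0.2).
#' @param seed mandatory integer seed.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 1000, zts = seq(0, 21, by = 3),
                     replicates = 2, conditions = c("CV", "GF"),
                     blocks = NULL, period = 24,
                     baseline_meanlog = 2, baseline_sdlog = 1,
                     noise = c("lognormal", "gaussian"), cv = 0.2,
                     seed) {
  if (missing(seed)) stop("a seed is mandatory for the generator")
  noise <- match.arg(noise)
  if (is.null(blocks)) {
    blocks <- list(
      list(name = "shared", n = 100, rhythmic_in = conditions),
      list(name = paste0(conditions[1], "only"), n = 50,
           rhythmic_in = conditions[1]),
      list(name = paste0(conditions[2], "only"), n = 50,
           rhythmic_in = conditions[2]))
  }
  used <- sum(vapply(blocks, `[[`, 0, "n"))
  if (used > n_genes) stop("block sizes exceed n_genes")
  for (b in blocks) {
    ra <- if (is.null(b$rel_amp)) 0.35 else b$rel_amp
    if (any(ra <= 0 | ra >= 1)) stop("rel_amp targets must lie in (0, 1)")
  }
  structure(list(n_genes = n_genes, zts = zts, replicates = replicates,
                 conditions = conditions, blocks = blocks, period = period,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, noise = noise, cv = cv,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a multi-condition expression time course with ground truth
#'
#' @param spec a [sim_spec()].
#' @return list with `matrices` (named list of [time_course_matrix()], one
#'   per condition) and `truth` (data.frame: gene_id, block, and per
#'   condition `rhythmic_<cond>`, `lag_<cond>`, `rel_amp_<cond>`).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(ng))
  tps <- rep(spec$zts, times = spec$replicates)
  reps <- rep(seq_len(spec$replicates), each = length(spec$zts))
  ns <- length(tps)

  block_of <- rep("arrhythmic", ng)
  at <- 1L
  for (b in spec$blocks) {
    block_of[at:(at + b$n - 1L)] <- b$name
    at <- at + b$n
  }
  M <- exp(stats::rnorm(ng, spec$baseline_meanlog, spec$baseline_sdlog))
  base_lag <- sample(spec$zts, ng, replace = TRUE)

  truth <- data.frame(gene_id = gene_ids, block = block_of,
                      baseline = M, stringsAsFactors = FALSE)
  sdlog <- sqrt(log(1 + spec$cv^2))
  mats <- list()
  for (cond in spec$conditions) {
    rhyth <- rep(FALSE, ng); ra <- rep(NA_real_, ng); lg <- rep(NA_real_, ng)
    at <- 1L
    for (b in spec$blocks) {
      idx <- at:(at + b$n - 1L); at <- at + b$n
      if (!cond %in% b$rhythmic_in) next
      rel <- if (is.null(b$rel_amp)) 0.35 else b$rel_amp
      if (!is.null(names(rel))) rel <- unname(rel[cond])
      shift <- 0
      if (!is.null(b$phase_shift) && cond %in% names(b$phase_shift))
        shift <- b$phase_shift[[cond]]
      rhyth[idx] <- TRUE
      ra[idx] <- rel
      lg[idx] <- (base_lag[idx] + shift) %% spec$period
    }
    a <- ifelse(rhyth, ra / (1 - ra), 0)
    mu <- M * (1 + outer(a, rep(1, ns)) *
                 cos(2 * pi * (outer(ifelse(rhyth, lg, 0), tps,
                                     function(l, t) t - l)) / spec$period))
    mu[!rhyth, ] <- M[!rhyth]
    if (spec$noise == "lognormal") {
      Y <- mu * exp(matrix(stats::rnorm(ng * ns, 0, sdlog), ng) - sdlog^2 / 2)
    } else {
      Y <- mu + matrix(stats::rnorm(ng * ns, 0, 1), ng) * (spec$cv * M)
      Y[Y < 0] <- 0
    }
    samples <- data.frame(
      sample_id = sprintf("%s_ZT%02d_r%d", cond, tps, reps),
      zt = tps, replicate = reps, condition = cond,
      stringsAsFactors = FALSE)
    mats[[cond]] <- time_course_matrix(Y, gene_ids, samples)
    truth[[paste0("rhythmic_", cond)]] <- rhyth
    truth[[paste0("lag_", cond)]] <- lg
    truth[[paste0("rel_amp_", cond)]] <- ra
  }
  list(matrices = mats, truth = truth)
}

#' Four-condition attribution benchmark with planted funnel groups
#'
#' Plants genes whose rhythmicity is driven by the microbiota only
#' (group A: rhythmic in CV/WT and KO, lost germ-free), by microbiota and
#' the deacetylase (group B: rhythmic in CV/WT only), or by the
#' deacetylase only (group C: rhythmic in CV/WT and GF, lost in KO), plus
#' an arrhythmic background.  The CV matrix doubles as the WT matrix,
#' mirroring the use of one wild-type dataset in both comparisons.
#'
#' @param n_per_group genes per funnel group (default 100).
#' @param n_null arrhythmic background genes (default 700).
#' @param seed integer seed.
#' @param ... further arguments to [sim_spec()] (e.g. `cv`, `replicates`).
#' @return as [simulate_expression()] plus `truth$funnel_group`.
#' @export
simulate_funnel_benchmark <- function(n_per_group = 100, n_null = 700,
                                      seed, ...) {
  blocks <- list(
    list(name = "A", n = n_per_group, rhythmic_in = c("CV", "KO")),
    list(name = "B", n = n_per_group, rhythmic_in = "CV"),
    list(name = "C", n = n_per_group, rhythmic_in = c("CV", "GF")))
  spec <- sim_spec(n_genes = 3 * n_per_group + n_null,
                   conditions = c("CV", "GF", "KO"), blocks = blocks,
                   seed = seed, ...)
  sim <- simulate_expression(spec)
  sim$truth$funnel_group <-
    ifelse(sim$truth$block %in% c("A", "B", "C"), sim$truth$block, "none")
  sim$matrices$WT <- sim$matrices$CV
  sim
}

#' Simulate random gene models on a synthetic chromosome
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length in bp.
#' @param gene_length fixed transcript length.
#' @param seed integer seed.
#' @return gene model data.frame as [gene_models()].
#' @export
simulate_gene_models <- function(n_genes = 100, chrom_length = 10e6,
                                 gene_length = 5000, seed) {
  set.seed(seed)
  # evenly spaced with jitter so promoter windows of neighbouring genes
  # never overlap (keeps per-gene read assignments unambiguous)
  spacing <- (chrom_length - 4000) / n_genes
  if (spacing < gene_length + 4000)
    stop("chromosome too short for non-overlapping gene models")
  start <- 2000 + round(spacing * (seq_len(n_genes) - 1) +
                          stats::runif(n_genes, 0, spacing - gene_length - 4000))
  gene_models(sprintf("gene%05d", seq_len(n_genes)), "chrS",
              sample(c("+", "-"), n_genes, replace = TRUE),
              start, start + gene_length)
}

#' Simulate promoter ChIP-seq read sets with planted acetylation rhythms
#'
#' Reads of length 50 are placed uniformly within each gene's promoter
#' window with per-timepoint Poisson counts whose means follow a cosine for
#' rhythmic-acetylation genes ((max-min)/max equal to `rel_amp_target`) and
#' a constant for the rest; background reads are scattered over the
#' chromosome.
#'
#' @param models gene model data.frame.
#' @param zts timepoints.
#' @param rhythmic_genes gene ids with rhythmic promoter signal.
#' @param mean_count Poisson mean reads per promoter per timepoint at peak.
#' @param rel_amp_target planted (max-min)/max of the Poisson means.
#' @param lag peak timepoint of the acetylation rhythm (scalar or per
#'   rhythmic gene).
#' @param background_reads background reads per timepoint.
#' @param chrom_length chromosome length for background placement.
#' @param seed integer seed.
#' @return list with `reads` (named list of [interval_set()], one per
#'   timepoint) and `truth` (data.frame gene_id, rhythmic, rel_amp, lag).
#' @export
simulate_chip <- function(models, zts = seq(0, 21, by = 3),
                          rhythmic_genes = character(),
                          mean_count = 200, rel_amp_target = 0.7,
                          lag = 8, background_reads = 2000,
                          chrom_length = 10e6, seed) {
  set.seed(seed)
  win <- make_promoter_windows(models)
  nrh <- length(rhythmic_genes)
  lag <- rep(lag, length.out = nrh)
  names(lag) <- rhythmic_genes
  reads <- list()
  for (t in zts) {
    rec <- vector("list", nrow(win) + 1L)
    for (i in seq_len(nrow(win))) {
      g <- win$gene_id[i]
      mu <- if (g %in% rhythmic_genes) {
        mean_count * (1 - rel_amp_target *
                        (1 - cos(2 * pi * (t - lag[[g]]) / 24)) / 2)
      } else mean_count
      cnt <- stats::rpois(1, mu)
      if (cnt > 0) {
        s <- sample(seq(win$start[i], max(win$start[i], win$end[i] - 50)),
                    cnt, replace = TRUE)
        rec[[i]] <- data.frame(chrom = win$chrom[i], start = s, end = s + 50,
                               stringsAsFactors = FALSE)
      }
    }
    nb <- stats::rpois(1, background_reads)
    if (nb > 0) {
      s <- sample.int(chrom_length - 50, nb, replace = TRUE)
      rec[[nrow(win) + 1L]] <- data.frame(chrom = unique(win$chrom)[1],
                                          start = s, end = s + 50,
                                          stringsAsFactors = FALSE)
    }
    reads[[paste0("ZT", t)]] <- interval_set(do.call(rbind, rec))
  }
  truth <- data.frame(gene_id = models$gene_id,
                      rhythmic = models$gene_id %in% rhythmic_genes,
                      rel_amp = ifelse(models$gene_id %in% rhythmic_genes,
                                       rel_amp_target, 0),
                      lag = ifelse(models$gene_id %in% rhythmic_genes,
                                   lag[models$gene_id], NA),
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate motif site maps with one planted enriched motif
#'
#' The planted motif receives a site in the -900..+100 promoter window of
#' each listed gene with probability `rate_in_list` and of each background
#' gene with probability `rate_background`; null motifs get sites at
#' `rate_background` uniformly.
#'
#' @param models gene model data.frame (the universe).
#' @param planted_list gene ids carrying the planted enrichment.
#' @param planted_motif id of the planted motif.
#' @param n_null_motifs number of null motifs.
#' @param rate_in_list,rate_background per-gene site probabilities.
#' @param site_width motif site width in bp.
#' @param seed integer seed.
#' @return list with `sites` ([interval_set()], name = motif id) and
#'   `truth` (planted motif id).
#' @export
simulate_motifs <- function(models, planted_list, planted_motif = "MOTIF_P",
                            n_null_motifs = 99, rate_in_list = 0.8,
                            rate_background = 0.1, site_width = 10, seed) {
  set.seed(seed)
  win <- motif_promoter_windows(models)
  place <- function(rows, motif) {
    if (!length(rows)) return(NULL)
    s <- win$start[rows] +
      floor(stats::runif(length(rows)) * (win$end[rows] - win$start[rows] - site_width))
    data.frame(chrom = win$chrom[rows], start = s, end = s + site_width,
               name = motif, stringsAsFactors = FALSE)
  }
  in_list <- win$gene_id %in% planted_list
  rec <- list()
  hit <- stats::runif(nrow(win)) <
    ifelse(in_list, rate_in_list, rate_background)
  rec[[1]] <- place(which(hit), planted_motif)
  for (m in seq_len(n_null_motifs)) {
    hit <- stats::runif(nrow(win)) < rate_background
    rec[[m + 1]] <- place(which(hit), sprintf("MOTIF_N%03d", m))
  }
  list(sites = interval_set(do.call(rbind, rec)), truth = planted_motif)
}

#' Simulate a gene-set collection with planted block structure
#'
#' Terms inside a block share most of their members (drawn from a common
#' pool); terms in different blocks share only background genes, giving a
#' known kappa-network community structure.
#'
#' @param universe gene id vector.
#' @param n_blocks number of term blocks.
#' @param terms_per_block terms per block.
#' @param set_size genes per term.
#' @param within_overlap fraction of a term drawn from its block pool.
#' @param seed integer seed.
#' @return list with `collection` ([gene_set_collection()]) and `truth`
#'   (data.frame term_id, block).
#' @export
simulate_gene_sets <- function(universe, n_blocks = 2, terms_per_block = 4,
                               set_size = 40, within_overlap = 0.8, seed) {
  set.seed(seed)
  pool_size <- ceiling(set_size / within_overlap)
  pools <- lapply(seq_len(n_blocks), function(i)
    sample(universe, pool_size))
  sets <- list(); truth <- NULL
  for (b in seq_len(n_blocks)) {
    for (j in seq_len(terms_per_block)) {
      id <- sprintf("T%d_%d", b, j)
      n_in <- round(set_size * within_overlap)
      sets[[id]] <- unique(c(sample(pools[[b]], n_in),
                             sample(setdiff(universe, pools[[b]]),
                                    set_size - n_in)))
      truth <- rbind(truth, data.frame(term_id = id, block = b,
                                       stringsAsFactors = FALSE))
    }
  }
  list(collection = gene_set_collection(sets), truth = truth)
}
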