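.scan_results <- function(x) {
  if (inherits(x, "jtk_scan")) x$results else as.data.frame(x)
}

.check_universe <- function(a, b) {
  missing_b <- setdiff(a$gene_id, b$gene_id)
  missing_a <- setdiff(b$gene_id, a$gene_id)
  if (length(missing_a) || length(missing_b))
    stop("gene universes differ; missing ids: ",
         paste(utils::head(c(missing_a, missing_b), 10), collapse = ", "))
}

#' Classify genes as shared or condition-specific rhythmic
#'
#' A gene is `shared` when rhythmic in both conditions at the Bonferroni
#' cutoff, `onlyA`/`onlyB` when rhythmic in exactly one, `neither`
#' otherwise.  With condition names "CV" and "GF" the field labels are
#' `CVonly`, `CVshareGF`, `GFonly`.
#'
#' @param resA,resB rhythm scan results ([jtk_scan()] objects or their
#'   data.frames) over the same gene universe.
#' @param alpha Bonferroni-adjusted significance cutoff (default 0.05).
#' @param name_a,name_b condition names used to build the named labels.
#' @return data.frame: gene_id, class (onlyA/shared/onlyB/neither), label
#'   (named variant), with the class counts as attribute `counts`.
#' @export
classify_pair <- function(resA, resB, alpha = 0.05,
                          name_a = "A", name_b = "B") {
  a <- .scan_results(resA); b <- .scan_results(resB)
  .check_universe(a, b)
  b <- b[match(a$gene_id, b$gene_id), ]
  ra <- a$p_adj <= alpha
  rb <- b$p_adj <= alpha
  cls <- ifelse(ra & rb, "shared",
         ifelse(ra, "onlyA", ifelse(rb, "onlyB", "neither")))
  lab <- c(shared = paste0(name_a, "share", name_b),
           onlyA = paste0(name_a, "only"),
           onlyB = paste0(name_b, "only"), neither = "neither")[cls]
  out <- data.frame(gene_id = a$gene_id, class = cls, label = unname(lab),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(cls, c("onlyA", "shared", "onlyB",
                                             "neither")))
  out
}

#' Two-level attribution funnel for rhythmicity drivers
#'
#' First level: `CVonly` = rhythmic in CV but not GF (microbiota-sensitive);
#' `WTonly` = rhythmic in WT but not KO (deacetylase-sensitive).  Second
#' level: group A = CVonly \ WTonly (microbiota only), B = CVonly
#' intersect WTonly (microbiota and HDAC3), C = WTonly \ CVonly (HDAC3
#' only).  The CV and WT arguments may be the same scan (one wild-type
#' dataset serving both comparisons).
#'
#' @param cv,gf,wt,ko rhythm scan results over a common gene universe.
#' @param alpha Bonferroni-adjusted significance cutoff.
#' @return data.frame: gene_id, cv_only, wt_only (logical), funnel_group
#'   in {A, B, C, none}; counts in attribute `counts`.
#' @export
funnel_groups <- function(cv, gf, wt, ko, alpha = 0.05) {
  cv <- .scan_results(cv); gf <- .scan_results(gf)
  wt <- .scan_results(wt); ko <- .scan_results(ko)
  .check_universe(cv, gf); .check_universe(cv, wt); .check_universe(cv, ko)
  gf <- gf[match(cv$gene_id, gf$gene_id), ]
  wt <- wt[match(cv$gene_id, wt$gene_id), ]
  ko <- ko[match(cv$gene_id, ko$gene_id), ]
  cv_only <- cv$p_adj <= alpha & gf$p_adj > alpha
  wt_only <- wt$p_adj <= alpha & ko$p_adj > alpha
  grp <- ifelse(cv_only & wt_only, "B",
         ifelse(cv_only, "A", ifelse(wt_only, "C", "none")))
  out <- data.frame(gene_id = cv$gene_id, cv_only = cv_only,
                    wt_only = wt_only,
                    funnel_group = factor(grp, c("A", "B", "C", "none")),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$funnel_group)
  out
}

#' Per-gene phase and amplitude differences between two conditions
#'
#' `phase_diff = lag1 - lag2` wrapped into `(-period/2, period/2]` using
#' the mean of the two best periods; `amp_diff = amp1 - amp2`.  Negative
#' phase_diff means the gene peaks earlier (is advanced) in condition 1.
#' Genes lacking a defined lag in either table are excluded with a
#' message.
#'
#' @param res1,res2 rhythm scan results (condition 1 and 2).
#' @return data.frame: gene_id, phase_diff, amp_diff, both_rhythmic.
#' @export
phase_amp_diff <- function(res1, res2) {
  a <- .scan_results(res1); b <- .scan_results(res2)
  common <- intersect(a$gene_id, b$gene_id)
  a <- a[match(common, a$gene_id), ]
  b <- b[match(common, b$gene_id), ]
  ok <- !is.na(a$lag) & !is.na(b$lag)
  if (any(!ok))
    message(sum(!ok), " gene(s) without a defined lag excluded")
  a <- a[ok, ]; b <- b[ok, ]
  per <- (a$period + b$period) / 2
  d <- (a$lag - b$lag) %% per
  wrap <- d > per / 2
  d[wrap] <- d[wrap] - per[wrap]
  data.frame(gene_id = a$gene_id, phase_diff = d,
             amp_diff = a$amp - b$amp,
             both_rhythmic = a$rhythmic & b$rhythmic,
             stringsAsFactors = FALSE)
}

#' Student's t-test on relative amplitudes of two gene groups
#'
#' Classic unpaired equal-variance Student's t-test (two-sided); Welch's
#' unequal-variance variant behind `welch = TRUE`.
#'
#' @param rel_amps_1,rel_amps_2 numeric vectors (>= 2 values each).
#' @param welch use the Welch test instead.
#' @return list with `t` and `p`.
#' @export
amplitude_ttest <- function(rel_amps_1, rel_amps_2, welch = FALSE) {
  x <- rel_amps_1[!is.na(rel_amps_1)]; y <- rel_amps_2[!is.na(rel_amps_2)]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 values per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    warning("degenerate variance in both groups; p set to 1")
    return(list(t = 0, p = 1))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' K-means temporal clustering with elbow selection of K
#'
#' Replicates are averaged per timepoint, each gene's temporal profile is
#' z-scored, and the within-cluster sum of squares WSS(k) is computed for
#' k = 1..k_max with fixed-seed multi-restart K-means.  K is selected as
#' the argmax of the second difference of the WSS curve (the sharpest
#' bend), overridable via `k`.
#'
#' @param tcm a [time_course_matrix()] restricted to the genes to cluster
#'   (typically the rhythmic set), or a genes x timepoints matrix.
#' @param k_max largest K examined (>= 3).
#' @param seed integer seed for the restarts.
#' @param k optional fixed K overriding elbow selection.
#' @param nstart restarts per K.
#' @return object of class `elbow_kmeans`: list with `assignments`
#'   (data.frame gene_id, cluster), `centers` (K x timepoints cluster mean
#'   z-profiles), `wss` (named vector over k), `k`.
#' @export
elbow_kmeans <- function(tcm, k_max = 10, seed, k = NULL, nstart = 10) {
  if (k_max < 3) stop("k_max must be at least 3")
  if (inherits(tcm, "TimeCourseMatrix")) {
    zt <- tcm$samples$zt
    uz <- sort(unique(zt))
    prof <- sapply(uz, function(t) rowMeans(tcm$values[, zt == t, drop = FALSE]))
    colnames(prof) <- paste0("ZT", uz)
    rownames(prof) <- tcm$gene_ids
  } else {
    prof <- as.matrix(tcm)
  }
  if (nrow(prof) < k_max) stop("fewer genes than k_max")
  mu <- rowMeans(prof); s <- apply(prof, 1, stats::sd)
  z <- (prof - mu) / ifelse(s > 0, s, 1)
  set.seed(seed)
  wss <- numeric(k_max)
  fits <- vector("list", k_max)
  for (kk in seq_len(k_max)) {
    fits[[kk]] <- stats::kmeans(z, centers = kk, nstart = nstart,
                                iter.max = 100)
    wss[kk] <- fits[[kk]]$tot.withinss
  }
  names(wss) <- seq_len(k_max)
  if (is.null(k)) {
    # elbow = sharpest relative bend: second difference of log WSS, so a
    # drop from 400 to 100 outweighs an equal absolute drop off a larger base
    lw <- log(pmax(wss, 1e-8 * wss[1]))
    d2 <- lw[1:(k_max - 2)] - 2 * lw[2:(k_max - 1)] + lw[3:k_max]
    k <- unname(which.max(d2)) + 1L   # second difference at k = 2..k_max-1
  }
  fit <- fits[[k]]
  structure(list(assignments = data.frame(gene_id = rownames(z),
                                          cluster = unname(fit$cluster),
                                          stringsAsFactors = FALSE),
                 centers = fit$centers, wss = wss, k = k),
            class = "elbow_kmeans")
}

#' @export
print.elbow_kmeans <- function(x, ...) {
  cat("Elbow K-means: K =", x$k, "selected from WSS curve over k = 1..",
      length(x$wss), "\n")
  print(table(cluster = x$assignments$cluster))
  invisible(x)
}

#' Split genes by mean expression level between genotypes
#'
#' A gene is "upregulated" when its mean abundance across all timepoints
#' and replicates is higher in the knockout than in the wild type, else
#' "downregulated"; exact ties go to "downregulated" with a warning.
#'
#' @param matrix_wt,matrix_ko [time_course_matrix()] objects covering
#'   `gene_list`.
#' @param gene_list gene ids to classify.
#' @return list with `upregulated` and `downregulated` gene id vectors.
#' @export
updown_split <- function(matrix_wt, matrix_ko, gene_list) {
  miss <- setdiff(gene_list, intersect(matrix_wt$gene_ids, matrix_ko$gene_ids))
  if (length(miss))
    stop("gene(s) absent from a matrix: ",
         paste(utils::head(miss, 10), collapse = ", "))
  mw <- rowMeans(matrix_wt$values[match(gene_list, matrix_wt$gene_ids), ,
                                  drop = FALSE])
  mk <- rowMeans(matrix_ko$values[match(gene_list, matrix_ko$gene_ids), ,
                                  drop = FALSE])
  if (any(mk == mw))
    warning(sum(mk == mw), " exact tie(s) classified as downregulated")
  list(upregulated = gene_list[mk > mw],
       downregulated = gene_list[mk <= mw])
}

#' Peak-phase histogram stratified by relative-amplitude rank
#'
#' Counts rhythmic genes in lag bins (one bin per sampling interval)
#' crossed with the five relative-amplitude ranks; the grand total equals
#' the number of rhythmic genes (the data behind a polar phase chart).
#'
#' @param res rhythm scan results; only rhythmic genes are counted.
#' @param interval lag bin width in hours (default 3).
#' @param period phase range (default 24).
#' @return contingency table lag bin x amplitude rank.
#' @export
phase_polar_summary <- function(res, interval = 3, period = 24) {
  r <- .scan_results(res)
  r <- r[r$rhythmic & !is.na(r$lag), ]
  bins <- seq(0, period - interval, by = interval)
  lag_bin <- factor(bins[findInterval(r$lag %% period, bins)], levels = bins)
  table(lag = lag_bin, rank = rank_rel_amp(r$rel_amp))
}
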