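#' Build the cosine reference-waveform grid
#'
#' One reference waveform per (period, lag) pair over the configured
#' period window.  The cosine is evaluated at each sample's zeitgeber time
#' and converted to dense integer ranks (ties allowed); waveforms with an
#' identical rank pattern are collapsed to one so that the Bonferroni
#' factor counts only rank-distinct references.
#'
#' @param zts numeric vector of sample zeitgeber times (hours).
#' @param period_window length-2 numeric, low and high period bound in
#'   hours (default 18-30).
#' @param period_step,lag_step grid steps in hours; default is the
#'   sampling interval (smallest gap between distinct timepoints).
#' @return An object of class `jtk_grid`: list with `refs` (list of
#'   waveforms, each `list(period, lag, ranks)`), `n_distinct`, `zts`,
#'   `interval`.
#' @export
build_reference_grid <- function(zts, period_window = c(18, 30),
                                 period_step = NULL, lag_step = NULL) {
  uz <- sort(unique(zts))
  if (length(uz) < 3)
    stop("need at least 3 distinct timepoints to build a reference grid")
  if (length(period_window) != 2 || period_window[1] > period_window[2])
    stop("period window low bound must not exceed high bound")
  interval <- min(diff(uz))
  if (is.null(period_step)) period_step <- interval
  if (is.null(lag_step)) lag_step <- interval
  if (period_step <= 0 || lag_step <= 0)
    stop("grid steps must be positive")
  periods <- seq(period_window[1], period_window[2], by = period_step)
  if (!length(periods)) stop("empty period grid")
  refs <- list()
  seen <- character()
  for (per in periods) {
    lags <- seq(0, per - 1e-9, by = lag_step)
    for (lag in lags) {
      v <- round(cos(2 * pi * (zts - lag) / per), 9)
      ranks <- match(v, sort(unique(v)))
      if (length(unique(ranks)) < 2) next  # flat reference carries no order
      key <- paste(ranks, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      refs[[length(refs) + 1L]] <- list(period = per, lag = lag, ranks = ranks)
    }
  }
  if (!length(refs)) stop("empty reference grid")
  structure(list(refs = refs, n_distinct = length(refs), zts = zts,
                 interval = interval),
            class = "jtk_grid")
}

#' @export
print.jtk_grid <- function(x, ...) {
  pers <- unique(vapply(x$refs, `[[`, 0, "period"))
  cat("jtk_grid:", x$n_distinct, "rank-distinct reference waveforms,",
      "periods", paste(pers, collapse = "/"), "h\n")
  invisible(x)
}

# Coefficients of the Gaussian binomial C(m+n, n)_q: the generating
# polynomial (in q) of the number of cross-group inversions created when a
# block of n tied items is interleaved with m previously placed items.
# Product formula prod_k (1 - q^(m+k)) / (1 - q^k); division is exact.
.qbinom_poly <- function(m, n) {
  poly <- 1
  for (k in seq_len(n)) {           # numerator factors (1 - q^(m+k))
    f <- c(1, rep(0, m + k - 1), -1)
    poly <- .polymul(poly, f)
  }
  for (k in seq_len(n)) {           # exact division by (1 - q^k)
    out <- numeric(length(poly) - k)
    for (i in seq_along(out)) {
      out[i] <- poly[i] + if (i > k) out[i - k] else 0
    }
    poly <- out
  }
  poly
}

.polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    if (a[i] != 0) {
      idx <- i + seq_along(b) - 1
      out[idx] <- out[idx] + a[i] * b
    }
  }
  out
}

#' Exact null distribution of the Jonckheere-Terpstra / Kendall S statistic
#'
#' For a reference waveform with tie groups of sizes n_1..n_g the number of
#' orderings with a given count of cross-group inversions is the
#' q-multinomial coefficient; the pmf over S = M - 2 x inversions (M the
#' number of reference-untied pairs) follows by convolution over groups
#' (Harding-style dynamic programming).  The distribution is symmetric
#' about 0 and sums to 1.
#'
#' @param reference a waveform from [build_reference_grid()], or an integer
#'   rank vector with ties.
#' @param n_samples optional check on the number of samples.
#' @return list with `S` (support, increasing), `pmf`, and `M` (maximal
#'   |S|).
#' @export
exact_jt_null <- function(reference, n_samples = NULL) {
  ranks <- if (is.list(reference)) reference$ranks else reference
  if (!is.null(n_samples) && length(ranks) != n_samples)
    stop("n_samples does not match the reference rank vector")
  sizes <- as.vector(table(ranks))
  if (length(sizes) < 2)
    stop("all reference ranks tied: statistic undefined")
  N <- sum(sizes)
  M <- (N^2 - sum(sizes^2)) / 2
  counts <- 1
  placed <- 0
  for (n_i in sizes) {
    counts <- .polymul(counts, .qbinom_poly(placed, n_i))
    placed <- placed + n_i
  }
  pmf <- counts / sum(counts)
  list(S = M - 2 * (seq_along(pmf) - 1), pmf = pmf, M = M)
}

# Two-sided tail lookup: tail[a + 1] = P(|S| >= a), a = 0..M.
.jt_tail <- function(null) {
  absS <- abs(null$S)
  tail <- numeric(null$M + 1)
  for (a in 0:null$M) tail[a + 1] <- sum(null$pmf[absS >= a])
  tail
}

#' Cosinor amplitude at a fixed period and phase
#'
#' Least-squares fit of `y = b0 + b1 cos(2 pi (t - lag)/period)`; the
#' amplitude is the cosine coefficient floored at zero (half the
#' peak-to-trough excursion).  The relative amplitude divides by the series
#' maximum.
#'
#' @param series numeric abundances.
#' @param zts matching zeitgeber times.
#' @param period,lag hours, typically the scan's best reference.
#' @return list with `amp`, `max_expr`, `rel_amp`.
#' @export
estimate_amplitude <- function(series, zts, period, lag) {
  max_expr <- max(series)
  x <- cos(2 * pi * (zts - lag) / period)
  xc <- x - mean(x)
  den <- sum(xc^2)
  b1 <- if (den > 0) sum(xc * (series - mean(series))) / den else 0
  amp <- max(b1, 0)
  rel_amp <- if (max_expr > 0) min(amp / max_expr, 1) else 0
  list(amp = amp, max_expr = max_expr, rel_amp = rel_amp)
}

#' Nonparametric circadian rhythm scan
#'
#' For every gene, Kendall's S is computed against each rank-distinct
#' cosine reference waveform; the two-sided tail probability comes from the
#' exact combinatorial null ([exact_jt_null()]).  The per-gene p-value is
#' the minimum over references multiplied by the number of rank-distinct
#' references (Bonferroni, capped at 1); Benjamini-Hochberg q-values are
#' computed across genes.  The best (period, lag) is the argmin reference,
#' ties broken by smaller period then smaller lag; amplitude is the cosinor
#' fit at that reference.
#'
#' @param tcm a [time_course_matrix()] (one condition).
#' @param grid a [build_reference_grid()] object, or NULL to build one from
#'   the sample times with the default 18-30 h window.
#' @param alpha Bonferroni-adjusted significance cutoff (default 0.05).
#' @param period_window used when `grid` is NULL.
#' @return Object of class `jtk_scan`: list with `results` (data.frame:
#'   gene_id, p_adj, q, period, lag, tau, amp, max_expr, rel_amp,
#'   rhythmic), `grid`, `alpha`, `n_samples`.  Genes with no ordering
#'   information (constant series) get p_adj 1 and NA period/lag/tau.
#' @export
jtk_scan <- function(tcm, grid = NULL, alpha = 0.05,
                     period_window = c(18, 30)) {
  stopifnot(inherits(tcm, "TimeCourseMatrix"))
  zts <- tcm$samples$zt
  if (is.null(grid)) grid <- build_reference_grid(zts, period_window)
  stopifnot(inherits(grid, "jtk_grid"))
  X <- tcm$values
  n <- ncol(X)
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  Dsign <- sign(X[, jj, drop = FALSE] - X[, ii, drop = FALSE])

  nref <- length(grid$refs)
  Rsign <- matrix(0, nref, length(ii))
  Mvec <- numeric(nref)
  tails <- vector("list", nref)
  null_cache <- new.env(parent = emptyenv())
  for (k in seq_len(nref)) {
    r <- grid$refs[[k]]$ranks
    Rsign[k, ] <- sign(r[jj] - r[ii])
    key <- paste(sort(as.vector(table(r))), collapse = ",")
    if (is.null(null_cache[[key]])) {
      nl <- exact_jt_null(r)
      null_cache[[key]] <- list(M = nl$M, tail = .jt_tail(nl))
    }
    Mvec[k] <- null_cache[[key]]$M
    tails[[k]] <- null_cache[[key]]$tail
  }

  S <- Dsign %*% t(Rsign)                      # genes x refs
  P <- matrix(1, nrow(S), ncol(S))
  for (k in seq_len(nref))
    P[, k] <- tails[[k]][pmin(abs(S[, k]), Mvec[k]) + 1]

  best <- max.col(-P, ties.method = "first")   # refs ordered (period, lag)
  pmin_raw <- P[cbind(seq_len(nrow(P)), best)]
  p_adj <- pmin(1, pmin_raw * grid$n_distinct)

  period <- vapply(grid$refs, `[[`, 0, "period")[best]
  lag <- vapply(grid$refs, `[[`, 0, "lag")[best]
  tau <- S[cbind(seq_len(nrow(S)), best)] / Mvec[best]
  # two-sided test: an anti-correlated reference is the same evidence as the
  # half-period-shifted one, so report the peak phase on the positive side
  neg <- tau < 0
  lag[neg] <- (lag[neg] + period[neg] / 2) %% period[neg]
  tau[neg] <- -tau[neg]

  amp <- max_expr <- rel_amp <- numeric(nrow(X))
  combo <- paste(period, lag)
  for (key in unique(combo)) {
    g <- which(combo == key)
    x <- cos(2 * pi * (zts - lag[g[1]]) / period[g[1]])
    xc <- x - mean(x)
    den <- sum(xc^2)
    Y <- X[g, , drop = FALSE]
    b1 <- as.vector((Y - rowMeans(Y)) %*% xc) / den
    amp[g] <- pmax(b1, 0)
    max_expr[g] <- apply(Y, 1, max)
    rel_amp[g] <- ifelse(max_expr[g] > 0, pmin(amp[g] / max_expr[g], 1), 0)
  }

  flat <- rowSums(Dsign != 0) == 0             # no ordering information
  p_adj[flat] <- 1
  q <- stats::p.adjust(p_adj, method = "BH")
  period[flat] <- NA_real_; lag[flat] <- NA_real_; tau[flat] <- NA_real_
  amp[flat] <- NA_real_; rel_amp[flat] <- NA_real_

  res <- data.frame(gene_id = tcm$gene_ids, p_adj = p_adj, q = q,
                    period = period, lag = lag, tau = tau, amp = amp,
                    max_expr = max_expr, rel_amp = rel_amp,
                    rhythmic = p_adj <= alpha & !flat,
                    stringsAsFactors = FALSE)
  structure(list(results = res, grid = grid, alpha = alpha,
                 n_samples = n, condition = unique(tcm$samples$condition)),
            class = "jtk_scan")
}

#' @export
print.jtk_scan <- function(x, ...) {
  cat("Circadian rhythm scan (exact Jonckheere-Terpstra/Kendall null)\n")
  cat("  ", nrow(x$results), " genes, ", x$n_samples, " samples, ",
      x$grid$n_distinct, " reference waveforms\n", sep = "")
  cat("  rhythmic at Bonferroni p <= ", x$alpha, ": ",
      sum(x$results$rhythmic), " genes\n", sep = "")
  invisible(x)
}

#' @export
summary.jtk_scan <- function(object, ...) {
  r <- object$results
  rh <- r[r$rhythmic, ]
  out <- list(n_genes = nrow(r), n_rhythmic = nrow(rh), alpha = object$alpha,
              period_table = table(rh$period),
              rel_amp_ranks = if (nrow(rh)) table(rank_rel_amp(rh$rel_amp))
                              else table(factor(character())))
  class(out) <- "summary.jtk_scan"
  out
}

#' @export
print.summary.jtk_scan <- function(x, ...) {
  cat(x$n_rhythmic, "of", x$n_genes, "genes rhythmic at Bonferroni p <=",
      x$alpha, "\n")
  if (x$n_rhythmic) {
    cat("best periods (h):\n"); print(x$period_table)
    cat("relative-amplitude ranks:\n"); print(x$rel_amp_ranks)
  }
  invisible(x)
}

#' @export
as.data.frame.jtk_scan <- function(x, ...) x$results

#' @export
plot.jtk_scan <- function(x, ...) {
  rh <- x$results[x$results$rhythmic & !is.na(x$results$lag), ]
  if (!nrow(rh)) {
    graphics::plot.new(); graphics::title("no rhythmic genes"); return(invisible(x))
  }
  graphics::hist(rh$lag, breaks = seq(0, 24, by = x$grid$interval),
                 main = "Peak phase of rhythmic genes",
                 xlab = "lag (ZT, h)", col = "grey70", ...)
  invisible(x)
}

#' Bin relative amplitudes into the five standard ranks
#'
#' Ranks `<0.1`, `0.1-0.15`, `0.15-0.2`, `0.2-0.25`, `>0.25`; boundary
#' values fall in the lower-open/upper-closed bin (0.15 -> "0.1-0.15").
#'
#' @param rel_amp numeric vector in [0, 1] (NA passed through).
#' @return factor with the five rank labels.
#' @export
rank_rel_amp <- function(rel_amp) {
  ok <- !is.na(rel_amp)
  if (any(rel_amp[ok] < 0 | rel_amp[ok] > 1))
    stop("relative amplitude outside [0, 1]")
  cut(rel_amp, breaks = c(0, 0.1, 0.15, 0.2, 0.25, 1),
      labels = c("<0.1", "0.1-0.15", "0.15-0.2", "0.2-0.25", ">0.25"),
      include.lowest = TRUE, right = TRUE)
}

#' Write a rhythm scan result as TSV
#' @param scan a `jtk_scan` object or its results data.frame.
#' @param path output path.
#' @export
write_rhythm_table <- function(scan, path) {
  res <- if (inherits(scan, "jtk_scan")) scan$results else scan
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rhythm scan result TSV
#' @param path TSV written by [write_rhythm_table()].
#' @return results data.frame.
#' @export
read_rhythm_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
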