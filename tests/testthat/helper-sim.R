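# shared fixtures and independent oracles, built in code at test time

default_samples <- function(zts = rep(seq(0, 21, by = 3), 2),
                            replicates = rep(1:2, each = 8),
                            condition = "CV") {
  data.frame(sample_id = paste0("s", seq_along(zts)), zt = zts,
             replicate = replicates, condition = condition,
             stringsAsFactors = FALSE)
}

make_tcm <- function(values, gene_ids = paste0("g", seq_len(nrow(values))),
                     samples = default_samples()) {
  time_course_matrix(values, gene_ids, samples)
}

# noisy multiplicative-cosine cohort with known lags
sim_cosine_matrix <- function(n_genes, rel_amp, cv, lags = NULL,
                              zts = rep(seq(0, 21, by = 3), 2), seed) {
  set.seed(seed)
  a <- rel_amp / (1 - rel_amp)
  M <- exp(rnorm(n_genes, 2, 1))
  if (is.null(lags)) lags <- sample(seq(0, 21, by = 3), n_genes, TRUE)
  mu <- M * (1 + a * cos(2 * pi * outer(lags, zts, function(l, t) t - l) / 24))
  sdlog <- sqrt(log(1 + cv^2))
  Y <- mu * exp(matrix(rnorm(n_genes * length(zts), 0, sdlog), n_genes) -
                  sdlog^2 / 2)
  list(Y = Y, lags = lags, M = M)
}

circ_dist <- function(a, b, period = 24) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

# all permutations of a vector (oracle-sized inputs only)
all_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- all_perms(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

# Kendall S between data vector x and reference ranks r (pairwise signs)
kendall_S <- function(x, r) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      s <- s + sign(x[j] - x[i]) * sign(r[j] - r[i])
  s
}

# empirical null pmf of S over all n! orderings (full-permutation oracle)
perm_null_pmf <- function(r) {
  P <- all_perms(seq_along(r))
  S <- apply(P, 1, kendall_S, r = r)
  tab <- table(S)
  list(S = as.numeric(names(tab)), pmf = as.vector(tab) / nrow(P))
}

# total variation distance between two pmfs given as (support, mass)
tvd <- function(a, b) {
  sup <- sort(union(a$S, b$S))
  pa <- ifelse(sup %in% a$S, a$pmf[match(sup, a$S)], 0)
  pb <- ifelse(sup %in% b$S, b$pmf[match(sup, b$S)], 0)
  sum(abs(pa - pb)) / 2
}

# brute-force all-pairs interval overlap counts (quadratic oracle)
brute_overlap_counts <- function(windows, records) {
  vapply(seq_len(nrow(windows)), function(i) {
    sum(records$chrom == windows$chrom[i] &
          records$start < windows$end[i] &
          records$end > windows$start[i])
  }, 0L)
}

# two-sided Fisher p by direct hypergeometric enumeration: sum the
# probabilities of all tables (same margins) no more likely than observed
fisher_p_oracle <- function(x1, n_list, z1, N) {
  lo <- max(0, z1 - (N - n_list))
  hi <- min(z1, n_list)
  ks <- lo:hi
  pr <- exp(lchoose(z1, ks) + lchoose(N - z1, n_list - ks) -
              lchoose(N, n_list))
  sum(pr[pr <= pr[ks == x1] * (1 + 1e-7)])
}
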