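test_that("motif-to-promoter mapping uses the any-overlap rule", {
  gm <- gene_models(c("g1", "g2"), "chr1", c("+", "+"),
                    c(2000, 3000), c(4000, 5000))
  w <- motif_promoter_windows(gm)   # [1100,2100) and [2100,3100)
  sites <- interval_set(data.frame(chrom = "chr1",
                                   start = c(1500, 2090), end = c(1510, 2110),
                                   name = c("M1", "M2")))
  hits <- genes_with_motif(sites, w)
  expect_equal(hits$M1, "g1")
  expect_equal(sort(hits$M2), c("g1", "g2"))  # spans both windows

  unnamed <- interval_set(data.frame(chrom = "chr1", start = 1, end = 10))
  expect_error(genes_with_motif(unnamed, w), "name field")
})

test_that("motif mapping equals the brute-force scan on random fixtures", {
  gm <- simulate_gene_models(40, chrom_length = 5e5, seed = 33)
  w <- motif_promoter_windows(gm)
  set.seed(33)
  start <- sample.int(5e5 - 20, 1500)
  sites <- interval_set(data.frame(chrom = "chrS", start = start,
                                   end = start + 10,
                                   name = sample(c("MA", "MB"), 1500, TRUE)))
  hits <- genes_with_motif(sites, w)
  for (m in c("MA", "MB")) {
    rec <- sites$records[sites$records$name == m, ]
    expected <- w$gene_id[brute_overlap_counts(w, rec) > 0]
    expect_equal(sort(hits[[m]]), sort(expected))
  }
})

test_that("fisher enrichment reports the four counts and exact p-values", {
  universe <- paste0("g", 1:100)
  glist <- universe[1:10]
  motif <- c(universe[1:8], universe[11:20])  # 8/10 in list, 10/90 outside
  tab <- fisher_enrichment(glist, universe, list(M = motif))
  expect_equal(tab$x1, 8)
  expect_equal(tab$x2, 2)
  expect_equal(tab$z1, 18)
  expect_equal(tab$z2, 82)
  expect_equal(tab$p, fisher_p_oracle(8, 10, 18, 100), tolerance = 1e-12)
  # marginal identities
  expect_equal(tab$x1 + tab$x2, 10)
  expect_equal(tab$z1 + tab$z2, 100)

  # motif hitting the whole universe is uninformative
  all_tab <- fisher_enrichment(glist, universe, list(M = universe))
  expect_equal(all_tab$p, 1)
  expect_error(fisher_enrichment(character(), universe, list(M = motif)),
               "empty")
  expect_error(fisher_enrichment("zz", universe, list(M = motif)), "subset")
})

test_that("fisher p equals the hypergeometric tail oracle across tables", {
  set.seed(61)
  for (rep in 1:40) {
    N <- sample(10:200, 1)
    n <- sample.int(N - 1, 1)
    z1 <- sample.int(N - 1, 1)
    x1 <- sample(max(0, z1 - (N - n)):min(z1, n), 1)
    universe <- paste0("u", seq_len(N))
    glist <- universe[seq_len(n)]
    motif <- c(universe[seq_len(x1)],
               if (z1 > x1) universe[n + seq_len(z1 - x1)])
    tab <- fisher_enrichment(glist, universe, list(M = motif))
    expect_equal(tab$p, fisher_p_oracle(x1, n, z1, N), tolerance = 1e-10)
  }
})

test_that("BH ordering of fdr matches the ordering of p", {
  set.seed(5)
  universe <- paste0("g", 1:300)
  sets <- lapply(1:30, function(i) sample(universe, 40))
  names(sets) <- paste0("M", 1:30)
  tab <- fisher_enrichment(sample(universe, 40), universe, sets)
  expect_equal(order(tab$p), order(tab$fdr))
  expect_true(all(tab$fdr >= tab$p))
})

test_that("a planted enriched motif dominates the null motifs", {
  gm <- simulate_gene_models(300, chrom_length = 3e6, seed = 70)
  planted <- gm$gene_id[1:30]
  msim <- simulate_motifs(gm, planted, n_null_motifs = 30, seed = 70)
  hits <- genes_with_motif(msim$sites, motif_promoter_windows(gm))
  tab <- fisher_enrichment(planted, gm$gene_id, hits)
  expect_equal(tab$motif_id[1], "MOTIF_P")
  expect_lt(tab$fdr[1], 0.05)
})

test_that("uniquely enriched motifs are split by the FDR threshold", {
  e1 <- data.frame(motif_id = c("A", "B", "C"), fdr = c(0.01, 0.2, 0.01))
  e2 <- data.frame(motif_id = c("A", "B", "C"), fdr = c(0.3, 0.01, 0.01))
  u <- uniquely_enriched(e1, e2)
  expect_equal(u$only1, "A")
  expect_equal(u$only2, "B")
})

test_that("PWM scanning thresholds the likelihood ratio on both strands", {
  consensus <- function(bases, p = 0.997) {
    m <- matrix((1 - p) / 3, length(bases), 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    m[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <- p
    m
  }
  pw <- pwm("CONS", consensus(c("A", "A", "C", "C", "G")))
  # exact match: LR ~ (0.997/0.25)^5 ~ 1009 > 500
  hit <- pwm_scan(c(s1 = "TTAACCGTT"), pw)
  expect_equal(hit$total_count, 1)
  expect_equal(hit$records$start, 2)
  expect_equal(hit$records$end, 7)
  expect_equal(hit$records$strand, "+")
  expect_gt(exp(hit$records$score), 500)

  # one mismatched near-zero base kills the site
  miss <- pwm_scan(c(s1 = "TTAACCCTT"), pw)
  expect_equal(miss$total_count, 0)

  # reverse complement of the match is found on '-' at mirrored coordinates
  rc <- pwm_scan(c(s1 = "AACGGTTAA"), pw)   # revcomp of TTAACCGTT
  expect_equal(rc$records$strand, "-")
  expect_equal(rc$records$start, 2)

  # N bases force LR to zero at overlapping placements
  expect_equal(pwm_scan(c(s1 = "TTAACCNTT"), pw)$total_count, 0)
  # sequence shorter than the motif yields no sites, no error
  expect_equal(pwm_scan(c(s1 = "ACG"), pw)$total_count, 0)
})

test_that("scanning a sequence and its reverse complement mirrors sites", {
  set.seed(77)
  m <- matrix(rgamma(5 * 4, 1), 5, 4)
  m <- m / rowSums(m)
  pw <- pwm("R", m)
  seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  rcseq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  fwd <- pwm_scan(stats::setNames(seq, "s"), pw, lr_threshold = 5)
  rev <- pwm_scan(stats::setNames(rcseq, "s"), pw, lr_threshold = 5)
  L <- nchar(seq); w <- 5
  mirrored <- sort(L - rev$records$end)
  expect_equal(sort(fwd$records$start), mirrored)
  expect_equal(fwd$total_count, rev$total_count)
})

test_that("MEME minimal files parse into valid PWMs", {
  f <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               "A 0.30 C 0.20 G 0.20 T 0.30", "",
               "MOTIF MX test",
               "letter-probability matrix: alength= 4 w= 3 nsites= 20",
               " 0.9 0.1 0.0 0.0", " 0.0 0.0 1.0 0.0", " 0.25 0.25 0.25 0.25"),
             f)
  pwms <- read_meme(f)
  expect_equal(names(pwms), "MX")
  expect_equal(nrow(pwms$MX$matrix), 3)
  expect_equal(rowSums(pwms$MX$matrix), rep(1, 3), tolerance = 1e-9)
  expect_true(all(pwms$MX$matrix > 0))   # pseudocount applied
  expect_equal(pwms$MX$background, c(0.3, 0.2, 0.2, 0.3))
})
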