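test_that("promoter windows are strand-oriented and clipped at zero", {
  gm <- gene_models(c("g1", "g2"), "chr1", c("+", "-"),
                    c(10000, 8000), c(12000, 10000))
  w <- make_promoter_windows(gm)
  expect_equal(w$start[1], 8500)   # '+': [tss-1500, tss+500)
  expect_equal(w$end[1], 10500)
  expect_equal(w$start[2], 9500)   # '-': [tss-500, tss+1500)
  expect_equal(w$end[2], 11500)
  expect_true(all(w$end - w$start == 2000))

  gmc <- gene_models("g3", "chr1", "+", 1000, 3000)
  expect_warning(wc <- make_promoter_windows(gmc), "clipped")
  expect_equal(c(wc$start, wc$end), c(0, 1500))

  m <- motif_promoter_windows(gene_models(c("a", "b"), "chr1", c("+", "-"),
                                          c(5000, 3000), c(9000, 5000)))
  expect_equal(c(m$start[1], m$end[1]), c(4100, 5100))
  expect_equal(c(m$start[2], m$end[2]), c(4900, 5900))
})

test_that("promoter counting is per-million normalized and half-open", {
  gm <- gene_models("g1", "chr1", "+", 1650, 5000)  # window [150, 2150)
  w <- make_promoter_windows(gm)
  inwin <- data.frame(chrom = "chr1", start = c(200, 300, 400),
                      end = c(250, 350, 450))
  filler <- data.frame(chrom = "chr1", start = 5000 + seq_len(997) * 10,
                       end = 5000 + seq_len(997) * 10 + 50)
  reads <- interval_set(rbind(inwin, filler))  # 1000 reads total
  sig <- count_promoter_signal(list(ZT0 = reads), w)
  expect_equal(unname(sig$raw[1, 1]), 3)
  expect_equal(unname(sig$signal[1, 1]), 3000)  # 3 / 1000 * 1e6

  # read ending exactly at window start does not overlap (half-open)
  touch <- interval_set(data.frame(chrom = "chr1", start = 100, end = 150))
  expect_equal(unname(count_promoter_signal(list(ZT0 = touch), w)$raw[1, 1]), 0)
  inside <- interval_set(data.frame(chrom = "chr1", start = 100, end = 151))
  expect_equal(unname(count_promoter_signal(list(ZT0 = inside), w)$raw[1, 1]), 1)

  empty <- interval_set(data.frame())
  expect_error(count_promoter_signal(list(ZT0 = empty), w), "zero total")
})

test_that("overlap counts equal the brute-force all-pairs scan", {
  set.seed(90)
  gm <- simulate_gene_models(50, chrom_length = 1e6, seed = 90)
  w <- make_promoter_windows(gm)
  start <- sample.int(1e6 - 100, 2000)
  reads <- interval_set(data.frame(chrom = "chrS", start = start,
                                   end = start + sample.int(100, 2000,
                                                            replace = TRUE)))
  sig <- count_promoter_signal(list(ZT0 = reads), w)
  expect_equal(unname(sig$raw[, 1]), brute_overlap_counts(w, reads$records))
})

test_that("relative amplitude follows (max - min)/max with degenerate rules", {
  expect_equal(promoter_rel_amp(c(4, 1, 2, 3)), 0.75)
  expect_equal(promoter_rel_amp(rep(5, 6)), 0)
  expect_equal(promoter_rel_amp(rep(0, 6)), 0)
  expect_error(promoter_rel_amp(3), "2 timepoints")
  # scale invariance
  set.seed(1)
  tr <- runif(8, 1, 10)
  expect_equal(promoter_rel_amp(tr * 17), promoter_rel_amp(tr))
  # matrix form is rowwise
  m <- rbind(a = c(4, 1, 2, 3), b = rep(2, 4))
  expect_equal(unname(promoter_rel_amp(m)), c(0.75, 0))
})

test_that("normalized signal is invariant under read-set duplication", {
  gm <- simulate_gene_models(10, chrom_length = 1e5, seed = 7)
  w <- make_promoter_windows(gm)
  set.seed(7)
  start <- sample.int(1e5 - 60, 500)
  rec <- data.frame(chrom = "chrS", start = start, end = start + 50)
  one <- count_promoter_signal(list(ZT0 = interval_set(rec)), w)
  two <- count_promoter_signal(list(ZT0 = interval_set(rbind(rec, rec))), w)
  expect_equal(two$raw, 2 * one$raw)
  expect_equal(two$signal, one$signal)
})

test_that("amplitude cutoff splits at the boundary into the low class", {
  ra <- c(g1 = 0.75, g2 = 0.466, g3 = 0.2)
  sp <- amp_cutoff_split(ra)
  expect_equal(sp$high, "g1")
  expect_equal(sort(sp$low), c("g2", "g3"))
  # planted bimodal mixture separates cleanly
  set.seed(14)
  mix <- c(pmin(pmax(rnorm(250, 0.2, 0.07), 0), 1),
           pmin(pmax(rnorm(250, 0.7, 0.07), 0), 1))
  names(mix) <- paste0("g", 1:500)
  sp2 <- amp_cutoff_split(mix)
  wrong <- sum(names(mix)[1:250] %in% sp2$high) +
    sum(names(mix)[251:500] %in% sp2$low)
  expect_lt(wrong / 500, 0.05)
})

test_that("simulated acetylation rhythms yield the planted amplitude", {
  gm <- simulate_gene_models(30, chrom_length = 1e6, seed = 55)
  # spread the acetylation peak phases so library totals stay level across
  # timepoints (per-million scaling then cancels as intended)
  chip <- simulate_chip(gm, rhythmic_genes = gm$gene_id[1:15],
                        mean_count = 300, rel_amp_target = 0.7,
                        lag = rep(seq(0, 21, by = 3), length.out = 15),
                        background_reads = 500, seed = 55)
  w <- make_promoter_windows(gm)
  sig <- count_promoter_signal(chip$reads, w)
  ra <- promoter_rel_amp(sig)
  expect_lt(abs(median(ra[1:15]) - 0.7), 0.1) # rhythmic block near target
  expect_lt(max(abs(ra[1:15] - 0.7)), 0.2)
  expect_lt(max(ra[16:30]), 0.35)             # flat block only Poisson noise
})
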