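# minimal rhythm-result stand-ins for set-logic tests
fake_res <- function(ids, p) {
  data.frame(gene_id = ids, p_adj = p, q = p, period = 24, lag = 0, tau = 1,
             amp = 1, max_expr = 2, rel_amp = 0.5, rhythmic = p <= 0.05,
             stringsAsFactors = FALSE)
}

test_that("pair classification follows the shared/only definitions", {
  a <- fake_res(c("g1", "g2", "g3"), c(0.01, 0.2, 0.01))
  b <- fake_res(c("g1", "g2", "g3"), c(0.2, 0.01, 0.01))
  cl <- classify_pair(a, b, name_a = "CV", name_b = "GF")
  expect_equal(cl$class, c("onlyA", "onlyB", "shared"))
  expect_equal(cl$label, c("CVonly", "GFonly", "CVshareGF"))

  # identical tables: shared = rhythmic set, no onlys
  cl2 <- classify_pair(a, a)
  expect_equal(sum(cl2$class == "shared"), 2)
  expect_false(any(cl2$class %in% c("onlyA", "onlyB")))

  # symmetry under swapping inputs
  cl3 <- classify_pair(b, a)
  expect_equal(cl3$class == "shared", cl$class == "shared")
  expect_equal(cl3$class == "onlyA", cl$class == "onlyB")

  expect_error(classify_pair(a, b[1:2, ]), "missing")
})

test_that("funnel groups implement the two-level set algebra", {
  ids <- paste0("g", 1:5)
  # g1: B (cv+wt only); g2: A (cv only, kept in ko); g3: C (lost in ko,
  # kept germ-free); g4: rhythmic everywhere -> none; g5: nowhere -> none
  cv <- fake_res(ids, c(0.01, 0.01, 0.01, 0.01, 0.5))
  gf <- fake_res(ids, c(0.50, 0.50, 0.01, 0.01, 0.5))
  ko <- fake_res(ids, c(0.50, 0.01, 0.50, 0.01, 0.5))
  fg <- funnel_groups(cv, gf, cv, ko)
  expect_equal(as.character(fg$funnel_group),
               c("B", "A", "C", "none", "none"))
  # A, B, C partition pieces are disjoint and within the rhythmic union
  expect_true(all(table(fg$gene_id[fg$funnel_group != "none"]) == 1))
  expect_true(all(fg$gene_id[fg$funnel_group != "none"] %in%
                    cv$gene_id[cv$p_adj <= 0.05]))
})

test_that("funnel recovery is exact on a noiseless planted benchmark", {
  sim <- simulate_funnel_benchmark(n_per_group = 30, n_null = 60, seed = 4,
                                   cv = 0)
  scans <- lapply(sim$matrices[c("CV", "GF", "KO")], jtk_scan)
  fg <- funnel_groups(scans$CV, scans$GF, scans$CV, scans$KO)
  expect_equal(as.character(fg$funnel_group), sim$truth$funnel_group)
})

test_that("phase differences wrap into (-period/2, period/2]", {
  r1 <- fake_res(c("g1", "g2", "g3"), rep(0.01, 3))
  r2 <- fake_res(c("g1", "g2", "g3"), rep(0.01, 3))
  r1$lag <- c(2, 8, 0); r2$lag <- c(22, 8, 12)
  d <- phase_amp_diff(r1, r2)
  expect_equal(d$phase_diff, c(4, 0, 12))  # +12 is the closed upper bound
  expect_true(all(d$phase_diff > -12 & d$phase_diff <= 12))
  # self-comparison is identically zero
  expect_true(all(phase_amp_diff(r1, r1)$phase_diff == 0))
  # genes without a defined lag are excluded with a message
  r2$lag[2] <- NA
  expect_message(d2 <- phase_amp_diff(r1, r2), "excluded")
  expect_equal(nrow(d2), 2)
})

test_that("a planted cross-condition delay is recovered in the median", {
  spec <- sim_spec(n_genes = 150, conditions = c("GF", "CV"),
                   blocks = list(list(name = "shared", n = 120,
                                      rhythmic_in = c("GF", "CV"),
                                      phase_shift = c(GF = 3))),
                   seed = 31)
  sim <- simulate_expression(spec)
  d <- phase_amp_diff(jtk_scan(sim$matrices$GF), jtk_scan(sim$matrices$CV))
  expect_lt(abs(median(d$phase_diff[d$both_rhythmic]) - 3), 1.5)
})

test_that("amplitude t-test matches its symmetry and degeneracy contracts", {
  x <- c(0.1, 0.2, 0.3); y <- c(0.25, 0.35, 0.15)
  tt <- amplitude_ttest(x, y)
  expect_equal(tt$p, t.test(x, y, var.equal = TRUE)$p.value)
  ts <- amplitude_ttest(y, x)
  expect_equal(ts$t, -tt$t)
  expect_equal(ts$p, tt$p)
  expect_warning(td <- amplitude_ttest(c(1, 1), c(1, 1)), "degenerate")
  expect_equal(td$t, 0)
  expect_equal(td$p, 1)
  # separated groups are overwhelmingly significant
  set.seed(8)
  big <- amplitude_ttest(rnorm(200, 0.3, 0.05), rnorm(200, 0.15, 0.05))
  expect_lt(big$p, 1e-4)
})

test_that("elbow K-means selects the planted number of temporal archetypes", {
  set.seed(42)
  zts <- rep(seq(0, 21, by = 3), 2)
  lag <- rep(c(2, 8, 14, 20), each = 40)
  sim <- sim_cosine_matrix(length(lag), rel_amp = 0.35, cv = 0.2,
                           lags = lag, seed = 42)
  ek <- elbow_kmeans(make_tcm(sim$Y), k_max = 8, seed = 5)
  expect_equal(ek$k, 4)
  tab <- table(lag, ek$assignments$cluster)
  expect_gte(sum(apply(tab, 1, max)) / length(lag), 0.95)
  # WSS is non-increasing and WSS(1) is the total sum of squares
  expect_true(all(diff(ek$wss) <= 1e-8))
  prof <- sapply(sort(unique(zts)), function(t)
    rowMeans(sim$Y[, zts == t, drop = FALSE]))
  z <- t(scale(t(prof)))
  expect_equal(unname(ek$wss[1]), sum(scale(z, scale = FALSE)^2),
               tolerance = 1e-8)
  # identical seed reproduces the fit exactly
  ek2 <- elbow_kmeans(make_tcm(sim$Y), k_max = 8, seed = 5)
  expect_identical(ek$assignments, ek2$assignments)
  expect_error(elbow_kmeans(make_tcm(sim$Y[1:5, ]), k_max = 8, seed = 1),
               "fewer genes")
})

test_that("up/down split uses timepoint-mean abundance with ties down", {
  samples <- default_samples()
  wt <- make_tcm(rbind(g1 = rep(2, 16), g2 = rep(4, 16), g3 = rep(3, 16)),
                 gene_ids = c("g1", "g2", "g3"))
  ko <- make_tcm(rbind(g1 = rep(4, 16), g2 = rep(2, 16), g3 = rep(3, 16)),
                 gene_ids = c("g1", "g2", "g3"))
  expect_warning(sp <- updown_split(wt, ko, c("g1", "g2", "g3")), "tie")
  expect_equal(sp$upregulated, "g1")
  expect_equal(sort(sp$downregulated), c("g2", "g3"))
  expect_error(updown_split(wt, ko, "g9"), "absent")
  # planted 2x induction with noise is recovered
  set.seed(12)
  base <- exp(rnorm(50, 2, 0.5))
  mkmat <- function(mu) make_tcm(
    mu * matrix(exp(rnorm(50 * 16, 0, sqrt(log(1.01)))), 50),
    gene_ids = paste0("i", 1:50))
  sp2 <- updown_split(mkmat(base), mkmat(2 * base), paste0("i", 1:50))
  expect_gte(length(sp2$upregulated) / 50, 0.95)
})

test_that("phase histogram conserves the rhythmic gene count", {
  sim <- sim_cosine_matrix(120, rel_amp = 0.4, cv = 0.15, seed = 19)
  res <- jtk_scan(make_tcm(sim$Y))$results
  h <- phase_polar_summary(res)
  expect_equal(sum(h), sum(res$rhythmic))
  expect_equal(dim(h), c(8, 5))
  # all mass in one bin when every gene peaks together
  res1 <- res[res$rhythmic, ]; res1$lag <- 9
  h1 <- phase_polar_summary(res1)
  expect_equal(sum(h1["9", ]), nrow(res1))
})
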