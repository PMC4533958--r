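two_cond <- function(nA, nB) {
  factor(rep(c("control", "case"), c(nA, nB)), levels = c("control", "case"))
}

test_that("count_reads counts every overlapping alignment record", {
  feats <- make_gr(data.frame(chrom = "chr1", start = c(100, 300, 500),
                              end = c(200, 400, 600), strand = "+"))
  mcols(feats)$feature_id <- c("f1", "f2", "f3")
  aln <- make_gr(data.frame(chrom = "chr1", start = rep(120, 5),
                            end = rep(145, 5), strand = "+"))
  m <- count_reads(feats, list(s1 = aln))
  expect_equal(unname(m[, 1]), c(5L, 0L, 0L))

  # one read with three alignments in three features adds one to each
  multi <- make_gr(data.frame(chrom = "chr1", start = c(120, 320, 520),
                              end = c(145, 345, 545), strand = "+"))
  m2 <- count_reads(feats, list(s1 = multi))
  expect_equal(unname(m2[, 1]), c(1L, 1L, 1L))

  expect_error(count_reads(GRanges(), list(s1 = aln)), "empty")
})

test_that("counting matches the brute-force all-pairs oracle", {
  set.seed(11)
  for (rep in 1:30) {
    fd <- random_intervals(8, max_pos = 500)
    ad <- random_intervals(40, max_pos = 500, min_w = 20, max_w = 35)
    feats <- make_gr(fd)
    mcols(feats)$feature_id <- sprintf("f%02d", 1:8)
    m <- count_reads(feats, list(s = make_gr(ad)))
    expect_equal(unname(m[, 1]), brute_count(fd, ad))
  }
})

test_that("unique-assignment counting drops alignments hitting several features", {
  feats <- make_gr(data.frame(chrom = "chr1", start = c(100, 140),
                              end = c(150, 190), strand = "+"))
  mcols(feats)$feature_id <- c("f1", "f2")
  aln <- make_gr(data.frame(chrom = "chr1", start = c(110, 145, 170),
                            end = c(135, 160, 185), strand = "+"))
  m_all <- count_reads(feats, list(s = aln), multimap = "all")
  m_unique <- count_reads(feats, list(s = aln), multimap = "unique")
  expect_equal(unname(m_all[, 1]), c(2L, 2L))
  expect_equal(unname(m_unique[, 1]), c(1L, 1L))
})

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), ncol = 2)
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)))

  same <- matrix(rep(c(5L, 9L, 14L), 3), ncol = 3)
  expect_equal(unname(size_factors(same)), rep(1, 3))

  single <- matrix(c(10L, 20L, 30L), ncol = 1)
  expect_equal(unname(size_factors(single)), 1)

  allzero_row <- matrix(c(0L, 5L, 0L, 7L), ncol = 2)
  expect_equal(unname(size_factors(allzero_row)),
               unname(size_factors(matrix(c(5L, 7L), ncol = 2))))
  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), ncol = 2)), "filter")
})

test_that("normalization conservation: median ratio to the reference is one", {
  set.seed(12)
  m <- matrix(rnbinom(200 * 6, mu = 100, size = 10), ncol = 6)
  sf <- size_factors(m)
  norm <- normalized_counts(m, sf)
  loggeo <- rowMeans(log(m))
  ok <- is.finite(loggeo)
  for (j in seq_len(ncol(m))) {
    expect_equal(median(norm[ok, j] / exp(loggeo[ok])), 1, tolerance = 1e-12)
  }
})

test_that("dispersion estimation: zero within-group variance floors raw at 0", {
  m <- cbind(matrix(rep(c(10L, 50L, 200L), 3), ncol = 3),
             matrix(rep(c(30L, 80L, 100L), 3), ncol = 3))
  sf <- rep(1, 6)
  expect_warning(
    dm <- estimate_dispersions(m, sf, two_cond(3, 3), fit_type = "local"),
    "zero"
  )
  expect_true(all(dm$raw == 0))
  expect_equal(dm$final, pmax(dm$fitted, dm$min_disp))
})

test_that("dispersion recovery and maximum sharing on NB simulations", {
  set.seed(13)
  m <- matrix(rnbinom(300 * 20, mu = 500, size = 1 / 0.2), ncol = 20)
  sf <- size_factors(m)
  cond <- two_cond(10, 10)
  dm <- estimate_dispersions(m, sf, cond, fit_type = "parametric")
  expect_gt(median(dm$final), 0.1)
  expect_lt(median(dm$final), 0.4)
  # maximum sharing: the final value is the floored max of raw and fitted
  expect_equal(dm$final, pmax(pmax(dm$raw, dm$fitted), dm$min_disp))

  # Poisson data: the asymptotic dispersion is essentially zero
  set.seed(14)
  mus <- exp(runif(2000, log(100), log(1000)))
  mp <- matrix(rpois(2000 * 20, rep(mus, 20)), ncol = 20)
  dp <- estimate_dispersions(mp, size_factors(mp), cond,
                             fit_type = "parametric")
  expect_lte(dp$coef[["asympt_disp"]], 0.05)

  expect_error(estimate_dispersions(m[, 1:2], sf[1:2],
                                    factor(c("a", "b")), "parametric"),
               "replicates")
})

test_that("the local fit follows a decreasing mean-dispersion trend", {
  set.seed(15)
  mus <- exp(runif(500, log(20), log(2000)))
  m <- matrix(rnbinom(500 * 12, mu = rep(mus, 12), size = 1 / 0.1), ncol = 12)
  dm <- estimate_dispersions(m, size_factors(m), two_cond(6, 6),
                             fit_type = "local")
  lo <- dm$trend$fn(20)
  hi <- dm$trend$fn(2000)
  expect_gt(lo, hi)  # small means carry more shot-noise dispersion
  expect_true(all(dm$final >= dm$min_disp, na.rm = TRUE))
})

test_that("the exact NB test equals direct exhaustive summation on small totals", {
  set.seed(16)
  n <- 40
  m <- matrix(rnbinom(n * 8, mu = 3, size = 1 / 0.3), ncol = 8)
  keep <- rowSums(m) > 0 & rowSums(m) <= 50
  m <- m[keep, , drop = FALSE]
  cond <- two_cond(4, 4)
  sf <- rep(1, 8)
  disp <- rep(0.3, nrow(m))
  p <- nbinom_test(m, sf, disp, cond)
  q <- rowMeans(normalized_counts(m, sf))
  for (i in seq_len(nrow(m))) {
    kA <- sum(m[i, 1:4]); kB <- sum(m[i, 5:8])
    muA <- q[i] * 4; muB <- q[i] * 4
    vA <- max(muA + disp[i] * q[i]^2 * 4, muA * (1 + 1e-8))
    vB <- max(muB + disp[i] * q[i]^2 * 4, muB * (1 + 1e-8))
    want <- brute_nbinom_p(kA, kB, muA, muA^2 / (vA - muA),
                           muB, muB^2 / (vB - muB))
    expect_equal(p[i], want, tolerance = 1e-10)
  }
})

test_that("the exact NB test is exchangeable in the group labels", {
  set.seed(17)
  m <- matrix(rnbinom(100 * 10, mu = 50, size = 10), ncol = 10)
  sf <- size_factors(m)
  disp <- rep(0.1, 100)
  cond <- two_cond(5, 5)
  p1 <- nbinom_test(m, sf, disp, cond)
  p2 <- nbinom_test(m, sf, disp, factor(cond, levels = rev(levels(cond))))
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("all-zero features get p = 1 and missing dispersions are an error", {
  m <- rbind(c(0L, 0L, 0L, 0L), c(10L, 12L, 9L, 11L))
  sf <- rep(1, 4)
  p <- nbinom_test(m, sf, c(NA, 0.1), two_cond(2, 2))
  expect_equal(p[1], 1)
  expect_error(nbinom_test(m, sf, c(0.1, NA), two_cond(2, 2)), "missing")
})

test_that("fold changes follow the 0-mean conventions", {
  m <- rbind(c(10L, 10L, 10L, 10L),
             c(0L, 0L, 5L, 7L),
             c(4L, 6L, 0L, 0L),
             c(0L, 0L, 0L, 0L))
  fc <- fold_change(m, rep(1, 4), two_cond(2, 2))
  expect_equal(fc$log2FoldChange[1], 0)
  expect_equal(fc$log2FoldChange[2], Inf)
  expect_equal(fc$log2FoldChange[3], -Inf)
  expect_true(is.na(fc$log2FoldChange[4]))
  expect_equal(fc$baseMean[1], 10)
})

test_that("BH adjustment matches the textbook step-up oracle", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(18)
  for (rep in 1:20) {
    p <- runif(sample(5:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("significance filtering is strict and sorted", {
  res <- data.frame(id = c("a", "b", "c", "d"),
                    baseMean = 1:4,
                    log2FoldChange = c(2, -8, Inf, 1),
                    pvalue = c(1e-7, 1e-9, 1e-9, 0.5),
                    padj = c(1e-6, 2e-7, 3e-8, 0.9))
  sig <- filter_significant(res, 1e-6)
  expect_equal(sig$id, c("c", "b"))  # padj == 1e-6 exactly is excluded
})

test_that("the VST is monotone, sqrt-like without dispersion, and stabilizing", {
  set.seed(19)
  cond <- two_cond(10, 10)
  mus <- exp(runif(1000, log(10), log(10000)))
  m <- matrix(rnbinom(1000 * 20, mu = rep(mus, 20), size = 1 / 0.05),
              ncol = 20)
  sf <- size_factors(m)
  dm <- estimate_dispersions(m, sf, cond, fit_type = "parametric")
  v <- vst(m, dm, sf)
  expect_equal(dim(v), dim(m))
  # monotonicity on a probe matrix
  probe <- matrix(as.integer(round(seq(1, 5000, length.out = 50))), ncol = 1)
  vp <- vst(cbind(probe, probe), dm, c(1, 1))[, 1]
  expect_true(all(diff(vp) > 0))
  # convergence to log2 shifts for large counts
  big <- vst(matrix(c(20000L, 40000L), ncol = 2), dm, c(1, 1))
  expect_equal(big[1, 2] - big[1, 1], 1, tolerance = 0.05)
  # variance stabilization across three decades of mean
  bins <- cut(log10(mus), 3)
  raw_ratio <- tapply(apply(m, 1, var), bins, median)
  vst_ratio <- tapply(apply(v, 1, var), bins, median)
  expect_gt(max(raw_ratio) / min(raw_ratio), 100)
  expect_lt(max(vst_ratio) / min(vst_ratio), 4)

  # Poisson-limit behavior: with a vanishing dispersion trend the transform
  # behaves like a square root (Anscombe-type stabilization)
  set.seed(20)
  mp <- matrix(rpois(2000 * 20, rep(exp(runif(2000, log(50), log(5000))), 20)),
               ncol = 20)
  dp <- estimate_dispersions(mp, size_factors(mp), cond, "parametric")
  vq <- function(q) vst(matrix(as.integer(q), ncol = 1), dp, 1)[1, 1]
  r <- (vq(400) - vq(100)) / (vq(100) - vq(25))
  expect_equal(r, (sqrt(400) - sqrt(100)) / (sqrt(100) - sqrt(25)),
               tolerance = 0.1)

  expect_error(vst(m, list()), "dispersion_model")
})

test_that("the local-fit VST is monotone and log2-anchored", {
  set.seed(21)
  mus <- exp(runif(400, log(10), log(5000)))
  m <- matrix(rnbinom(400 * 12, mu = rep(mus, 12), size = 1 / 0.1), ncol = 12)
  sf <- size_factors(m)
  dm <- estimate_dispersions(m, sf, two_cond(6, 6), fit_type = "local")
  v <- vst(m, dm, sf)
  probe <- matrix(as.integer(round(seq(1, 4000, length.out = 40))), ncol = 1)
  vp <- vst(cbind(probe, probe), dm, c(1, 1))[, 1]
  expect_true(all(diff(vp) > 0))
})

test_that("nbinom_de assembles the published result columns", {
  set.seed(22)
  mus <- exp(runif(120, log(20), log(500)))
  m <- matrix(rnbinom(120 * 10, mu = rep(mus, 10), size = 20), ncol = 10)
  rownames(m) <- sprintf("f%03d", 1:120)
  m[1, 6:10] <- m[1, 6:10] + 400L  # one strong case-side feature
  res <- nbinom_de(m, two_cond(5, 5), fit_type = "parametric")
  expect_named(res, c("id", "baseMean", "log2FoldChange", "pvalue", "padj"))
  expect_true(all(res$padj >= res$pvalue, na.rm = TRUE))
  expect_equal(res$id[which.min(res$padj)], "f001")
  expect_gt(res$log2FoldChange[1], 0)
})
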