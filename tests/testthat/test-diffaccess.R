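test_that("exact Mann-Whitney matches full enumeration for all group sizes up to (6,7)", {
  set.seed(42)
  for (n1 in 2:6) for (n2 in 2:7) {
    for (rep in 1:3) {
      x <- rnorm(n1); y <- rnorm(n2) + rnorm(1)
      got <- mw_test(x, y)$p_value
      expect_equal(got, enumerate_mw_p(x, y), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
    }
  }
  # frozen hand case: enumeration over C(6,3)=20 assignments gives 2/20
  expect_equal(mw_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  # perfectly interleaved identical values: p = 1
  expect_equal(mw_test_rows(matrix(c(1, 2, 3, 1, 2, 3), nrow = 1),
                            rep(c("control", "mutant"), each = 3))$p_value, 1)
})

test_that("tied or large-n rows agree with wilcox.test's corrected normal approximation", {
  set.seed(7)
  # ties from discrete counts
  m <- matrix(rpois(20 * 13, 6), nrow = 20)
  g <- rep(c("control", "mutant"), c(6, 7))
  got <- mw_test_rows(m, g)
  ref <- apply(m, 1, function(r) {
    suppressWarnings(stats::wilcox.test(r[7:13], r[1:6], exact = FALSE,
                                        correct = TRUE)$p.value)
  })
  has_ties <- apply(m, 1, function(r) any(duplicated(r)))
  expect_true(any(has_ties))
  expect_equal(got$p_value[has_ties], ref[has_ties], tolerance = 1e-10)
  # tie-free exact route also matches wilcox.test's exact route
  m2 <- matrix(rnorm(10 * 13), nrow = 10)
  got2 <- mw_test_rows(m2, g)
  ref2 <- apply(m2, 1, function(r)
    stats::wilcox.test(r[7:13], r[1:6], exact = TRUE)$p.value)
  expect_equal(got2$p_value, ref2, tolerance = 1e-12)
  # constant row: no information, p = 1
  expect_equal(mw_test_rows(matrix(5, 1, 13), g)$p_value, 1)
})

test_that("size factors: identity, doubled-library closed form, idempotence, scaling", {
  m <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  set.seed(3)
  m3 <- matrix(rpois(200 * 6, 20) + 1, ncol = 6)
  s <- size_factors(m3)
  norm <- sweep(m3, 2, s, "/")
  expect_equal(unname(size_factors(norm)), rep(1, 6), tolerance = 1e-9)

  # scaling library j by c multiplies s_j by c * c^(-1/n) and divides the
  # others by c^(1/n) (after the unit-geomean rescale)
  cfac <- 3
  m4 <- m3; m4[, 2] <- m4[, 2] * cfac
  s4 <- size_factors(m4)
  expect_equal(s4[2] / s[2], cfac * cfac^(-1 / 6), tolerance = 1e-9)
  expect_equal(unname(s4[-2] / s[-2]), rep(cfac^(-1 / 6), 5), tolerance = 1e-9)

  # agreement with the reference median-of-ratios estimator up to its
  # geometric mean (the package rescales to unit geomean)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m3)
  expect_equal(unname(s), unname(ref / exp(mean(log(ref)))), tolerance = 1e-12)

  # all-zero-containing rows only -> informative error
  expect_error(size_factors(cbind(c(0, 1), c(1, 0))), "positive")
})

test_that("retention filter keeps intervals with raw mean >= 5", {
  m <- matrix(5, nrow = 1, ncol = 13)
  expect_equal(retention_filter(m), 1L)                  # mean exactly 5 kept
  expect_length(retention_filter(matrix(0, 1, 13)), 0)   # all-zero dropped
  # scan: per-interval means 0..10, smallest retained mean is min_mean
  m2 <- matrix(rep(0:10, each = 4), ncol = 4, byrow = TRUE)
  kept <- retention_filter(m2, min_mean = 5)
  expect_equal(min(rowMeans(m2)[kept]), 5)
  expect_equal(kept, 6:11)
})

test_that("low-count library exclusion and group-size guard", {
  counts <- cbind(a = rep(1, 10) * 1e5, b = rep(2, 10) * 1e5,
                  c = rep(18, 10) * 1e5, d = rep(25, 10) * 1e5)
  g <- c("control", "mutant", "control", "mutant")
  # totals 1e6, 2e6, 1.8e7, 2.5e7 with min_reads 1e7 -> 2 kept, 2 excluded,
  # but that leaves one library per group: hard error
  expect_error(exclude_low_count_libraries(counts, g, min_reads = 1e7),
               "fewer than 2")
  counts2 <- cbind(counts, counts + 5e5)
  g2 <- c(g, g)
  ex <- exclude_low_count_libraries(counts2, g2, min_reads = 1e7)
  expect_equal(length(ex$kept), 4)
  expect_equal(nrow(ex$excluded), 4)
  # all above threshold -> nothing excluded
  ex2 <- exclude_low_count_libraries(counts2, g2, min_reads = 1e5)
  expect_equal(nrow(ex2$excluded), 0)
})

test_that("fold change is mean(mutant)/mean(control) on normalized counts; label swap inverts it", {
  set.seed(9)
  n_bins <- 400
  counts <- matrix(rpois(n_bins * 13, 12), ncol = 13,
                   dimnames = list(NULL, sprintf("lib%02d", 1:13)))
  g <- rep(c("control", "mutant"), c(6, 7))
  da <- diff_accessibility(counts, g, min_reads = 0)
  # arithmetic spot check on one interval
  s <- da$size_factors
  i <- da$intervals$bin[1]
  norm <- counts[i, ] / s
  expect_equal(da$intervals$fold_change[1],
               mean(norm[7:13]) / mean(norm[1:6]))
  # swapped labels: FC inverts, p invariant
  g_sw <- rep(c("mutant", "control"), c(6, 7))
  da_sw <- diff_accessibility(counts, g_sw, min_reads = 0)
  expect_equal(da_sw$intervals$fold_change, 1 / da$intervals$fold_change,
               tolerance = 1e-12)
  expect_equal(da_sw$intervals$p_value, da$intervals$p_value,
               tolerance = 1e-12)
})

test_that("zero-control-mean intervals are flagged and excluded from the curve", {
  counts <- rbind(matrix(rpois(300 * 5, 10), ncol = 5),
                  c(0, 0, 20, 22, 21))
  g <- c("control", "control", "mutant", "mutant", "mutant")
  da <- diff_accessibility(counts, g, min_reads = 0)
  iv <- da$intervals
  flagged <- iv[!iv$fc_defined, ]
  expect_equal(nrow(flagged), 1)
  expect_true(is.na(flagged$fold_change))
  cv <- ratio_curve(da, W = 50)
  expect_false(any(is.na(cv$ranked$fold_change)))
})

test_that("null counts give conservative (stochastically super-uniform) p-values", {
  set.seed(123)
  n_bins <- 2000
  counts <- matrix(rpois(n_bins * 13, 15), ncol = 13)
  g <- rep(c("control", "mutant"), c(6, 7))
  da <- diff_accessibility(counts, g, min_reads = 0)
  p <- da$intervals$p_value
  # one-sided KS: empirical CDF must not exceed the uniform CDF by more
  # than the alpha = 0.01 one-sided band; for the discrete exact null
  # P(p <= t) <= t holds pointwise, so ECDF(t) - t is centred below 0
  tgrid <- sort(unique(p))
  excess <- max(ecdf(p)(tgrid) - tgrid)
  band <- sqrt(log(1 / 0.01) / (2 * length(p)))
  expect_lt(excess, band)
})
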