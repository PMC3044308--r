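test_that("extend_tags follows the strand conventions and truncates at 0", {
  tags <- data.frame(chrom = "chr1", pos = c(1000, 1000, 50),
                     strand = c("+", "-", "-"), stringsAsFactors = FALSE)
  fr <- extend_tags(tags, 200)
  expect_equal(fr$start, c(1000, 801, 0))
  expect_equal(fr$end, c(1200, 1001, 51))
  expect_error(extend_tags(tags, 0), ">= 1")
})

test_that("call_peaks finds maximal regions with max-coverage intensity", {
  # uniform stack of 100 identical fragments
  fr <- make_fragments(rep(1000, 100))
  pk <- call_peaks(fr, min_height = 5)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 1000)
  expect_equal(pk$end, 1200)
  expect_equal(pk$intensity, 100)

  # nothing reaches the threshold
  expect_equal(nrow(call_peaks(make_fragments(c(0, 1000)), 5)), 0L)

  # two disjoint stacks separated by zero coverage
  fr2 <- make_fragments(c(rep(100, 7), rep(2000, 3)))
  pk2 <- call_peaks(fr2, min_height = 2)
  expect_equal(nrow(pk2), 2L)
  expect_equal(pk2$intensity, c(7, 3))
})

test_that("call_peaks agrees with a per-base brute-force oracle", {
  for (s in 1:5) {
    fr <- with(list(), {
      set.seed(s)
      make_fragments(sample.int(9800, 120, replace = TRUE) - 1L,
                     length = 200)
    })
    for (h in c(1, 2, 4)) {
      got <- call_peaks(fr, h)
      exp <- brute_call_peaks(fr, h, 10000)
      expect_equal(got$start, exp$start)
      expect_equal(got$end, exp$end)
      expect_equal(got$intensity, as.numeric(exp$intensity))
    }
  }
})

test_that("coverage is conserved for untruncated fragments", {
  set.seed(1)
  fr <- make_fragments(sample.int(5000, 60) + 200)
  cov <- IRanges::coverage(IRanges::IRanges(fr$start + 1L, fr$end))
  expect_equal(sum(as.numeric(cov)), nrow(fr) * 200)
})

test_that("Monte-Carlo FDR tables are deterministic with non-increasing FDR", {
  tab1 <- estimate_fdr_mc(300, 50000, 200, n_iterations = 20, seed = 42,
                          observed_counts = c(50, 40, 20, 10, 5, 2, 1))
  tab2 <- estimate_fdr_mc(300, 50000, 200, n_iterations = 20, seed = 42,
                          observed_counts = c(50, 40, 20, 10, 5, 2, 1))
  expect_identical(tab1, tab2)
  expect_true(all(diff(tab1$fdr) <= 0))
  expect_true(all(tab1$fdr >= 0 & tab1$fdr <= 1))

  # empty library
  tab0 <- estimate_fdr_mc(0, 50000, 200, n_iterations = 5, seed = 1)
  expect_equal(tab0$expected_false, 0)
})

test_that("fold enrichment normalizes by library size with a control pseudocount", {
  peak <- make_peaks(0, 100, 10)
  # equal normalized overlap -> 1
  s <- make_fragments(c(rep(0, 10), rep(5000, 990)))
  c_eq <- make_fragments(c(rep(0, 10), rep(5000, 990)))
  expect_equal(fold_enrichment(peak, s, c_eq), 1.0)
  # 10/1000 vs 1/1000 -> 10
  c10 <- make_fragments(c(0, rep(5000, 999)))
  expect_equal(fold_enrichment(peak, s, c10), 10.0)
  # control overlap 0 -> +1 pseudocount: 5/500 vs 1/500 -> 5
  s5 <- make_fragments(c(rep(0, 5), rep(5000, 495)))
  c0 <- make_fragments(rep(5000, 500))
  expect_equal(fold_enrichment(peak, s5, c0), 5.0)
  expect_error(fold_enrichment(peak, s5, make_fragments(numeric(0))),
               "non-empty")
})

test_that("filter_peaks applies FDR < max and fold >= min jointly", {
  tab <- data.frame(h = 1:10,
                    expected_false = c(100, 50, 20, 8, 3, 1, 0.3, 0.1,
                                       0.02, 0),
                    fdr = c(1, 1, 0.8, 0.4, 0.10, 0.04, 0.01, 0.01,
                            0.001, 0))
  pk <- make_peaks(c(0, 500, 1000), c(100, 600, 1100),
                   intensity = c(8, 5, 8),        # FDR 0.01, 0.10, 0.01
                   fold_enrichment = c(6, 6, 4.9))
  kept <- filter_peaks(pk, tab)
  expect_equal(kept$start, 0)          # only the first survives
  expect_equal(kept$fdr, 0.01)
  # intensities above the simulated maximum get FDR 0
  pk2 <- make_peaks(0, 100, intensity = 50, fold_enrichment = 10)
  expect_equal(filter_peaks(pk2, tab)$fdr, 0)
})
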