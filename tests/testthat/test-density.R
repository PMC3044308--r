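test_that("relative_positions orients offsets by the nearest gene's strand", {
  genes <- make_genes(1000, strand = "+")
  pk <- make_peaks(1400, 1600, 1)        # midpoint 1500
  expect_equal(as.numeric(relative_positions(pk, genes)), 500)

  genes_m <- make_genes(1000, strand = "-")
  expect_equal(as.numeric(relative_positions(pk, genes_m)), -500)
  expect_equal(as.numeric(relative_positions(pk, genes_m,
                                             strand_aware = FALSE)), 500)

  # beyond the window -> excluded
  far <- make_peaks(80900, 81100, 1)     # 80 kb from the only TSS
  expect_length(relative_positions(far, genes, window = 50000), 0)

  # equidistant TSSs break toward the lower coordinate
  two <- make_genes(c(1000, 2000), strand = "+")
  mid <- make_peaks(1400, 1600, 1)       # midpoint 1500, 500 from both
  expect_equal(as.numeric(relative_positions(mid, two)), 500)

  # peaks on chromosomes without genes are skipped
  off_chrom <- make_peaks(100, 300, 1, chrom = "chr9")
  expect_length(relative_positions(off_chrom, genes), 0)
})

test_that("relative_positions is invariant to peak order", {
  set.seed(11)
  genes <- make_genes(sort(sample.int(4e6, 50)))
  pk <- make_peaks(sample.int(4e6, 200), sample.int(4e6, 200) + 200, 1)
  a <- sort(as.numeric(relative_positions(pk, genes)))
  b <- sort(as.numeric(relative_positions(pk[sample.int(200), ], genes)))
  expect_equal(a, b)
})

test_that("estimate_density matches the exact kernel sum and normalizes to max 1", {
  # single offset: maximum at grid point 0
  pr <- estimate_density(0, bandwidth = 300)
  expect_equal(pr$heights[pr$grid == 0], 1.0)
  expect_equal(max(pr$heights), 1.0, tolerance = 1e-12)

  # brute-force sum-of-Gaussians oracle on a modest sample
  set.seed(2)
  off <- rnorm(150, 0, 5000)
  pr2 <- estimate_density(off, bandwidth = 300, grid_step = 500)
  oracle <- vapply(pr2$grid, function(g)
    sum(stats::dnorm(g - off, sd = 300)) / length(off), numeric(1))
  oracle <- oracle / max(oracle)
  expect_equal(pr2$heights, oracle, tolerance = 1e-10)

  # two symmetric offsets: two modes of equal height 1
  pr3 <- estimate_density(c(-40000, 40000), bandwidth = 300)
  expect_equal(pr3$heights[pr3$grid == -40000], 1.0)
  expect_equal(pr3$heights[pr3$grid == 40000], 1.0)

  expect_error(estimate_density(numeric(0)), "empty")
})

test_that("profile_at interpolates linearly and is zero outside the grid", {
  pr <- flat_profile(0.5)
  expect_equal(profile_at(pr, 5000), 0.5)
  expect_equal(profile_at(pr, 50), 0.75)   # halfway between 1 and 0.5
  expect_equal(profile_at(pr, 60001), 0)
})

test_that("two-sample KS matches an exhaustive ECDF scan", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(rep(-1000, 3), rep(1000, 3))$statistic, 1)
  for (s in 1:6) {
    set.seed(s)
    a <- rnorm(sample(5:100, 1), 0, 1000)
    b <- rnorm(sample(5:100, 1), 200, 1200)
    expect_equal(ks_two_sample(a, b)$statistic, brute_ks_D(a, b),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1), "empty")
})

test_that("exponential KS accepts exponential offsets and rejects bimodal ones", {
  accepted <- 0L
  for (s in 1:10) {
    set.seed(s)
    off <- sample(c(-1, 1), 2000, TRUE) * rexp(2000, 1 / 5000)
    if (ks_vs_exponential(off)$p_value > 0.01) accepted <- accepted + 1L
  }
  expect_gte(accepted, 9L)

  set.seed(1)
  bimodal <- sample(c(-1, 1), 2000, TRUE) * rnorm(2000, 10000, 500)
  expect_lt(ks_vs_exponential(bimodal)$p_value, 0.001)

  # degenerate single observation
  one <- ks_vs_exponential(5000)
  expect_true(is.finite(one$statistic))
  expect_gt(one$p_value, 0.5)
  expect_error(ks_vs_exponential(c(0, 0)), "zero")
})
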