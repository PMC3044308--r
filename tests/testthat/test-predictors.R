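test_that("density_score sums intensity times interpolated profile height", {
  genes <- make_genes(10000, strand = "+")
  pr <- flat_profile(0.5)
  # no peaks in window
  expect_equal(density_score(genes, make_peaks(numeric(0), numeric(0),
                                               numeric(0)), pr), 0)
  # one peak, g = 10, F = 0.5 at offset 5000
  pk <- make_peaks(14900, 15100, 10)
  expect_equal(density_score(genes, pk, pr), 5.0)
  # two peaks: (g=2 at F=1, i.e. offset 0) + (g=4 at F=0.25)
  pr2 <- flat_profile(0.25)
  pk2 <- make_peaks(c(9900, 14900), c(10100, 15100), c(2, 4))
  expect_equal(density_score(genes, pk2, pr2), 2 * 1 + 4 * 0.25)
})

test_that("density_score is additive over peak partitions and order-invariant", {
  set.seed(3)
  genes <- make_genes(sort(sample.int(2e6, 30)))
  pk <- make_peaks(sample.int(2e6, 100), sample.int(2e6, 100) + 200,
                   runif(100, 1, 20))
  pr <- estimate_density(rnorm(200, 0, 8000))
  full <- density_score(genes, pk, pr)
  part <- density_score(genes, pk[1:40, ], pr) +
    density_score(genes, pk[41:100, ], pr)
  expect_equal(full, part, tolerance = 1e-12)
  shuffled <- density_score(genes, pk[sample.int(100), ], pr)
  expect_equal(full, shuffled, tolerance = 1e-12)
})

test_that("exponential_score applies the decay weight", {
  genes <- make_genes(10000)
  # peak at the TSS: exp(0) = 1
  expect_equal(exponential_score(genes, make_peaks(9900, 10100, 7), d0 = 5000),
               7.0)
  # |l| = d0 -> g * exp(-1)
  expect_equal(exponential_score(genes, make_peaks(14900, 15100, 10),
                                 d0 = 5000), 10 * exp(-1))
  expect_equal(exponential_score(genes, make_peaks(numeric(0), numeric(0),
                                                   numeric(0))), 0)
  expect_error(exponential_score(genes, make_peaks(1, 2, 1), d0 = 0),
               "positive")
})

test_that("categorical encodings reproduce the specified codes", {
  expect_equal(encode_histone(c("none", "K27me3", "bivalent", "K4me3")),
               c(1, 2, 3, 4))
  expect_error(encode_histone("H3K9me3"), "unknown")
  expect_equal(encode_methylation(c(0.8, 0.1, 0.8, NA, 0.5),
                                  c(0.6, 0.6, 0.4, 0.6, 0.6)),
               c(2, 3, 1, 1, 1))
  expect_equal(encode_cpg(c(TRUE, FALSE)), c(2, 1))
})

test_that("transform_design quantile-normalizes score columns", {
  v <- cbind(a = c(1, 2, 3), b = c(10, 20, 30))
  rownames(v) <- c("g1", "g2", "g3")
  d <- structure(list(values = v, score_cols = c("a", "b"),
                      epi_cols = character(0), transform_state = "raw"),
                 class = "design_matrix")
  out <- transform_design(d, log = FALSE)
  expect_equal(unname(out$values[, "a"]), c(5.5, 11.0, 16.5))
  expect_equal(unname(out$values[, "b"]), c(5.5, 11.0, 16.5))
  expect_error(transform_design(out), "already")

  # single column unchanged by the quantile step
  d1 <- structure(list(values = v[, 1, drop = FALSE], score_cols = "a",
                       epi_cols = character(0), transform_state = "raw"),
                  class = "design_matrix")
  expect_equal(transform_design(d1, log = FALSE)$values[, 1], v[, 1])

  # after transformation all columns share one multiset of values
  set.seed(4)
  v2 <- matrix(rexp(60), 20, 3, dimnames = list(NULL, c("x", "y", "z")))
  d2 <- structure(list(values = v2, score_cols = c("x", "y", "z"),
                       epi_cols = character(0), transform_state = "raw"),
                  class = "design_matrix")
  tv <- transform_design(d2)$values
  expect_equal(sort(tv[, 1]), sort(tv[, 2]), tolerance = 1e-12)
  expect_equal(sort(tv[, 2]), sort(tv[, 3]), tolerance = 1e-12)
})

test_that("build_design assembles TF and epigenetic columns", {
  set.seed(5)
  genes <- make_genes(seq(50000, by = 40000, length.out = 20))
  tfs <- paste0("TF", 1:11)
  peak_sets <- setNames(lapply(tfs, function(tf) {
    s <- sample(seq(30000, 900000), 30)
    make_peaks(s, s + 200, runif(30, 1, 10), tf_name = tf)
  }), tfs)
  profiles <- setNames(rep(list(flat_profile(0.5)), 11), tfs)
  states <- data.frame(gene_id = genes$gene_id,
                       histone = "K4me3", methylation = "methylated",
                       cpg = TRUE, stringsAsFactors = FALSE)
  d <- build_design(genes, peak_sets, profiles, states,
                    include_epigenetic = TRUE)
  expect_equal(ncol(d$values), 14L)      # 11 TFs + HistM, Methy, CpGI
  expect_equal(colnames(d$values), c(tfs, "HistM", "Methy", "CpGI"))
  expect_equal(d$transform_state, "raw")

  d12 <- build_design(genes, c(peak_sets, list(TF12 = peak_sets[[1]])),
                      c(profiles, list(TF12 = profiles[[1]])),
                      include_epigenetic = FALSE)
  expect_equal(ncol(d12$values), 12L)

  d0 <- build_design(genes[0, ], peak_sets, profiles,
                     include_epigenetic = FALSE)
  expect_equal(nrow(d0$values), 0L)

  expect_error(build_design(genes, peak_sets, profiles,
                            states[-1, ], include_epigenetic = TRUE),
               "g001")
})
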