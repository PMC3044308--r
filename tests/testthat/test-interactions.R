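test_that("enumerate_terms counts follow m + C(m,2) + C(m,3)", {
  t14 <- enumerate_terms(paste0("v", 1:14))
  expect_equal(nrow(t14), 469L)
  expect_equal(sum(t14$order > 1), 455L)

  t3 <- enumerate_terms(c("a", "b", "c"))
  expect_equal(t3$term, c("a", "b", "c", "a:b", "a:c", "b:c", "a:b:c"))
  expect_equal(nrow(enumerate_terms(c("a", "b"))), 3L)

  for (m in 3:20) {
    n <- nrow(enumerate_terms(paste0("x", seq_len(m))))
    expect_equal(n, m + choose(m, 2) + choose(m, 3))
  }
})

test_that("saturated matrix columns are elementwise products", {
  X <- cbind(A = c(1, 2), B = c(3, 4), C = c(5, 6))
  M <- build_saturated_matrix(X, enumerate_terms(colnames(X)))
  expect_equal(ncol(M), 7L)
  expect_equal(unname(M[, "A:B"]), c(3, 8))
  expect_equal(unname(M[, "A:B:C"]), c(15, 48))
  expect_error(build_saturated_matrix(X, "A:Z"), "unknown")
})

test_that("sequential ANOVA screening flags the signal-bearing term", {
  set.seed(31)
  X <- matrix(rnorm(500 * 5), 500, 5, dimnames = list(NULL, paste0("x", 1:5)))
  terms <- enumerate_terms(colnames(X))
  sat <- build_saturated_matrix(X, terms)
  y <- 2 * X[, 3] + rnorm(500, 0, 1)
  sc <- anova_screen(sat, y)
  expect_equal(sc$term[which.min(sc$p_value)], "x3")

  # F(1, nu) = t^2 identity for a single-column model
  x <- rnorm(60)
  ys <- 0.5 * x + rnorm(60)
  sc1 <- anova_screen(cbind(x = x), ys)
  tstat <- summary(lm(ys ~ x))$coefficients["x", "t value"]
  fstat <- anova(lm(ys ~ x))["x", "F value"]
  expect_equal(fstat, tstat^2, tolerance = 1e-10)
  expect_equal(sc1$p_value, anova(lm(ys ~ x))["x", "Pr(>F)"],
               tolerance = 1e-12)

  # aliased columns are screened out with NA p-values
  Xa <- cbind(a = X[, 1], b = X[, 1])
  sca <- anova_screen(Xa, y)
  expect_true(is.na(sca$p_value[2]))
})

test_that("null-model p-values are approximately uniform", {
  pooled <- numeric(0)
  for (s in 1:4) {
    set.seed(s + 50)
    X <- matrix(rnorm(300 * 8), 300, 8,
                dimnames = list(NULL, paste0("x", 1:8)))
    sat <- build_saturated_matrix(X, enumerate_terms(colnames(X)))
    sc <- anova_screen(sat, rnorm(300))
    pooled <- c(pooled, sc$p_value[!is.na(sc$p_value)])
  }
  expect_gt(length(pooled), 300)
  expect_gt(suppressWarnings(ks.test(pooled, "punif"))$p.value, 0.01)
})

test_that("greedy selection finds a planted interaction and stays deterministic", {
  set.seed(41)
  n <- 800
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- X[, 1] + X[, 2] + 2 * X[, 1] * X[, 2] + rnorm(n, 0, 0.5)
  sat <- build_saturated_matrix(X, enumerate_terms(colnames(X)))
  sc <- anova_screen(sat, y)
  sel <- greedy_select(sc, X, y, cv_seed = 41)
  expect_true("x1:x2" %in% sel$terms)
  main_cv <- cross_validate(X, y, seed = 41)
  expect_gt(sel$cv_r2, main_cv$cv_r2)
  expect_gte(sel$cv_r2, 0)              # never below the empty model
  sel2 <- greedy_select(sc, X, y, cv_seed = 41)
  expect_identical(sel$terms, sel2$terms)
  expect_identical(sel$cv_r2, sel2$cv_r2)

  # nothing significant -> intercept-only with a warning
  sc0 <- sc
  sc0$p_value <- 0.9
  expect_warning(out <- greedy_select(sc0, X, y, cv_seed = 1), "no term")
  expect_length(out$terms, 0)
})

test_that("the network split rule handles epigenetic partners and multiplicity", {
  net <- terms_to_network(c("Oct4:Sox2:Stat3", "Zfx:Methy", "Klf4"))
  want <- data.frame(
    node_a = c("Klf4", "Methy", "Oct4", "Oct4", "Oct4", "Sox2", "Sox2",
               "Stat3"),
    node_b = c("__geneset__", "Zfx", "Sox2", "Stat3", "__geneset__",
               "Stat3", "__geneset__", "__geneset__"),
    multiplicity = rep(1L, 8), stringsAsFactors = FALSE)
  rownames(net) <- NULL
  rownames(want) <- NULL
  expect_equal(net, want)
  # Zfx must NOT be linked to the target through Zfx:Methy
  expect_false(any(net$node_a == "Zfx" & net$node_b == "__geneset__"))

  # pairwise term without epigenetic partner links both members to target
  net2 <- terms_to_network("Oct4:Sox2")
  expect_equal(nrow(net2), 3L)

  # duplicate edges accumulate; order of terms is irrelevant
  a <- terms_to_network(c("Oct4:Sox2", "Oct4"))
  b <- terms_to_network(c("Oct4", "Oct4:Sox2"))
  expect_equal(a, b)
  expect_equal(a$multiplicity[a$node_a == "Oct4" &
                              a$node_b == "__geneset__"], 2L)
})
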