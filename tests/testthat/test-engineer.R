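test_that("engineered features follow the count formula and definitions", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  one <- brute_force_engineer(X, op_set = "product", top_k = 2)
  expect_equal(ncol(one), 1)
  expect_equal(unname(one[, "a*b"]), unname(X[, "a"] * X[, "b"]))

  full2 <- brute_force_engineer(X, top_k = 2)
  expect_equal(ncol(full2), 5)  # 3*C(2,2=1 pair) + 2 ordered ratios

  # closed form vs exhaustive enumeration for several settings
  for (k in 2:4) {
    for (ops in list("sum", c("sum", "product"),
                     c("sum", "abs_diff", "product", "ratio"))) {
      expect_equal(ncol(brute_force_engineer(X, op_set = ops, top_k = k)),
                   engineered_count(k, ops))
    }
  }
  expect_warning(none <- brute_force_engineer(X, top_k = 1), "top_k")
  expect_equal(ncol(none), 0)
  expect_error(brute_force_engineer(X, top_k = 9), "config")
})

test_that("ratio denominators are guarded at zero", {
  X <- cbind(num = c(3, 1), den = c(0, 2))
  e <- brute_force_engineer(X, op_set = "ratio", top_k = 2,
                            ratio_epsilon = 1e-9)
  expect_equal(unname(e[1, "num/den"]), 3 / 1e-9)
  expect_true(all(is.finite(e)))
})

test_that("standardized engineering reproduces at prediction time", {
  set.seed(2)
  X <- matrix(rnorm(60, 5, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  e <- brute_force_engineer(X, top_k = 3, standardize = TRUE)
  specs <- attr(e, "specs")
  e2 <- gbfs:::.apply_engineered(X, specs)
  expect_equal(colnames(e2), colnames(e))
  expect_equal(as.vector(e2), as.vector(e))
})

test_that("the correlation filter removes offending pairs by priority", {
  set.seed(3)
  n <- 300
  base <- rnorm(n)
  X <- cbind(top = base + rnorm(n, 0, 0.1),
             mid = base + rnorm(n, 0, 0.12),
             low = base + rnorm(n, 0, 0.15),
             free = rnorm(n))
  kept <- correlation_filter(X, threshold = 0.8,
                             priority = c("top", "mid", "low", "free"))
  expect_setequal(kept, c("top", "free"))
  # duplicated column: exactly one survives
  X2 <- cbind(a = base, b = base, c = rnorm(n))
  expect_setequal(correlation_filter(X2, 0.8, priority = c("a", "b", "c")),
                  c("a", "c"))
  # strictly below the threshold: both kept
  r <- 0.79
  y2 <- r * scale(base)[, 1] + sqrt(1 - r^2) * scale(resid(lm(rnorm(n) ~ base)))[, 1]
  X3 <- cbind(p = scale(base)[, 1], q = y2)
  expect_setequal(correlation_filter(X3, threshold = 0.8), c("p", "q"))
  expect_error(correlation_filter(X, threshold = 0), "config")
})

test_that("no retained pair correlates above the threshold (post-condition)", {
  set.seed(4)
  n <- 200
  Z <- matrix(rnorm(n * 6), n, 6)
  X <- cbind(Z, Z[, 1:3] + matrix(rnorm(n * 3, 0, 0.2), n, 3))
  colnames(X) <- paste0("v", 1:9)
  for (mode in c("ranked", "random")) {
    kept <- correlation_filter(X, threshold = 0.8, mode = mode, seed = 9)
    cm <- cor(X[, kept]); diag(cm) <- 0
    expect_lt(max(abs(cm)), 0.8)
  }
  # random mode is seeded
  k1 <- correlation_filter(X, 0.8, mode = "random", seed = 5)
  k2 <- correlation_filter(X, 0.8, mode = "random", seed = 5)
  expect_identical(k1, k2)
})

test_that("Spearman/Ward clustering retains one representative per cluster", {
  set.seed(5)
  n <- 2000
  a <- rnorm(n)
  X <- cbind(a1 = a, a2 = a, indep = rnorm(n))
  expect_warning(cl <- spearman_ward_cluster(cbind(X, const = rep(1, n)),
                                             priority = c("a1", "a2",
                                                          "indep", "const")),
                 "constant")
  expect_equal(cl$assignment[["a1"]], cl$assignment[["a2"]])
  expect_false(cl$assignment[["a1"]] == cl$assignment[["indep"]])
  expect_true("a1" %in% cl$retained)       # best priority represents
  expect_false("a2" %in% cl$retained)
  expect_true("indep" %in% cl$retained)
  # exactly one representative per cluster, none lost
  expect_equal(length(cl$retained), length(unique(cl$assignment)))
  expect_equal(sort(unique(cl$assignment[cl$retained])),
               sort(unique(cl$assignment)))
})

test_that("independent columns split at the default Ward cut", {
  set.seed(6)
  X <- cbind(u = rnorm(2000), v = rnorm(2000))
  cl <- spearman_ward_cluster(X, linkage_threshold = 0.5)
  expect_equal(length(unique(cl$assignment)), 2)
})
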