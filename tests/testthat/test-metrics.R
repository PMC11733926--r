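# brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized code
ref_mae <- function(y, p) { s <- 0; for (i in seq_along(y)) s <- s + abs(y[i] - p[i]); s / length(y) }
ref_mse <- function(y, p) { s <- 0; for (i in seq_along(y)) s <- s + (y[i] - p[i])^2; s / length(y) }
ref_r <- function(y, p) {
  my <- sum(y) / length(y); mp <- sum(p) / length(p)
  num <- sum((y - my) * (p - mp))
  num / sqrt(sum((y - my)^2) * sum((p - mp)^2))
}
ref_auc <- function(lab, sc) {
  pos <- which(lab == 1); neg <- which(lab == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
  }
  tot / (length(pos) * length(neg))
}

test_that("regression errors match hand-computed values", {
  expect_equal(mae(c(0, 0), c(1, 3)), 2)
  expect_equal(mse(c(0, 0), c(1, 3)), 5)
  expect_equal(rmse(c(0, 0), c(1, 3)), sqrt(5))
  expect_equal(mae(1:5, 1:5), 0)
  expect_error(mae(1:3, 1:2), "length")
})

test_that("correlation metrics behave at the extremes and in between", {
  y <- c(1, 2, 3)
  expect_equal(pearson_r(y, 2 * y), 1)
  expect_equal(pearson_r(y, -y), -1)
  expect_equal(r_squared(y, -y), 1)
  expect_equal(pearson_r(y, c(1, 2, 4)), ref_r(y, c(1, 2, 4)))
  expect_error(pearson_r(y, rep(1, 3)), "zero variance")
})

test_that("classification metrics follow the confusion-count formulas", {
  m <- classification_metrics(list(TP = 2, FP = 1, FN = 1, TN = 6))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 0.8)
  perfect <- classification_metrics(list(TP = 5, FP = 0, FN = 0, TN = 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  degen <- classification_metrics(list(TP = 0, FP = 0, FN = 2, TN = 3))
  expect_equal(degen$precision, 0)
  expect_true("precision" %in% degen$degenerate)
})

test_that("AUC equals the pairwise Mann-Whitney statistic", {
  expect_equal(auc_roc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auc_roc(c(0, 1, 0, 1), c(0.5, 0.5, 0.5, 0.5)), 0.5)
  expect_equal(auc_roc(c(0, 0, 1), c(1, 2, 3)), 1)
  expect_error(auc_roc(c(1, 1), c(0.3, 0.4)), "both classes")
})

test_that("metrics agree with brute force on random instances", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    y <- rnorm(n); p <- rnorm(n)
    expect_equal(mae(y, p), ref_mae(y, p), tolerance = 1e-12)
    expect_equal(mse(y, p), ref_mse(y, p), tolerance = 1e-12)
    expect_equal(pearson_r(y, p), ref_r(y, p), tolerance = 1e-12)
    lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    sc <- round(rnorm(n), 1)  # force ties
    expect_equal(auc_roc(lab, sc), ref_auc(lab, sc), tolerance = 1e-12)
  }
})

test_that("metric invariances hold", {
  set.seed(5)
  y <- rnorm(30); p <- rnorm(30)
  expect_equal(rmse(y, p)^2, mse(y, p), tolerance = 1e-14)
  expect_lte(mae(y, p), rmse(y, p))  # Jensen
  lab <- sample(0:1, 30, replace = TRUE); lab[1:2] <- c(0, 1)
  sc <- rnorm(30)
  expect_equal(auc_roc(lab, sc), auc_roc(lab, exp(sc)))   # monotone invariant
  expect_equal(pearson_r(y, p), pearson_r(2 * y + 3, 0.5 * p - 1))
})

test_that("multi-task reports average over tasks and skip missing labels", {
  set.seed(8)
  yt <- cbind(t1 = c(0, 1, NA, 1, 0, 1), t2 = c(1, 0, 1, NA, 0, 1))
  pp <- matrix(runif(12), 6, 2)
  rep <- metrics_report(yt, pp, "classification")
  a1 <- auc_roc(yt[!is.na(yt[, 1]), 1], pp[!is.na(yt[, 1]), 1])
  a2 <- auc_roc(yt[!is.na(yt[, 2]), 2], pp[!is.na(yt[, 2]), 2])
  expect_equal(rep$auc, mean(c(a1, a2)))
  expect_length(rep$per_task, 2)
})
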