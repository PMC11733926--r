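test_that("F statistics match the closed form and a direct ANOVA", {
  # closed form: r = 0.5, n = 102 -> F = 0.25*100/0.75
  n <- 102
  set.seed(1)
  x <- rnorm(n)
  # build y with an exact sample correlation of 0.5 to x
  e <- residuals(lm(rnorm(n) ~ x))
  xs <- scale(x)[, 1]; es <- scale(e)[, 1]
  y <- 0.5 * xs + sqrt(1 - 0.25) * es
  sc <- anova_f_scores(cbind(f = x), y)
  expect_equal(sc$f_stat, 0.25 * 100 / 0.75, tolerance = 1e-9)

  # direct one-way ANOVA decomposition on a discrete regressor
  g <- rep(c(0, 1, 2), each = 20)
  set.seed(2)
  yy <- g * 0.7 + rnorm(60)
  # regression F on a single predictor equals MSR/MSE of the linear fit
  fit <- lm(yy ~ g)
  msr <- sum((fitted(fit) - mean(yy))^2) / 1
  mse_ <- sum(residuals(fit)^2) / (60 - 2)
  expect_equal(anova_f_scores(cbind(g = g), yy)$f_stat, msr / mse_,
               tolerance = 1e-9)
})

test_that("F scores normalize to 1 at the top and flag degenerate columns", {
  set.seed(3)
  X <- cbind(a = rnorm(50), b = rnorm(50), const = rep(2, 50))
  y <- X[, "a"] + rnorm(50, 0, 0.1)
  sc <- anova_f_scores(X, y)
  expect_equal(max(sc$f_stat_normalized), 1)
  expect_equal(sc$feature[which.max(sc$f_stat_normalized)], "a")
  expect_equal(sc$f_stat[sc$feature == "const"], 0)
  expect_true(sc$degenerate[sc$feature == "const"])
  # scale-free: rescaling a column leaves F unchanged
  X2 <- X; X2[, "a"] <- X2[, "a"] * 1000
  expect_equal(anova_f_scores(X2, y)$f_stat, sc$f_stat, tolerance = 1e-9)
})

test_that("k-NN mutual information identifies dependence and independence", {
  set.seed(4)
  n <- 1000
  x <- rnorm(n)
  X <- cbind(same = x, indep = rnorm(n))
  mi <- knn_mutual_information(X, x, k = 3, seed = 1)
  expect_equal(mi$mi_normalized[mi$feature == "same"], 1)
  expect_lt(abs(mi$mi[mi$feature == "indep"]), 0.05)
  expect_true(all(mi$mi >= 0))
  expect_error(knn_mutual_information(X[1:3, ], x[1:3], k = 5), "config")
})

test_that("MI calibration: near-zero mean on independent data over seeds", {
  mis <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(400); y <- rnorm(400)
    knn_mutual_information(cbind(v = x), y, k = 3, seed = s)$mi
  }, numeric(1))
  expect_lt(mean(abs(mis)), 0.02)
})

test_that("GBDT gain concentrates on the generating feature", {
  set.seed(6)
  n <- 500
  X <- cbind(x1 = rnorm(n),
             matrix(rnorm(n * 20), n, 20,
                    dimnames = list(NULL, paste0("z", 1:20))),
             const = rep(1, n))
  y <- X[, "x1"]
  g <- gbdt_gain_ranking(X, y, "regression", n_trees = 100, seed = 1)
  expect_equal(g$feature[g$gain_rank == 1], "x1")
  expect_equal(g$gain[g$feature == "const"], 0)
  expect_setequal(g$gain_rank, seq_len(ncol(X)))
  g2 <- gbdt_gain_ranking(X, y, "regression", n_trees = 100, seed = 1)
  expect_identical(g, g2)  # seeded determinism
  expect_error(gbdt_gain_ranking(cbind(a = c(1, NA)), c(1, 2)), "non-finite")
})

test_that("selection policy takes the gain top and the statistical union", {
  d <- planted_design()
  sc <- feature_scores(d$X, d$y, n_trees = 100, seed = 2)
  top5 <- select_relevant(sc, n_gain = 5, n_stat = 0)
  expect_length(top5, 5)
  expect_setequal(top5, sc$feature[order(sc$gain_rank)][1:5])
  # a high-MI feature outside the gain top joins through the union
  sc2 <- sc
  low <- sc2$feature[which.max(sc2$gain_rank)]
  sc2$mi_normalized[sc2$feature == low] <- 0.99
  got <- select_relevant(sc2, n_gain = 3, n_stat = 5, min_normalized = 0.9)
  expect_true(low %in% got)
})

test_that("incremental subset curves flatten once the signal is included", {
  set.seed(9)
  n <- 400
  X <- cbind(inf = rnorm(n),
             matrix(rnorm(n * 60), n, 60,
                    dimnames = list(NULL, paste0("n", 1:60))))
  y <- 2 * X[, "inf"] + rnorm(n, 0, 0.3)
  ranking <- c("inf", paste0("n", 1:60))
  cur <- incremental_subset_curve(X, y, ranking, step = 20,
                                  train_idx = 1:300, val_idx = 301:400,
                                  n_trees = 100, seed = 1)
  expect_setequal(unique(cur$size), c(20, 40, 60, 61))
  v <- cur[cur$partition == "validation", ]
  expect_lt(v$rmse[v$size == 20], 1.25 * v$rmse[v$size == max(v$size)])
  expect_error(incremental_subset_curve(X, y, ranking, step = 0,
                                        train_idx = 1:300,
                                        val_idx = 301:400), "config")
})
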