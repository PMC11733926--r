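test_that("the coarse grid scans every point and brackets the optimum", {
  obj <- function(p) (p$learning_rate - 0.05)^2 + (p$num_leaves - 31)^2 / 1e4
  g <- coarse_grid_search(grid = list(learning_rate = c(0.01, 0.05, 0.1),
                                      num_leaves = c(15, 31, 63)),
                          objective = obj)
  expect_equal(nrow(g$evaluations), 9)
  expect_equal(g$best_point$learning_rate, 0.05)
  expect_equal(g$region$learning_rate$bounds, c(0.01, 0.1))
  expect_equal(g$region$num_leaves$bounds, c(15, 63))
  single <- coarse_grid_search(grid = list(learning_rate = 0.07),
                               objective = function(p) 1)
  expect_equal(single$best_point$learning_rate, 0.07)
  expect_error(coarse_grid_search(grid = list(), objective = obj), "config")
})

test_that("Bayesian optimization minimizes an analytic objective", {
  sp <- hyperparameter_space(x = c(0, 5))
  res <- bayesian_optimize(space = sp, n_calls = 30, seed = 4,
                           objective = function(p) (p$x - 2)^2)
  expect_lt(abs(res$best_point$x - 2), 0.1)
  expect_true(all(diff(res$best_so_far) <= 1e-12))
  res2 <- bayesian_optimize(space = sp, n_calls = 30, seed = 4,
                            objective = function(p) (p$x - 2)^2)
  expect_identical(res$evaluations, res2$evaluations)
  expect_error(bayesian_optimize(space = sp, n_calls = 3,
                                 objective = function(p) 0), "config")
  expect_error(hyperparameter_space(), "empty")
  expect_error(hyperparameter_space(x = list(type = "real",
                                             bounds = c(1, Inf))), "bounds")
})

test_that("embedding concatenation is additive, ordered and collision-safe", {
  X <- matrix(0, 5, 129, dimnames = list(NULL, paste0("f", 1:129)))
  E <- matrix(1, 5, 300, dimnames = list(NULL, paste0("Mol2Vec-", 0:299)))
  XE <- attach_embeddings(X, E)
  expect_equal(ncol(XE), 429)
  expect_equal(colnames(XE), c(colnames(X), colnames(E)))
  expect_identical(attach_embeddings(X, NULL), X)
  expect_identical(attach_embeddings(X, E[, 0]), X)
  bad <- E; colnames(bad)[1] <- "f1"
  expect_error(attach_embeddings(X, bad), "collide")
  expect_error(attach_embeddings(X[1:3, ], E), "alignment")
})

test_that("the final model is deterministic and fits clean structure", {
  set.seed(6)
  n <- 300
  X <- cbind(a = rbinom(n, 1, 0.4), b = rbinom(n, 2, 0.3),
             c = rbinom(n, 1, 0.2))
  y <- 2 * X[, "a"] - X[, "b"] + 0.5 * X[, "c"]
  m1 <- train_final_model(X, y, seed = 7)
  m2 <- train_final_model(X, y, seed = 7)
  probe <- X[1:50, ]
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_gte(r_squared(y, predict(m1, X)), 0.99)  # noiseless target
  expect_warning(mc <- train_final_model(X, rep(2, n)), "constant")
  expect_equal(unique(round(predict(mc, probe), 6)), 2)
})

test_that("prediction aligns columns by name and validates the schema", {
  set.seed(7)
  X <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + rnorm(100, 0, 0.1)
  m <- train_final_model(X, y, seed = 1)
  p0 <- predict(m, X)
  expect_length(p0, 100)
  expect_identical(predict(m, X[, c("c", "a", "b")]), p0)
  expect_error(predict(m, X[, c("a", "b")]), "schema")
})

test_that("classification models emit calibrated-range probabilities", {
  set.seed(8)
  n <- 400
  X <- cbind(u = rnorm(n), v = rnorm(n))
  pr <- 1 / (1 + exp(-2 * X[, "u"]))
  lab <- rbinom(n, 1, pr)
  m <- train_final_model(X, lab, task_type = "classification", seed = 2)
  p <- predict(m, X)
  expect_true(all(p >= 0 & p <= 1))
  cls <- predict(m, X, type = "class")
  expect_true(all(cls %in% c(0, 1)))
  expect_gt(auc_roc(lab, p), 0.8)
})

test_that("models round-trip through disk with identical predictions", {
  set.seed(9)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- X[, 1] - X[, 2] + rnorm(60, 0, 0.1)
  m <- train_final_model(X, y, best_point = list(n_trees = 80,
                                                 learning_rate = 0.1),
                         seed = 3)
  d <- withr::local_tempdir()
  save_gbfs_model(m, d)
  m2 <- load_gbfs_model(d)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_identical(m2$feature_names, m$feature_names)
})
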