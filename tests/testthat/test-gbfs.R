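# end-to-end workflow behavior on a small synthetic study (the shared
# small_fit() fixture is defined in helper-fixtures.R)

test_that("the workflow produces a coherent manifest and S3 surface", {
  fit <- cached("small_fit", small_fit())
  counts <- fit$manifest$stage_counts
  # selection stages only ever shrink the pool; engineering is the single
  # counted increase
  expect_lte(counts["after_correlation_filter"], counts["after_engineering"])
  expect_lte(counts["after_clustering"], counts["after_correlation_filter"])
  expect_lte(counts["final"], counts["after_clustering"])
  expect_equal(unname(counts["after_engineering"]),
               unname(counts["selected"] + counts["engineered_added"]))
  expect_equal(fit$manifest$test_accesses, 1L)

  expect_output(print(fit), "GBFS")
  expect_output(summary(fit), "Top features")
  co <- coef(fit)
  expect_setequal(co$feature, fit$model$feature_names)
  expect_true(all(diff(co$gain) <= 0))
  expect_length(residuals(fit), length(fitted(fit)))
  expect_s3_class(fit$scores, "data.frame")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("the workflow is reproducible end to end under one master seed", {
  f1 <- cached("small_fit", small_fit())
  f2 <- small_fit()
  expect_identical(f1$manifest$selection_hash, f2$manifest$selection_hash)
  expect_identical(f1$final_features, f2$final_features)
  expect_identical(f1$test_metrics$rmse, f2$test_metrics$rmse)
  expect_identical(f1$fitted_values, f2$fitted_values)
})

test_that("GBFS and GBFS-Mol2Vec share all selection artifacts", {
  f <- cached("small_fit", small_fit())
  fm <- cached("small_fit_m2v", small_fit(mol2vec = TRUE))
  expect_identical(fm$manifest$selection_hash, f$manifest$selection_hash)
  expect_identical(fm$final_features, f$final_features)
  expect_identical(fm$selected, f$selected)
  # they diverge only at the embedding concatenation
  expect_equal(length(fm$model$feature_names),
               length(f$final_features) + fm$embedding$dimension)
  expect_equal(unname(fm$manifest$stage_counts["model_width"]),
               length(f$final_features) + 12)
  expect_equal(fm$manifest$test_accesses, 1L)
})

test_that("fitted workflows predict on new molecules end to end", {
  fit <- cached("small_fit", small_fit())
  new_tab <- generate_molecules(10, seed = 901)
  p <- predict(fit, new_tab)
  expect_length(p, 10)
  expect_true(all(is.finite(p)))
  # SMILES input takes the same path
  p2 <- predict(fit, new_tab$smiles)
  expect_equal(unname(p2), unname(p))
})

test_that("the workflow runs under a scaffold split", {
  tab <- gen_table(120, seed = 42)
  X <- gen_features(120, seed = 42)
  tab2 <- plant_regression_target(tab, X, c(MolWt = 1), noise_sd = 0.3,
                                  seed = 6)
  cfg <- gbfs_config(split = "scaffold", n_gain = 10, n_stat = 0,
                     rank_trees = 40, rfe_trees = 20, rfe_folds = 3,
                     rfe_step = 3, optimize = FALSE)
  fit <- suppressWarnings(gbfs(tab2, features = X, config = cfg, seed = 8))
  te <- test_indices(fit$split, peek = TRUE)
  scaf <- murcko_scaffold(tab2$smiles)
  # train and test share no scaffold (ring-free group aside, which the
  # greedy fill puts in train)
  common <- intersect(setdiff(scaf[fit$split$train], ""),
                      setdiff(scaf[te], ""))
  expect_length(common, 0)
  expect_true(is.finite(fit$test_metrics$rmse))
})

test_that("the workflow handles binary classification end to end", {
  tab <- gen_table(120, seed = 42)
  X <- gen_features(120, seed = 42)
  tabc <- plant_classification_target(tab, X, c(`fr-COO` = 4), seed = 9)
  cfg <- gbfs_config(n_gain = 10, n_stat = 0, rank_trees = 40,
                     rfe_trees = 20, rfe_folds = 3, rfe_step = 3,
                     optimize = FALSE)
  fit <- gbfs(tabc, features = X, config = cfg, seed = 10)
  expect_equal(fit$task, "classification")
  expect_true(fit$test_metrics$auc >= 0.5)
  p <- predict(fit, X[1:5, ])
  expect_true(all(p >= 0 & p <= 1))
})

test_that("Mol2Vec fits embed new molecules at prediction time", {
  fm <- cached("small_fit_m2v", small_fit(mol2vec = TRUE))
  new_tab <- generate_molecules(6, seed = 902)
  p <- suppressWarnings(predict(fm, new_tab))
  expect_length(p, 6)
  expect_true(all(is.finite(p)))
})

test_that("artifact directories capture every stage report", {
  fit <- cached("small_fit", small_fit())
  d <- withr::local_tempdir()
  write_gbfs_artifacts(fit, d)
  expect_true(all(file.exists(file.path(d, c(
    "feature_scores.csv", "selected_features.txt", "final_features.txt",
    "cluster_assignment.json", "permutation_importance.csv",
    "rfe_report.json", "test_metrics.json", "manifest.json", "split.json")))))
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 77)
  m <- load_gbfs_model(file.path(d, "model"))
  expect_identical(m$feature_names, fit$model$feature_names)
})
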