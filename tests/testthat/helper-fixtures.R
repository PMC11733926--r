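# Shared fixtures, built in code and cached for the session so expensive
# featurizations run once across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# a tiny hand-picked molecule table with known chemistry
tiny_table <- function() {
  cached("tiny_table", suppressMessages(molecule_table(
    c("CCO", "CC(=O)O", "Oc1ccccc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
      "c1ccccc1", "CCN", "O"),
    targets = data.frame(y = c(0.2, -1.1, 0.6, 1.9, 1.2, -0.3, -2.5)))))
}

# small generated table + lean feature matrix (graph blocks only, fast)
lean_blocks <- function() {
  list("physchem_descriptors", "element_fractions", "element_property_stats")
}

gen_table <- function(n = 120, seed = 42) {
  cached(paste0("gen_table_", n, "_", seed),
         generate_molecules(n, seed = seed))
}

gen_features <- function(n = 120, seed = 42) {
  cached(paste0("gen_features_", n, "_", seed),
         featurize(gen_table(n, seed), blocks = lean_blocks(), clean = FALSE))
}

# a small but complete workflow fit, shared across test files
small_fit <- function(mol2vec = FALSE, seed = 77) {
  tab <- gen_table(120, seed = 42)
  X <- gen_features(120, seed = 42)
  tab2 <- plant_regression_target(tab, X, c(`fr-COO` = -1, MolWt = 1),
                                  noise_sd = 0.2, seed = 5)
  cfg <- gbfs_config(n_gain = 15, n_stat = 5, rank_trees = 60,
                     rfe_trees = 30, rfe_folds = 3, rfe_step = 2,
                     optimize = FALSE, mol2vec_dimension = 12,
                     mol2vec_epochs = 2, mol2vec_min_count = 1)
  gbfs(tab2, features = X, config = cfg, mol2vec = mol2vec, seed = seed)
}

# random regression design with planted structure for selection tests
planted_design <- function(n = 400, p_noise = 30, seed = 7) {
  cached(paste0("planted_", n, "_", p_noise, "_", seed), {
    set.seed(seed)
    X <- cbind(matrix(rnorm(n * 3), n, 3,
                      dimnames = list(NULL, c("inf1", "inf2", "inf3"))),
               matrix(rnorm(n * p_noise), n, p_noise,
                      dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
    y <- X[, "inf1"] + 0.8 * X[, "inf2"] - 0.6 * X[, "inf3"] +
      rnorm(n, 0, 0.1)
    list(X = X, y = y)
  })
}
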