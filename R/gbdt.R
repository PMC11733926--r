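# Thin wrapper around the gradient-boosted tree engine (xgboost). All fits
# in the package go through here so that seeds, thread counts and the
# leaf-wise growth policy are consistent and reproducible.

.gbdt_params <- function(task_type, learning_rate = 0.05, num_leaves = 31,
                         min_child_samples = 5, subsample = 1,
                         colsample = 1, reg_alpha = 0, reg_lambda = 1) {
  list(objective = if (task_type == "classification") "binary:logistic"
       else "reg:squarederror",
       eta = learning_rate,
       max_depth = 0L,
       max_leaves = as.integer(num_leaves),
       grow_policy = "lossguide",
       tree_method = "hist",
       min_child_weight = min_child_samples,
       subsample = subsample,
       colsample_bytree = colsample,
       alpha = reg_alpha,
       lambda = reg_lambda,
       nthread = 1L)
}

# fit a GBDT; feature names are taken from X's columns
.fit_gbdt <- function(X, y, task_type, n_trees = 500, params = NULL,
                      seed = 1L, weights = NULL) {
  if (is.null(params)) params <- .gbdt_params(task_type)
  params$seed <- as.integer(seed %% 2147483647)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, weight = weights,
                                 nthread = 1)
  .with_seed(seed,
             xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = as.integer(n_trees), verbose = 0))
}

.predict_gbdt <- function(model, X) {
  stats::predict(model, xgboost::xgb.DMatrix(as.matrix(X), nthread = 1))
}

# total loss-reduction (gain) attributed to each feature over the ensemble;
# features never split on have gain 0
.gbdt_total_gain <- function(model, feature_names) {
  dt <- tryCatch(xgboost::xgb.model.dt.tree(model = model),
                 error = function(e) NULL)
  gain <- stats::setNames(numeric(length(feature_names)), feature_names)
  if (is.null(dt)) return(gain)
  gcol <- intersect(c("Gain", "Quality"), colnames(dt))[1]
  fcol <- "Feature"
  splits <- dt[[fcol]] != "Leaf"
  agg <- tapply(dt[[gcol]][splits], dt[[fcol]][splits], sum)
  common <- intersect(names(agg), feature_names)
  gain[common] <- agg[common]
  gain
}
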