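# Subset refinement: permutation feature importance and cross-validated
# recursive feature elimination (RFE) with negative RMSE as the default
# performance metric.

# score convention: larger is better
.eval_metric <- function(metric, y, pred) {
  switch(metric,
         neg_rmse = -rmse(y, pred),
         neg_mae = -mae(y, pred),
         r2 = r_squared(y, pred),
         auc = auc_roc(y, pred),
         stop("config error: unknown metric '", metric, "'", call. = FALSE))
}

#' Permutation feature importance
#'
#' Shuffles one feature column at a time (\code{n_repeats} seeded shuffles
#' per feature) and reports the mean and standard deviation of the drop in
#' the model's score (baseline score minus permuted score; positive drops
#' mean the model relies on the feature).
#'
#' @param model fitted GBDT (from \code{\link{train_final_model}} or the
#'   internal fitter).
#' @param X feature matrix the model was fitted on (columns = model features).
#' @param y target vector.
#' @param metric "neg_rmse", "neg_mae", "r2" or "auc".
#' @param n_repeats shuffles per feature (default 10).
#' @param seed integer seed.
#' @return data.frame with feature, mean_drop, std_drop, n_repeats.
#' @export
permutation_importance <- function(model, X, y, metric = "neg_rmse",
                                   n_repeats = 10, seed = 1L) {
  booster <- if (inherits(model, "gbfs_model")) model$booster else model
  base <- .eval_metric(metric, y, .predict_gbdt(booster, X))
  n <- nrow(X)
  perms <- .with_seed(seed, {
    lapply(seq_len(ncol(X) * n_repeats), function(i) sample.int(n))
  })
  mean_drop <- std_drop <- numeric(ncol(X))
  k <- 0
  for (j in seq_len(ncol(X))) {
    drops <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      k <- k + 1
      Xp <- X
      Xp[, j] <- X[perms[[k]], j]
      drops[r] <- base - .eval_metric(metric, y, .predict_gbdt(booster, Xp))
    }
    mean_drop[j] <- mean(drops)
    std_drop[j] <- stats::sd(drops)
  }
  data.frame(feature = colnames(X), mean_drop = mean_drop,
             std_drop = std_drop, n_repeats = n_repeats,
             stringsAsFactors = FALSE)
}

#' Cross-validated recursive feature elimination
#'
#' Greedy backward elimination: at each round the GBDT is refitted on the
#' surviving features and the lowest-gain \code{step} feature(s) are
#' removed; at every visited size the k-fold cross-validated score is
#' recorded. The optimal size maximizes the mean CV score (ties broken
#' toward the smallest subset), and the selected features are the
#' survivors at that size — so with step 1 the selected set is nested in
#' every earlier visited set.
#'
#' @param X feature matrix.
#' @param y target vector.
#' @param task_type "regression" or "classification".
#' @param cv_folds number of folds (default 10).
#' @param metric CV metric, larger is better (default "neg_rmse").
#' @param step features removed per round (default 1).
#' @param min_size smallest subset size visited (default 1).
#' @param n_trees trees per fit (default 200; elimination signal and CV
#'   share the fit budget).
#' @param seed integer seed (fold assignment and fits).
#' @return list with \code{sizes}, \code{cv_mean}, \code{cv_sd},
#'   \code{optimal_size}, \code{selected_features}, \code{trajectory}
#'   (list of surviving sets per visited size).
#' @export
recursive_feature_elimination <- function(X, y, task_type = "regression",
                                          cv_folds = 10, metric = "neg_rmse",
                                          step = 1, min_size = 1,
                                          n_trees = 200, seed = 1L) {
  if (cv_folds < 2) stop("config error: cv_folds must be >= 2", call. = FALSE)
  if (step < 1) stop("config error: step must be >= 1", call. = FALSE)
  if (ncol(X) < step) {
    stop("config error: matrix narrower than the elimination step",
         call. = FALSE)
  }
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(X)
  folds <- .with_seed(.derive_seed(seed, 1), sample(rep(seq_len(cv_folds),
                                                        length.out = n)))
  surviving <- colnames(X)
  sizes <- integer(0); cv_mean <- cv_sd <- numeric(0)
  trajectory <- list()
  round_i <- 0
  repeat {
    round_i <- round_i + 1
    s <- length(surviving)
    scores <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      model <- .fit_gbdt(X[tr, surviving, drop = FALSE], y[tr], task_type,
                         n_trees = n_trees,
                         seed = .derive_seed(seed, 100 + round_i * 17 + f))
      pred <- .predict_gbdt(model, X[!tr, surviving, drop = FALSE])
      scores[f] <- .eval_metric(metric, y[!tr], pred)
    }
    sizes <- c(sizes, s)
    cv_mean <- c(cv_mean, mean(scores))
    cv_sd <- c(cv_sd, stats::sd(scores))
    trajectory[[length(trajectory) + 1]] <- surviving
    if (s <= min_size) break
    full <- .fit_gbdt(X[, surviving, drop = FALSE], y, task_type,
                      n_trees = n_trees,
                      seed = .derive_seed(seed, 500 + round_i))
    gain <- .gbdt_total_gain(full, surviving)
    ord <- order(gain, rev(seq_along(gain)))  # lowest gain out first
    n_drop <- min(step, s - min_size)
    surviving <- setdiff(surviving, surviving[ord[seq_len(n_drop)]])
  }
  best <- which(cv_mean == max(cv_mean))
  best <- best[which.min(sizes[best])]
  list(sizes = sizes, cv_mean = cv_mean, cv_sd = cv_sd,
       optimal_size = sizes[best],
       selected_features = trajectory[[best]],
       trajectory = trajectory, metric = metric)
}
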