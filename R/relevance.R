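# Feature-relevance ranking: GBDT loss-reduction gain, regression
# F-statistics derived from Pearson correlation, k-nearest-neighbour mutual
# information, incremental feature-subset performance curves, and the
# selection policy that merges the gain and statistical rankings.

#' GBDT gain ranking
#'
#' Trains a gradient-boosted decision-tree ensemble on all features and
#' scores each feature by the total objective loss reduction attributed to
#' splits on it. Ties are broken deterministically (column order).
#'
#' @param X numeric feature matrix (finite entries).
#' @param y target vector.
#' @param task_type "regression" or "classification".
#' @param n_trees,params ensemble size and engine parameters
#'   (defaults: 500 trees, learning rate 0.05, 31 leaves).
#' @param seed integer seed; fixed seed gives an identical ranking.
#' @return data.frame feature score table with columns \code{feature},
#'   \code{gain}, \code{gain_rank}.
#' @export
gbdt_gain_ranking <- function(X, y, task_type = "regression", n_trees = 500,
                              params = NULL, seed = 1L) {
  .check_finite(X)
  keep <- !is.na(y)
  model <- .fit_gbdt(X[keep, , drop = FALSE], y[keep], task_type,
                     n_trees = n_trees, params = params, seed = seed)
  gain <- .gbdt_total_gain(model, colnames(X))
  ord <- order(-gain, seq_along(gain))
  rank <- integer(length(gain)); rank[ord] <- seq_along(gain)
  data.frame(feature = colnames(X), gain = unname(gain), gain_rank = rank,
             stringsAsFactors = FALSE)
}

#' ANOVA regression F-statistics per feature
#'
#' For each feature, the Pearson correlation r with the target is
#' transformed into the one-way-ANOVA regression F-statistic
#' F = r^2 (n - 2) / (1 - r^2) with (1, n - 2) degrees of freedom.
#' Scores are additionally normalized by the maximum so the top feature
#' scores exactly 1. Zero-variance features get F = 0 and are flagged.
#'
#' @param X numeric feature matrix.
#' @param y numeric target (for classification tasks the 0/1 labels give
#'   the point-biserial analogue).
#' @return data.frame with \code{feature}, \code{f_stat},
#'   \code{f_stat_normalized}, \code{degenerate}.
#' @export
anova_f_scores <- function(X, y) {
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  stopifnot(n > 2)
  sds <- apply(X, 2, stats::sd)
  degenerate <- !is.finite(sds) | sds == 0 | stats::sd(y) == 0
  r <- rep(0, ncol(X))
  if (any(!degenerate)) {
    r[!degenerate] <- as.vector(stats::cor(X[, !degenerate, drop = FALSE], y))
  }
  r2 <- pmin(r^2, 1 - 1e-15)
  f <- r2 * (n - 2) / (1 - r2)
  f[degenerate] <- 0
  fmax <- max(f)
  data.frame(feature = colnames(X), f_stat = f,
             f_stat_normalized = if (fmax > 0) f / fmax else f,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

# Kraskov-Stoegbauer-Grassberger estimator (algorithm 1) for continuous
# x, y; Chebyshev balls in the joint space, digamma correction from the
# marginal neighbour counts.
.ksg_mi <- function(x, y, k) {
  n <- length(x)
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dj <- pmax(dx, dy)
  diag(dj) <- Inf
  eps <- apply(dj, 1, function(row) sort(row, partial = k)[k])
  nx <- rowSums(dx < eps) - 1L
  ny <- rowSums(dy < eps) - 1L
  digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
}

# discrete-target variant (per-class neighbourhoods)
.ksg_mi_discrete <- function(x, y, k) {
  n <- length(x)
  dx <- abs(outer(x, x, "-"))
  diag(dx) <- Inf
  eps <- numeric(n); nall <- numeric(n); nyc <- numeric(n)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    kc <- min(k, length(idx) - 1)
    if (kc < 1) { eps[idx] <- Inf; nyc[idx] <- length(idx); next }
    sub <- dx[idx, idx, drop = FALSE]
    eps[idx] <- apply(sub, 1, function(row) sort(row, partial = kc)[kc])
    nyc[idx] <- length(idx)
  }
  m <- rowSums(dx < eps)
  keep <- is.finite(eps)
  digamma(n) + digamma(k) - mean(digamma(nyc[keep])) -
    mean(digamma(m[keep] + 1))
}

#' k-nearest-neighbour mutual information per feature
#'
#' Estimates the mutual information between each feature and the target
#' with the entropy estimator based on k-nearest-neighbour distances
#' (continuous targets) or its per-class variant (0/1 targets). A tiny
#' seeded jitter breaks ties in discrete-valued columns; negative
#' estimates are clipped to 0 and scores are normalized by the maximum.
#'
#' @param X numeric feature matrix.
#' @param y target vector.
#' @param k neighbour count (default 3).
#' @param seed seed for the tie-breaking jitter.
#' @param discrete_y treat y as class labels (default: TRUE when y only
#'   takes values 0/1).
#' @return data.frame with \code{feature}, \code{mi}, \code{mi_normalized}.
#' @export
knn_mutual_information <- function(X, y, k = 3L, seed = 1L,
                                   discrete_y = NULL) {
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  if (k < 1 || k >= n) stop("config error: need 1 <= k < n", call. = FALSE)
  if (is.null(discrete_y)) discrete_y <- all(y %in% c(0, 1))
  mi <- numeric(ncol(X))
  jit <- .with_seed(seed, {
    lapply(seq_len(ncol(X) + 1), function(j) stats::rnorm(n))
  })
  ys <- as.vector(scale(y))
  if (!discrete_y) {
    ys <- ys + 1e-10 * jit[[ncol(X) + 1]]
  }
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    if (stats::sd(xj) == 0) { mi[j] <- 0; next }
    xs <- as.vector(scale(xj)) + 1e-10 * jit[[j]]
    mi[j] <- if (discrete_y) .ksg_mi_discrete(xs, y, k)
    else .ksg_mi(xs, ys, k)
  }
  mi <- pmax(mi, 0)
  mmax <- max(mi)
  data.frame(feature = colnames(X), mi = mi,
             mi_normalized = if (mmax > 0) mi / mmax else mi,
             stringsAsFactors = FALSE)
}

#' Combined feature score table
#'
#' Runs the gain ranking, F-statistics and mutual information on the same
#' matrix and merges them into a single feature score table.
#'
#' @inheritParams gbdt_gain_ranking
#' @param mi_k neighbour count for the MI estimator.
#' @return data.frame with all score columns.
#' @export
feature_scores <- function(X, y, task_type = "regression", n_trees = 500,
                           params = NULL, mi_k = 3L, seed = 1L) {
  g <- gbdt_gain_ranking(X, y, task_type, n_trees, params, seed)
  f <- anova_f_scores(X, y)
  m <- knn_mutual_information(X, y, k = mi_k, seed = seed)
  out <- merge(merge(g, f, by = "feature", sort = FALSE), m,
               by = "feature", sort = FALSE)
  out[match(colnames(X), out$feature), , drop = FALSE]
}

#' Incremental feature-subset performance curve
#'
#' Recursively trains GBDT models on the top-1..k ranked features (sizes
#' step, 2 step, ...) and records MAE, RMSE and R^2 on the training and a
#' held-out validation partition, reproducing the convergence-curve view
#' of the selection process.
#'
#' @param X feature matrix.
#' @param y regression target.
#' @param ranking character vector of features in decreasing relevance.
#' @param step subset-size increment (> 0).
#' @param train_idx,val_idx row indices of the two partitions.
#' @param n_trees trees per fit (default 200 for tractable curves).
#' @param seed seed.
#' @return data.frame with columns size, partition, mae, rmse, r2.
#' @export
incremental_subset_curve <- function(X, y, ranking, step = 5,
                                     train_idx, val_idx,
                                     n_trees = 200, seed = 1L) {
  if (step <= 0) stop("config error: step must be positive", call. = FALSE)
  stopifnot(all(ranking %in% colnames(X)))
  sizes <- unique(c(seq(step, length(ranking), by = step), length(ranking)))
  rows <- list()
  for (s in sizes) {
    feats <- ranking[seq_len(s)]
    model <- .fit_gbdt(X[train_idx, feats, drop = FALSE], y[train_idx],
                       "regression", n_trees = n_trees, seed = seed)
    for (part in c("train", "validation")) {
      idx <- if (part == "train") train_idx else val_idx
      pred <- .predict_gbdt(model, X[idx, feats, drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        size = s, partition = part,
        mae = mae(y[idx], pred), rmse = rmse(y[idx], pred),
        r2 = tryCatch(r_squared(y[idx], pred), error = function(e) NA_real_))
    }
  }
  do.call(rbind, rows)
}

#' Select the most relevant features
#'
#' Union policy: the top \code{n_gain} features by gain joined with the
#' features whose normalized F or MI score reaches \code{min_normalized}
#' (the statistical picks capped at \code{n_stat}, best first).
#'
#' @param scores combined feature score table (\code{\link{feature_scores}}).
#' @param n_gain number of gain-ranked features (default 150).
#' @param n_stat cap on extra statistically selected features (default 50).
#' @param min_normalized normalized-score threshold (default 0.9).
#' @return character vector of selected feature names (gain order first).
#' @export
select_relevant <- function(scores, n_gain = 150, n_stat = 50,
                            min_normalized = 0.9) {
  stopifnot(all(c("feature", "gain_rank") %in% colnames(scores)))
  by_gain <- scores$feature[order(scores$gain_rank)]
  picked <- by_gain[seq_len(min(n_gain, length(by_gain)))]
  if (n_stat > 0 &&
      all(c("f_stat_normalized", "mi_normalized") %in% colnames(scores))) {
    stat_score <- pmax(scores$f_stat_normalized, scores$mi_normalized)
    cand <- scores$feature[stat_score >= min_normalized]
    cand <- cand[order(-stat_score[match(cand, scores$feature)])]
    cand <- setdiff(cand, picked)
    picked <- c(picked, cand[seq_len(min(n_stat, length(cand)))])
  }
  if (!length(picked)) stop("selection error: no features selected",
                            call. = FALSE)
  picked
}
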