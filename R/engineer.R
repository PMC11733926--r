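# Brute-force feature engineering on the selected subset, followed by the
# two-step multicollinearity reduction: a pairwise correlation filter and
# hierarchical clustering of Spearman correlations with Ward linkage.

#' Brute-force pairwise feature engineering
#'
#' For the \code{top_k} highest-priority features, constructs derived
#' columns with no domain knowledge: sum, absolute difference and product
#' for every unordered pair, and both ordered ratios (denominators guarded
#' by \code{ratio_epsilon}). With the full operation set the engineered
#' count is 3 C(top_k, 2) + top_k (top_k - 1).
#'
#' @param X_subset feature matrix of the selected features, columns in
#'   priority (gain-rank) order.
#' @param op_set subset of c("sum", "abs_diff", "product", "ratio").
#' @param top_k number of leading columns to combine (default 5).
#' @param ratio_epsilon denominator guard (default 1e-9).
#' @param standardize z-score the parent columns before combining
#'   (default FALSE: operate on the raw values). The workflow uses TRUE so
#'   that sums and differences are not dominated by the larger-scale
#'   parent; the scaling constants are recorded in the spec attribute and
#'   reused at prediction time.
#' @return matrix of engineered columns named "a+b", "|a-b|", "a*b", "a/b".
#' @export
brute_force_engineer <- function(X_subset,
                                 op_set = c("sum", "abs_diff", "product",
                                            "ratio"),
                                 top_k = 5, ratio_epsilon = 1e-9,
                                 standardize = FALSE) {
  op_set <- match.arg(op_set, several.ok = TRUE)
  if (top_k < 2) {
    warning("top_k < 2: nothing to engineer")
    return(matrix(numeric(0), nrow = nrow(X_subset), ncol = 0))
  }
  if (top_k > ncol(X_subset)) {
    stop("config error: top_k exceeds the subset width", call. = FALSE)
  }
  nms <- colnames(X_subset)[seq_len(top_k)]
  mu <- stats::setNames(rep(0, top_k), nms)
  sdev <- stats::setNames(rep(1, top_k), nms)
  if (standardize) {
    mu <- apply(X_subset[, nms, drop = FALSE], 2, mean)
    sdev <- apply(X_subset[, nms, drop = FALSE], 2, stats::sd)
    sdev[!is.finite(sdev) | sdev == 0] <- 1
    X_subset <- X_subset[, , drop = FALSE]
    X_subset[, nms] <- sweep(sweep(X_subset[, nms, drop = FALSE], 2, mu),
                             2, sdev, "/")
  }
  cols <- list()
  guard <- function(v) sign(v) * pmax(abs(v), ratio_epsilon) +
    (v == 0) * ratio_epsilon
  for (a in seq_len(top_k - 1)) {
    for (b in seq((a + 1), top_k)) {
      xa <- X_subset[, nms[a]]; xb <- X_subset[, nms[b]]
      if ("sum" %in% op_set) cols[[paste0(nms[a], "+", nms[b])]] <- xa + xb
      if ("abs_diff" %in% op_set)
        cols[[paste0("|", nms[a], "-", nms[b], "|")]] <- abs(xa - xb)
      if ("product" %in% op_set)
        cols[[paste0(nms[a], "*", nms[b])]] <- xa * xb
    }
  }
  if ("ratio" %in% op_set) {
    for (a in seq_len(top_k)) {
      for (b in seq_len(top_k)) {
        if (a == b) next
        xa <- X_subset[, nms[a]]; xb <- X_subset[, nms[b]]
        cols[[paste0(nms[a], "/", nms[b])]] <- xa / guard(xb)
      }
    }
  }
  out <- do.call(cbind, cols)
  if (is.null(out)) out <- matrix(numeric(0), nrow = nrow(X_subset), ncol = 0)
  rownames(out) <- rownames(X_subset)
  specs <- .engineer_specs(nms, op_set)
  if (nrow(specs)) {
    specs$mu_a <- mu[specs$a]; specs$sd_a <- sdev[specs$a]
    specs$mu_b <- mu[specs$b]; specs$sd_b <- sdev[specs$b]
  }
  attr(out, "specs") <- specs
  attr(out, "ratio_epsilon") <- ratio_epsilon
  out
}

# the (op, parent_a, parent_b, name) table describing the engineered columns
.engineer_specs <- function(nms, op_set) {
  rows <- list()
  k <- length(nms)
  for (a in seq_len(max(k - 1, 0))) {
    for (b in seq((a + 1), k)) {
      if ("sum" %in% op_set)
        rows[[length(rows) + 1]] <- c("sum", nms[a], nms[b],
                                      paste0(nms[a], "+", nms[b]))
      if ("abs_diff" %in% op_set)
        rows[[length(rows) + 1]] <- c("abs_diff", nms[a], nms[b],
                                      paste0("|", nms[a], "-", nms[b], "|"))
      if ("product" %in% op_set)
        rows[[length(rows) + 1]] <- c("product", nms[a], nms[b],
                                      paste0(nms[a], "*", nms[b]))
    }
  }
  if ("ratio" %in% op_set) {
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a != b)
        rows[[length(rows) + 1]] <- c("ratio", nms[a], nms[b],
                                      paste0(nms[a], "/", nms[b]))
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (nrow(out)) colnames(out) <- c("op", "a", "b", "name")
  out
}

# recompute engineered columns (prediction path)
.apply_engineered <- function(X, specs, ratio_epsilon = 1e-9) {
  if (is.null(specs) || nrow(specs) == 0) {
    return(matrix(numeric(0), nrow = nrow(X), ncol = 0))
  }
  guard <- function(v) sign(v) * pmax(abs(v), ratio_epsilon) +
    (v == 0) * ratio_epsilon
  if (is.null(specs$mu_a)) {
    specs$mu_a <- specs$mu_b <- 0
    specs$sd_a <- specs$sd_b <- 1
  }
  cols <- lapply(seq_len(nrow(specs)), function(i) {
    xa <- (X[, specs$a[i]] - specs$mu_a[i]) / specs$sd_a[i]
    xb <- (X[, specs$b[i]] - specs$mu_b[i]) / specs$sd_b[i]
    switch(specs$op[i],
           sum = xa + xb,
           abs_diff = abs(xa - xb),
           product = xa * xb,
           ratio = xa / guard(xb))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- specs$name
  rownames(out) <- rownames(X)
  out
}

#' Expected engineered-feature count
#'
#' Closed form for the number of columns \code{\link{brute_force_engineer}}
#' produces for a given operation set and top_k.
#'
#' @inheritParams brute_force_engineer
#' @return integer count.
#' @export
engineered_count <- function(top_k,
                             op_set = c("sum", "abs_diff", "product",
                                        "ratio")) {
  if (top_k < 2) return(0L)
  pairs <- choose(top_k, 2)
  n_sym <- sum(c("sum", "abs_diff", "product") %in% op_set)
  as.integer(n_sym * pairs + ("ratio" %in% op_set) * top_k * (top_k - 1))
}

#' Pairwise correlation filter
#'
#' Greedily removes features so that no retained pair has |Pearson r| at or
#' above the threshold. In \code{ranked} mode (default) the lower-priority
#' member of an offending pair is dropped; in \code{random} mode the victim
#' is chosen by a seeded coin, matching the workflow description in which
#' highly correlated features are eliminated randomly.
#'
#' @param X feature matrix (finite).
#' @param threshold correlation threshold in (0, 1] (default 0.8).
#' @param priority character vector of column names, most important first
#'   (default: column order).
#' @param mode "ranked" or "random".
#' @param seed seed for random mode.
#' @return character vector of retained feature names.
#' @export
correlation_filter <- function(X, threshold = 0.8, priority = colnames(X),
                               mode = c("ranked", "random"), seed = 1L) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1) {
    stop("config error: threshold must be in (0, 1]", call. = FALSE)
  }
  .check_finite(X)
  priority <- c(intersect(priority, colnames(X)),
                setdiff(colnames(X), priority))
  cm <- suppressWarnings(stats::cor(X[, priority, drop = FALSE]))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  p <- length(priority)
  keep <- rep(TRUE, p)
  if (mode == "ranked") {
    for (i in seq_len(p)) {
      if (!keep[i]) next
      bad <- which(keep & abs(cm[i, ]) >= threshold)
      bad <- bad[bad > i]
      keep[bad] <- FALSE
    }
  } else {
    coin <- .with_seed(seed, stats::runif(p * p))
    ci <- 0
    repeat {
      offend <- which(abs(cm) >= threshold & outer(keep, keep, "&"),
                      arr.ind = TRUE)
      offend <- offend[offend[, 1] < offend[, 2], , drop = FALSE]
      if (nrow(offend) == 0) break
      i <- offend[1, 1]; j <- offend[1, 2]
      ci <- ci + 1
      drop <- if (coin[ci] < 0.5) i else j
      keep[drop] <- FALSE
    }
  }
  retained <- priority[keep]
  colnames(X)[colnames(X) %in% retained]
}

#' Spearman/Ward hierarchical clustering of features
#'
#' Computes the feature-feature distance 1 - |Spearman rho| (ties handled
#' by average ranks; absolute rho so anticorrelated features cluster
#' together), applies agglomerative clustering with Ward linkage, cuts the
#' tree at \code{linkage_threshold} and retains one representative per
#' cluster (best priority rank by default). Constant columns have
#' undefined rank correlation and are isolated into singleton clusters
#' with a warning.
#'
#' @param X feature matrix with at least 2 columns.
#' @param linkage_threshold tree cut height (default 0.5).
#' @param priority column names, most important first (representative rule).
#' @return list with \code{assignment} (feature -> cluster id),
#'   \code{representatives} (cluster id -> feature), \code{retained}
#'   (character vector), \code{merge_heights} and the \code{hclust} object.
#' @export
spearman_ward_cluster <- function(X, linkage_threshold = 0.5,
                                  priority = colnames(X)) {
  stopifnot(ncol(X) >= 2)
  .check_finite(X)
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning("constant column(s) isolated into singleton clusters: ",
            paste(colnames(X)[const], collapse = ", "))
  }
  vary <- colnames(X)[!const]
  assignment <- stats::setNames(integer(ncol(X)), colnames(X))
  hc <- NULL
  if (length(vary) >= 2) {
    rho <- suppressWarnings(
      stats::cor(X[, vary, drop = FALSE], method = "spearman"))
    d <- stats::as.dist(1 - abs(rho))
    hc <- stats::hclust(d, method = "ward.D2")
    cl <- stats::cutree(hc, h = linkage_threshold)
    assignment[vary] <- cl
  } else if (length(vary) == 1) {
    assignment[vary] <- 1L
  }
  nclust <- max(assignment, 0)
  for (nm in colnames(X)[const]) {
    nclust <- nclust + 1L
    assignment[nm] <- nclust
  }
  priority <- c(intersect(priority, colnames(X)),
                setdiff(colnames(X), priority))
  reps <- character(nclust)
  for (cid in seq_len(nclust)) {
    members <- names(assignment)[assignment == cid]
    reps[cid] <- priority[priority %in% members][1]
  }
  list(assignment = assignment,
       representatives = reps,
       retained = colnames(X)[colnames(X) %in% reps],
       merge_heights = if (!is.null(hc)) hc$height else numeric(0),
       hclust = hc,
       linkage_threshold = linkage_threshold)
}
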