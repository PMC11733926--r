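# Two-step hyperparameter optimization of the final GBDT: a coarse grid
# search to locate a promising region, then Gaussian-process Bayesian
# optimization (expected improvement) inside it. Also the final-model fit,
# prediction, persistence, and the Mol2Vec concatenation point.

#' Hyperparameter space definition
#'
#' @param ... named axes. Each axis is either a numeric length-2 vector
#'   (bounds), a list \code{list(type=, bounds=)} with type "integer",
#'   "real" or "log-real", or a character/numeric vector of length > 2
#'   (categorical choices).
#' @return a \code{hyperparameter_space} object.
#' @export
hyperparameter_space <- function(...) {
  axes <- list(...)
  if (!length(axes)) stop("config error: empty space", call. = FALSE)
  stopifnot(!is.null(names(axes)), all(nzchar(names(axes))))
  parsed <- lapply(axes, function(a) {
    if (is.list(a)) {
      stopifnot(a$type %in% c("integer", "real", "log-real", "categorical"))
      a
    } else if (is.numeric(a) && length(a) == 2) {
      list(type = "real", bounds = sort(a))
    } else {
      list(type = "categorical", choices = a)
    }
  })
  for (a in parsed) {
    if (!is.null(a$bounds) &&
        (any(!is.finite(a$bounds)) || a$bounds[1] > a$bounds[2])) {
      stop("config error: bounds must be finite and ordered", call. = FALSE)
    }
  }
  structure(parsed, class = "hyperparameter_space")
}

#' Default GBDT search space
#' @return a \code{hyperparameter_space} for the final-model tuning.
#' @export
default_search_space <- function() {
  hyperparameter_space(
    learning_rate = list(type = "log-real", bounds = c(0.005, 0.3)),
    n_trees = list(type = "integer", bounds = c(100, 3000)),
    num_leaves = list(type = "integer", bounds = c(15, 255)),
    min_child_samples = list(type = "integer", bounds = c(5, 100)),
    subsample = list(type = "real", bounds = c(0.5, 1)),
    colsample = list(type = "real", bounds = c(0.5, 1)),
    reg_alpha = list(type = "log-real", bounds = c(1e-8, 10)),
    reg_lambda = list(type = "log-real", bounds = c(1e-8, 10)))
}

# map a named point onto engine parameters and fit count
.point_to_fit <- function(point) {
  defaults <- list(learning_rate = 0.05, n_trees = 500, num_leaves = 31,
                   min_child_samples = 5, subsample = 1, colsample = 1,
                   reg_alpha = 0, reg_lambda = 1)
  for (nm in names(point)) defaults[[nm]] <- point[[nm]]
  defaults
}

# k-fold CV objective (minimized): RMSE for regression, 1 - AUC for
# classification
.cv_objective <- function(X, y, task_type, cv_folds, seed) {
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(X)
  folds <- .with_seed(.derive_seed(seed, 7),
                      sample(rep(seq_len(cv_folds), length.out = n)))
  function(point) {
    p <- .point_to_fit(point)
    pars <- .gbdt_params(task_type, learning_rate = p$learning_rate,
                         num_leaves = p$num_leaves,
                         min_child_samples = p$min_child_samples,
                         subsample = p$subsample, colsample = p$colsample,
                         reg_alpha = p$reg_alpha, reg_lambda = p$reg_lambda)
    vals <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      m <- .fit_gbdt(X[tr, , drop = FALSE], y[tr], task_type,
                     n_trees = p$n_trees, params = pars,
                     seed = .derive_seed(seed, 31 * f))
      pred <- .predict_gbdt(m, X[!tr, , drop = FALSE])
      vals[f] <- if (task_type == "classification") {
        1 - auc_roc(y[!tr], pred)
      } else {
        rmse(y[!tr], pred)
      }
    }
    mean(vals)
  }
}

#' Coarse grid search
#'
#' Evaluates every point of a discretized grid by k-fold cross-validation
#' and returns the best point together with a shrunken space bracketing it
#' (plus/minus one grid step per axis), the promising region for the
#' Bayesian fine-tuning step.
#'
#' @param X,y training data (ignored when \code{objective} is supplied).
#' @param grid named list of value vectors, one per hyperparameter.
#' @param task_type "regression" or "classification".
#' @param cv_folds folds for the CV objective (default 5).
#' @param seed integer seed.
#' @param objective optional function(point) -> value to minimize.
#' @return list with \code{best_point}, \code{best_value}, \code{region}
#'   (a \code{hyperparameter_space}), \code{evaluations} (data.frame).
#' @export
coarse_grid_search <- function(X = NULL, y = NULL, grid,
                               task_type = "regression", cv_folds = 5,
                               seed = 1L, objective = NULL) {
  if (!length(grid)) stop("config error: empty grid", call. = FALSE)
  if (is.null(objective)) {
    objective <- .cv_objective(X, y, task_type, cv_folds, seed)
  }
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  vals <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    vals[i] <- objective(as.list(pts[i, , drop = FALSE]))
  }
  best <- which.min(vals)
  best_point <- as.list(pts[best, , drop = FALSE])
  region <- lapply(names(grid), function(nm) {
    ax <- sort(unique(grid[[nm]]))
    if (!is.numeric(ax) || length(ax) == 1) {
      return(list(type = "categorical", choices = best_point[[nm]]))
    }
    i <- which.min(abs(ax - best_point[[nm]]))
    lo <- ax[max(1, i - 1)]; hi <- ax[min(length(ax), i + 1)]
    if (lo == hi) list(type = "categorical", choices = lo)
    else list(type = if (all(ax == round(ax))) "integer" else "real",
              bounds = c(lo, hi))
  })
  names(region) <- names(grid)
  list(best_point = best_point, best_value = vals[best],
       region = structure(region, class = "hyperparameter_space"),
       evaluations = cbind(pts, objective = vals))
}

# ---- Gaussian-process expected-improvement optimizer ------------------------

.space_dim <- function(space) length(space)

# encode a point into [0,1]^d
.encode_point <- function(space, point) {
  vapply(names(space), function(nm) {
    a <- space[[nm]]; v <- point[[nm]]
    if (a$type == "categorical") {
      ch <- a$choices
      if (length(ch) == 1) return(0.5)
      return((match(v, ch) - 1) / (length(ch) - 1))
    }
    b <- a$bounds
    if (a$type == "log-real") {
      (log(v) - log(b[1])) / max(log(b[2]) - log(b[1]), 1e-12)
    } else {
      (v - b[1]) / max(b[2] - b[1], 1e-12)
    }
  }, numeric(1))
}

# decode a unit-cube vector into a typed point
.decode_point <- function(space, u) {
  out <- list()
  for (i in seq_along(space)) {
    nm <- names(space)[i]; a <- space[[i]]
    if (a$type == "categorical") {
      ch <- a$choices
      out[[nm]] <- ch[pmin(length(ch), 1 + floor(u[i] * length(ch)))]
      next
    }
    b <- a$bounds
    v <- if (a$type == "log-real") {
      exp(log(b[1]) + u[i] * (log(b[2]) - log(b[1])))
    } else {
      b[1] + u[i] * (b[2] - b[1])
    }
    if (a$type == "integer") v <- as.integer(round(v))
    out[[nm]] <- min(max(v, b[1]), b[2])
  }
  out
}

#' Bayesian optimization of the CV objective
#'
#' Sequential model-based minimization: a Gaussian-process surrogate (RBF
#' kernel on the unit-cube encoding of the space) is fitted to the
#' evaluations so far and the next point maximizes expected improvement
#' over the incumbent. The first \code{max(5, 2 d)} points are a seeded
#' space-filling sample. The best-so-far curve is non-increasing by
#' construction and the whole trace is reproducible under a fixed seed.
#'
#' @param X,y training data (ignored when \code{objective} is supplied).
#' @param space a \code{\link{hyperparameter_space}}.
#' @param n_calls total number of objective evaluations (>= 5).
#' @param task_type,cv_folds forwarded to the CV objective.
#' @param seed integer seed.
#' @param objective optional function(point) -> value to minimize
#'   (replaces the CV objective; used for analytic test functions).
#' @return list with \code{best_point}, \code{best_value},
#'   \code{evaluations} (data.frame of points and values), \code{best_so_far}.
#' @export
bayesian_optimize <- function(X = NULL, y = NULL, space, n_calls = 30,
                              task_type = "regression", cv_folds = 5,
                              seed = 1L, objective = NULL) {
  stopifnot(inherits(space, "hyperparameter_space"))
  if (n_calls < 5) stop("config error: n_calls must be >= 5", call. = FALSE)
  if (is.null(objective)) {
    objective <- .cv_objective(X, y, task_type, cv_folds, seed)
  }
  d <- .space_dim(space)
  n_init <- min(max(5, 2 * d), n_calls)
  U <- matrix(NA_real_, n_calls, d)
  vals <- numeric(n_calls)
  rand <- .with_seed(.derive_seed(seed, 77), {
    list(init = matrix(stats::runif(n_init * d), n_init, d),
         cand = lapply(seq_len(n_calls), function(i) {
           matrix(stats::runif(512 * d), 512, d)
         }))
  })
  for (i in seq_len(n_calls)) {
    if (i <= n_init) {
      u <- rand$init[i, ]
    } else {
      u <- .propose_ei(U[seq_len(i - 1), , drop = FALSE],
                       vals[seq_len(i - 1)], rand$cand[[i]])
    }
    U[i, ] <- u
    vals[i] <- objective(.decode_point(space, u))
  }
  best <- which.min(vals)
  evals <- as.data.frame(do.call(rbind, lapply(seq_len(n_calls), function(i) {
    unlist(.decode_point(space, U[i, ]))
  })), stringsAsFactors = FALSE)
  evals$objective <- vals
  list(best_point = .decode_point(space, U[best, ]),
       best_value = vals[best],
       evaluations = evals,
       best_so_far = cummin(vals),
       seed = seed)
}

# GP posterior + expected improvement; returns the best candidate row
.propose_ei <- function(U, vals, cand) {
  n <- nrow(U); d <- ncol(U)
  mu_y <- mean(vals); sd_y <- stats::sd(vals)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  z <- (vals - mu_y) / sd_y
  ell <- 0.25 * sqrt(d)
  sqd <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  }
  K <- exp(-pmax(sqd(U, U), 0) / (2 * ell^2)) + diag(1e-6 + 1e-4, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(cand[1, ])
  alpha <- backsolve(L, forwardsolve(t(L), z))
  Ks <- exp(-pmax(sqd(cand, U), 0) / (2 * ell^2))
  mu <- as.vector(Ks %*% alpha)
  v <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  fbest <- min(z)
  imp <- fbest - mu
  zz <- imp / s
  ei <- imp * stats::pnorm(zz) + s * stats::dnorm(zz)
  cand[which.max(ei), ]
}

#' Concatenate Mol2Vec embedding columns onto the selected features
#'
#' The GBFS and GBFS-Mol2Vec workflows are identical through feature
#' selection; this is the single point at which they diverge. Selected
#' columns precede the embedding columns; an empty embedding matrix
#' returns the input unchanged (pure GBFS path).
#'
#' @param X_selected feature matrix of the selected features.
#' @param E embedding matrix ("Mol2Vec-" columns), same rows.
#' @return combined matrix of width ncol(X_selected) + ncol(E).
#' @export
attach_embeddings <- function(X_selected, E) {
  if (is.null(E) || ncol(E) == 0) return(X_selected)
  if (nrow(E) != nrow(X_selected)) {
    stop("alignment error: row mismatch between features and embeddings",
         call. = FALSE)
  }
  if (any(colnames(E) %in% colnames(X_selected))) {
    stop("alignment error: embedding column names collide with features",
         call. = FALSE)
  }
  cbind(X_selected, E)
}

#' Train the final predictive model
#'
#' Fits the GBDT with the chosen hyperparameters on the full training
#' partition only and records the exact feature-name order required at
#' prediction time.
#'
#' @param X training feature matrix.
#' @param y target vector.
#' @param task_type "regression" or "classification".
#' @param best_point named list of hyperparameters (see
#'   \code{\link{default_search_space}}); NULL fits engine defaults.
#' @param seed integer seed.
#' @return a \code{gbfs_model} with a \code{predict} method.
#' @export
train_final_model <- function(X, y, task_type = "regression",
                              best_point = NULL, seed = 1L) {
  .check_finite(X)
  keep <- !is.na(y)
  if (task_type == "regression" && stats::sd(y[keep]) == 0) {
    warning("constant target: the model will predict a constant")
  }
  p <- .point_to_fit(best_point)
  pars <- .gbdt_params(task_type, learning_rate = p$learning_rate,
                       num_leaves = p$num_leaves,
                       min_child_samples = p$min_child_samples,
                       subsample = p$subsample, colsample = p$colsample,
                       reg_alpha = p$reg_alpha, reg_lambda = p$reg_lambda)
  booster <- .fit_gbdt(X[keep, , drop = FALSE], y[keep], task_type,
                       n_trees = p$n_trees, params = pars, seed = seed)
  structure(list(booster = booster, feature_names = colnames(X),
                 task_type = task_type, hyperparameters = p, seed = seed),
            class = "gbfs_model")
}

#' @export
predict.gbfs_model <- function(object, newdata, type = c("response", "class"),
                               ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(X))
  extra <- setdiff(colnames(X), object$feature_names)
  if (length(missing)) {
    stop("schema error: missing feature column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (length(extra)) {
    X <- X[, object$feature_names, drop = FALSE]
  } else {
    X <- X[, object$feature_names, drop = FALSE]
  }
  pred <- .predict_gbdt(object$booster, X)
  if (object$task_type == "classification" && type == "class") {
    return(as.numeric(pred >= 0.5))
  }
  pred
}

#' Persist / restore a fitted model
#'
#' Writes the booster (JSON) plus a JSON sidecar with feature names,
#' hyperparameters and seed into a directory; \code{load_gbfs_model}
#' restores an object producing identical predictions.
#'
#' @param model a \code{gbfs_model}.
#' @param dir target directory (created if needed).
#' @export
save_gbfs_model <- function(model, dir) {
  stopifnot(inherits(model, "gbfs_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.json"))
  meta <- list(feature_names = model$feature_names,
               task_type = model$task_type,
               hyperparameters = model$hyperparameters,
               seed = model$seed)
  jsonlite::write_json(meta, file.path(dir, "model_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_gbfs_model
#' @export
load_gbfs_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model_meta.json"),
                              simplifyVector = TRUE)
  booster <- xgboost::xgb.load(file.path(dir, "booster.json"))
  structure(list(booster = booster, feature_names = meta$feature_names,
                 task_type = meta$task_type,
                 hyperparameters = as.list(meta$hyperparameters),
                 seed = meta$seed),
            class = "gbfs_model")
}
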