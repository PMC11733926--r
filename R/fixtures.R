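# Synthetic molecule fixtures: a fragment grammar for generating valid
# drug-like SMILES, and planted structure-property targets so that feature
# selection and model fitting can be exercised (and their recovery rates
# measured) without any external dataset.

# attach/replace a target column on an existing molecule table without
# re-parsing the SMILES
.set_target <- function(table, name, values, task_type = NULL) {
  stopifnot(inherits(table, "molecule_table"), nrow(table) == length(values))
  at <- attributes(table)
  table[[name]] <- as.numeric(values)
  attr(table, "target_names") <- union(at$target_names, name)
  if (!is.null(task_type)) attr(table, "task_type") <- task_type
  class(table) <- c("molecule_table", "data.frame")
  table
}

#' Generate synthetic molecules from a fragment grammar
#'
#' Assembles unique, valid SMILES from a weighted grammar of drug-like
#' fragments: alkyl chains (lengths 1-8), benzene rings, ether links, and
#' terminal carboxylic acid, hydroxyl, amine and halogen groups (H, C, N,
#' O, F, S, Cl, Br chemistry only). Generation is seed-reproducible and
#' every generated string round-trips unchanged through
#' \code{\link{canonicalize_smiles}}.
#'
#' @param n_molecules number of unique molecules.
#' @param seed integer seed.
#' @param max_units backbone length in fragments (default 4).
#' @param weights named weights for the backbone fragment classes
#'   \code{alkyl}, \code{branched}, \code{benzene}, \code{substituted_ring},
#'   \code{hydroxyalkyl}, \code{aminoalkyl}, \code{ether}, \code{amide},
#'   \code{thio}.
#' @param terminal_weights named weights for the terminal groups
#'   \code{none}, \code{acid}, \code{hydroxyl}, \code{amine},
#'   \code{nitrile}, \code{thiol}, \code{ester}, \code{fluoro},
#'   \code{chloro}, \code{bromo}.
#' @return a \code{molecule_table} without targets.
#' @export
generate_molecules <- function(n_molecules, seed = 1L, max_units = 4,
                               weights = c(alkyl = 2, branched = 1.5,
                                           benzene = 1.5,
                                           substituted_ring = 2,
                                           hydroxyalkyl = 1,
                                           aminoalkyl = 1,
                                           ether = 1.5, amide = 1,
                                           thio = 0.5),
                               terminal_weights = c(none = 1.5, acid = 1.2,
                                                    hydroxyl = 1.2,
                                                    amine = 1, nitrile = 1,
                                                    thiol = 1, ester = 1,
                                                    fluoro = 0.5,
                                                    chloro = 0.5,
                                                    bromo = 0.25)) {
  stopifnot(n_molecules >= 1)
  draw <- function(w) names(w)[sample.int(length(w), 1, prob = w)]
  frag <- function(kind) {
    switch(kind,
           alkyl = strrep("C", sample.int(4, 1)),
           branched = paste0("C(", strrep("C", sample.int(2, 1)), ")",
                             strrep("C", sample.int(2, 1))),
           benzene = "c1ccccc1",
           substituted_ring = sample(c("c1ccc(O)cc1", "c1ccc(N)cc1",
                                       "c1ccc(F)cc1", "c1ccc(Cl)cc1",
                                       "c1ccc(C(=O)O)cc1"), 1),
           hydroxyalkyl = "CC(O)C",
           aminoalkyl = "CC(N)C",
           ether = paste0("O", strrep("C", sample.int(3, 1))),
           amide = "C(=O)NC",
           thio = "CSC")
  }
  term <- function(kind) {
    switch(kind, none = "", acid = "C(=O)O", hydroxyl = "O", amine = "N",
           nitrile = "C#N", thiol = "S", ester = "C(=O)OC",
           fluoro = "F", chloro = "Cl", bromo = "Br")
  }
  smiles <- .with_seed(seed, {
    seen <- character(0)
    tries <- 0
    while (length(seen) < n_molecules) {
      tries <- tries + 1
      if (tries > 200 * n_molecules) {
        stop("generation error: grammar cannot yield ", n_molecules,
             " unique molecules; enlarge the grammar", call. = FALSE)
      }
      units <- vapply(seq_len(sample.int(max_units, 1)), function(i) {
        frag(draw(weights))
      }, character(1))
      s <- paste0(paste0(units, collapse = ""), term(draw(terminal_weights)))
      # substituted rings carry their own terminal; a lone hetero unit
      # ("OC", "SC") must still contain carbon, which the grammar ensures
      if (!grepl("[Cc]", s)) next
      can <- tryCatch(canonicalize_smiles(s), error = function(e) NA)
      if (is.na(can) || can %in% seen) next
      seen <- c(seen, can)
    }
    seen
  })
  molecule_table(smiles)
}

#' Plant a regression target on a feature matrix
#'
#' Builds y as a linear combination of standardized informative feature
#' columns plus Gaussian noise: y = sum beta_j z(x_j) + N(0, noise_sd^2).
#' The ground truth (features, coefficients, noise draw, signal sd) is
#' attached as attribute \code{"ground_truth"} for recovery tests.
#'
#' @param table a \code{molecule_table}.
#' @param X feature matrix aligned to the table.
#' @param informative named numeric vector: feature name -> coefficient.
#' @param noise_sd noise standard deviation.
#' @param seed integer seed.
#' @param target_name target column name (default "y").
#' @return the table with the target column added.
#' @export
plant_regression_target <- function(table, X, informative, noise_sd = 0.1,
                                    seed = 1L, target_name = "y") {
  missing <- setdiff(names(informative), colnames(X))
  if (length(missing)) {
    stop("schema error: informative feature(s) absent from X: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  Z <- scale(X[, names(informative), drop = FALSE])
  Z[!is.finite(Z)] <- 0
  signal <- as.vector(Z %*% informative)
  eps <- .with_seed(seed, stats::rnorm(nrow(X), 0, noise_sd))
  out <- .set_target(table, target_name, signal + eps, "regression")
  attr(out, "ground_truth") <- list(informative = informative,
                                    signal = signal, noise_sd = noise_sd,
                                    signal_sd = stats::sd(signal), seed = seed)
  out
}

#' Plant binary classification labels
#'
#' Labels are Bernoulli draws with probability
#' sigmoid(sum beta_j z(x_j) + intercept).
#'
#' @inheritParams plant_regression_target
#' @param intercept linear-score intercept (default 0: balanced classes for
#'   symmetric scores).
#' @return the table with a 0/1 label column; the empirical positive rate
#'   is recorded in the ground-truth attribute.
#' @export
plant_classification_target <- function(table, X, informative, intercept = 0,
                                        seed = 1L, target_name = "y") {
  missing <- setdiff(names(informative), colnames(X))
  if (length(missing)) {
    stop("schema error: informative feature(s) absent from X: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  Z <- scale(X[, names(informative), drop = FALSE])
  Z[!is.finite(Z)] <- 0
  score <- as.vector(Z %*% informative) + intercept
  prob <- 1 / (1 + exp(-score))
  lab <- .with_seed(seed, stats::rbinom(nrow(X), 1, prob))
  out <- .set_target(table, target_name, lab, "classification")
  attr(out, "ground_truth") <- list(informative = informative, score = score,
                                    intercept = intercept,
                                    positive_rate = mean(lab), seed = seed)
  out
}
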