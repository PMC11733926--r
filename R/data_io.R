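# Molecule tables, dataset I/O and train/validation/test splitting.

#' Construct a molecule table
#'
#' The unit of dataset I/O: an ordered set of molecules (canonical SMILES)
#' with named numeric targets (regression) or 0/1 labels (classification;
#' NA marks a missing label in multi-task tables). Rows whose SMILES do not
#' parse are dropped with a message; the number dropped is recorded in the
#' \code{n_dropped} attribute. Row order is preserved and defines the row
#' index of every feature matrix built from the table.
#'
#' @param smiles character vector of SMILES.
#' @param targets data.frame (or NULL) of target columns, one row per input.
#' @param ids optional unique ids; defaults to \code{mol_<row>}.
#' @param task_type "regression" or "classification".
#' @return A \code{molecule_table}: data.frame with columns \code{id},
#'   \code{smiles} and one column per target, plus \code{task_type} /
#'   \code{target_names} / \code{n_dropped} attributes.
#' @export
molecule_table <- function(smiles, targets = NULL, ids = NULL,
                           task_type = c("regression", "classification")) {
  task_type <- match.arg(task_type)
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) stop("empty table: no rows", call. = FALSE)
  if (is.null(ids)) ids <- paste0("mol_", seq_along(smiles))
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  if (!is.null(targets)) {
    targets <- as.data.frame(targets)
    stopifnot(nrow(targets) == length(smiles))
  }
  p <- .parse_smiles(smiles)
  keep <- p$valid
  if (!any(keep)) stop("empty table: no valid SMILES rows", call. = FALSE)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " row(s) with unparseable SMILES")
  }
  can <- canonicalize_smiles(smiles[keep])
  tab <- data.frame(id = ids[keep], smiles = can, stringsAsFactors = FALSE)
  tnames <- character(0)
  if (!is.null(targets)) {
    tnames <- colnames(targets)
    for (nm in tnames) {
      v <- targets[keep, nm]
      if (task_type == "classification") {
        ok <- is.na(v) | v %in% c(0, 1)
        if (!all(ok)) stop("classification labels must be 0/1/NA in column ",
                           nm, call. = FALSE)
      }
      tab[[nm]] <- as.numeric(v)
    }
  }
  structure(tab, task_type = task_type, target_names = tnames,
            n_dropped = n_dropped,
            class = c("molecule_table", "data.frame"))
}

#' @export
print.molecule_table <- function(x, ...) {
  cat("Molecule table: ", nrow(x), " molecules, task = ",
      attr(x, "task_type"), "\n", sep = "")
  tn <- attr(x, "target_names")
  if (length(tn)) cat("Targets: ", paste(tn, collapse = ", "), "\n", sep = "")
  if (attr(x, "n_dropped") > 0)
    cat("(", attr(x, "n_dropped"), " unparseable row(s) dropped on import)\n",
        sep = "")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read a molecule table from CSV or XLSX
#'
#' @param path file path; \code{.csv} (UTF-8, header row) or \code{.xlsx}
#'   (requires the readxl package; first sheet by default).
#' @param smiles_column name of the SMILES column (default "smiles").
#' @param target_columns character vector of target column names; default:
#'   every numeric column other than the SMILES column.
#' @param task_type "regression" or "classification".
#' @param sheet sheet name or index for XLSX input.
#' @return A \code{\link{molecule_table}}; unparseable rows are dropped and
#'   counted in the \code{n_dropped} attribute.
#' @export
read_molecule_table <- function(path, smiles_column = "smiles",
                                target_columns = NULL,
                                task_type = c("regression", "classification"),
                                sheet = 1) {
  task_type <- match.arg(task_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  }
  if (!smiles_column %in% colnames(df)) {
    stop("schema error: SMILES column '", smiles_column, "' not found",
         call. = FALSE)
  }
  if (is.null(target_columns)) {
    num <- vapply(df, is.numeric, logical(1))
    target_columns <- setdiff(colnames(df)[num], smiles_column)
  } else if (!all(target_columns %in% colnames(df))) {
    stop("schema error: missing target column(s): ",
         paste(setdiff(target_columns, colnames(df)), collapse = ", "),
         call. = FALSE)
  }
  ids <- if ("id" %in% colnames(df) && !"id" %in% target_columns &&
             !anyDuplicated(df$id)) as.character(df$id) else NULL
  molecule_table(as.character(df[[smiles_column]]),
                 targets = df[, target_columns, drop = FALSE],
                 ids = ids, task_type = task_type)
}

# ---- splits -----------------------------------------------------------------

.new_split <- function(train, validation, test, n) {
  e <- new.env(parent = emptyenv())
  e$train <- sort(as.integer(train))
  e$validation <- sort(as.integer(validation))
  e$.test <- sort(as.integer(test))
  e$n <- as.integer(n)
  e$.test_accesses <- 0L
  if (anyDuplicated(c(e$train, e$validation, e$.test)))
    stop("split sets are not disjoint", call. = FALSE)
  class(e) <- "split_index"
  e
}

#' Test-set indices of a split (guarded access)
#'
#' The test partition is intended to be touched exactly once, by the final
#' model evaluation. Every non-peek access is counted;
#' \code{\link{test_access_count}} reports the count so that pipelines can
#' assert single use.
#'
#' @param split a \code{split_index}.
#' @param peek if TRUE, do not count this access (for inspection/tests).
#' @return integer vector of 1-based row indices.
#' @export
test_indices <- function(split, peek = FALSE) {
  stopifnot(inherits(split, "split_index"))
  if (!peek) split$.test_accesses <- split$.test_accesses + 1L
  split$.test
}

#' @rdname test_indices
#' @export
test_access_count <- function(split) split$.test_accesses

#' @export
print.split_index <- function(x, ...) {
  cat("Split: ", length(x$train), " train / ", length(x$validation),
      " validation / ", length(x$.test), " test (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Seeded random train/validation/test split
#'
#' @param table a \code{molecule_table} (or an integer row count).
#' @param test_fraction fraction of rows in the test set (default 0.1,
#'   the benchmark 9:1 convention; the lipophilicity case study uses 0.2).
#' @param validation_fraction fraction in the validation set (default 0).
#' @param seed integer seed; identical arguments give identical splits.
#' @return A \code{split_index} with pairwise-disjoint index sets.
#' @export
random_split <- function(table, test_fraction = 0.1,
                         validation_fraction = 0, seed = 1L) {
  n <- if (inherits(table, "molecule_table") || is.data.frame(table))
    nrow(table) else as.integer(table)
  if (test_fraction <= 0 || test_fraction >= 1 || validation_fraction < 0 ||
      test_fraction + validation_fraction >= 1) {
    stop("config error: fractions must be in (0,1) and sum below 1",
         call. = FALSE)
  }
  n_test <- round(n * test_fraction)
  n_val <- round(n * validation_fraction)
  perm <- .with_seed(seed, sample.int(n))
  test <- perm[seq_len(n_test)]
  val <- if (n_val > 0) perm[n_test + seq_len(n_val)] else integer(0)
  train <- setdiff(perm, c(test, val))
  .new_split(train, val, test, n)
}

#' Bemis-Murcko scaffold split
#'
#' Groups molecules by Murcko scaffold and assigns whole groups,
#' largest-first, to the training set until its target fraction is met,
#' then to validation, then test. Molecules sharing a scaffold never
#' straddle two sets; ring-free molecules (empty scaffold) form one shared
#' group. The most prevalent scaffolds therefore end up in training while
#' test molecules are structurally distinct.
#'
#' @param table a \code{molecule_table}.
#' @param fractions numeric (train, validation, test), summing to 1
#'   (default c(0.8, 0.1, 0.1)).
#' @return A \code{split_index}.
#' @export
scaffold_split <- function(table, fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(inherits(table, "molecule_table"))
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("config error: fractions must be (train, validation, test) summing to 1",
         call. = FALSE)
  }
  scaf <- murcko_scaffold(table$smiles)
  if (all(scaf == "")) {
    warning("all molecules are acyclic: one scaffold group, all in train")
  }
  groups <- split(seq_len(nrow(table)), scaf)
  sizes <- lengths(groups)
  ord <- order(-sizes, vapply(groups, min, integer(1)))
  groups <- groups[ord]
  n <- nrow(table)
  target <- c(train = fractions[1] * n, validation = fractions[2] * n)
  train <- validation <- test <- integer(0)
  for (g in groups) {
    if (length(train) < target["train"]) {
      train <- c(train, g)
    } else if (length(validation) < target["validation"]) {
      validation <- c(validation, g)
    } else {
      test <- c(test, g)
    }
  }
  for (nm in c("validation", "test")) {
    if (fractions[match(nm, c("train", "validation", "test"))] > 0 &&
        length(get(nm)) == 0) {
      warning("scaffold split produced an empty ", nm, " set")
    }
  }
  .new_split(train, validation, test, n)
}

#' Serialize a split to JSON (0-based indices)
#'
#' @param split a \code{split_index}.
#' @param path optional output file; if omitted the JSON string is returned.
#' @export
split_to_json <- function(split, path = NULL) {
  stopifnot(inherits(split, "split_index"))
  obj <- list(train = split$train - 1L, validation = split$validation - 1L,
              test = test_indices(split, peek = TRUE) - 1L)
  js <- jsonlite::toJSON(obj)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
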