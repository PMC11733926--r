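# Molecule-to-vector substructure embeddings: circular-substructure
# "sentences", skip-gram training, and per-molecule vectors computed as
# the sum of the substructure vectors.

#' Substructure sentence of a molecule
#'
#' For each heavy atom (in canonical order) one substructure identifier
#' per radius 0..max_radius for which a circular environment exists
#' (isolated atoms have no environment beyond radius 0). Identifiers are
#' stable hashes of the atom-centered environment, so the token multiset
#' is invariant to how the SMILES is written.
#'
#' @param smiles a single SMILES string.
#' @param max_radius maximum environment radius (0..3, default 1).
#' @return character vector of identifier tokens.
#' @export
molecule_sentence <- function(smiles, max_radius = 1) {
  stopifnot(length(smiles) == 1, max_radius >= 0, max_radius <= 3)
  can <- canonicalize_smiles(smiles)
  p <- .parse_smiles(can)
  if (!p$valid[1]) stop("unparseable SMILES: ", smiles, call. = FALSE)
  ids <- .morgan_identifiers(p$graphs[[1]], max_radius)
  # row-major: all radii of atom 1, then atom 2, ... (canonical atom order)
  toks <- as.vector(t(ids))
  sprintf("s%.0f", toks[!is.na(toks)])
}

# sentences for a whole table (NULL-safe, one shared parse)
.table_sentences <- function(table, max_radius = 1) {
  p <- .parse_smiles(table$smiles)
  lapply(seq_len(nrow(table)), function(i) {
    g <- p$graphs[[i]]
    if (is.null(g)) return(character(0))
    ids <- .morgan_identifiers(g, max_radius)
    toks <- as.vector(t(ids))
    sprintf("s%.0f", toks[!is.na(toks)])
  })
}

#' Train substructure embeddings (skip-gram)
#'
#' Trains skip-gram-with-negative-sampling vectors over substructure
#' sentences. Identifiers occurring fewer than \code{min_count} times are
#' excluded from the vocabulary; the UNK vector for out-of-vocabulary
#' lookups is the mean of all trained vectors. Training is single-threaded
#' and bit-reproducible for a fixed seed.
#'
#' @param corpus list of character vectors (sentences), or a
#'   \code{molecule_table} (sentences are generated at \code{max_radius}).
#' @param dimension embedding dimension (default 300, the reference
#'   Mol2Vec setting).
#' @param window context window (default 10).
#' @param min_count vocabulary threshold (default 3).
#' @param epochs training epochs (default 5).
#' @param negative negative samples per positive (default 5).
#' @param lr initial learning rate (default 0.025).
#' @param max_radius sentence radius when corpus is a molecule table.
#' @param seed integer seed.
#' @return an \code{embedding_model}: list with \code{dimension},
#'   \code{vectors} (vocabulary x dimension matrix, rownames =
#'   identifiers), \code{unk_vector} and \code{training_meta}.
#' @export
train_embeddings <- function(corpus, dimension = 300, window = 10,
                             min_count = 3, epochs = 5, negative = 5,
                             lr = 0.025, max_radius = 1, seed = 1L) {
  if (inherits(corpus, "molecule_table")) {
    corpus <- .table_sentences(corpus, max_radius)
  }
  stopifnot(is.list(corpus), length(corpus) >= 1)
  counts <- table(unlist(corpus))
  vocab <- names(counts)[counts >= min_count]
  if (!length(vocab)) {
    stop("training error: empty vocabulary after the min_count filter; ",
         "lower min_count", call. = FALSE)
  }
  idx <- stats::setNames(seq_along(vocab) - 1L, vocab)
  sent_idx <- lapply(corpus, function(s) {
    v <- idx[s[s %in% vocab]]
    as.integer(unname(v))
  })
  sent_idx <- sent_idx[lengths(sent_idx) > 0]
  vecs <- .sgns_train(sent_idx, length(vocab),
                      as.numeric(counts[vocab]), as.integer(dimension),
                      as.integer(window), as.integer(epochs),
                      as.integer(negative), lr, as.integer(seed %% 2^31))
  rownames(vecs) <- vocab
  colnames(vecs) <- paste0("d", seq_len(dimension) - 1)
  structure(list(dimension = as.integer(dimension),
                 vectors = vecs,
                 unk_vector = colMeans(vecs),
                 training_meta = list(window = window, min_count = min_count,
                                      epochs = epochs, negative = negative,
                                      lr = lr, seed = seed,
                                      max_radius = max_radius)),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("Substructure embedding model: ", nrow(x$vectors),
      " identifiers x ", x$dimension, " dimensions\n", sep = "")
  invisible(x)
}

#' Molecule vector by substructure-vector addition
#'
#' The molecule embedding is the sum over sentence tokens of the trained
#' substructure vectors (UNK vector for out-of-vocabulary tokens); an
#' empty sentence yields the zero vector with a warning.
#'
#' @param model an \code{embedding_model}.
#' @param sentence character vector of identifier tokens.
#' @return numeric vector of length \code{model$dimension}.
#' @export
molecule_vector <- function(model, sentence) {
  stopifnot(inherits(model, "embedding_model"))
  if (!length(sentence)) {
    warning("empty sentence: returning the zero vector")
    return(numeric(model$dimension))
  }
  known <- sentence %in% rownames(model$vectors)
  out <- numeric(model$dimension)
  if (any(known)) {
    out <- out + colSums(model$vectors[sentence[known], , drop = FALSE])
  }
  if (any(!known)) {
    out <- out + sum(!known) * model$unk_vector
  }
  unname(out)
}

#' Embed a molecule table
#'
#' @param model an \code{embedding_model}.
#' @param table a \code{molecule_table}.
#' @param max_radius sentence radius (default: the model's training radius).
#' @return matrix with columns \code{Mol2Vec-0 .. Mol2Vec-(d-1)}, one row
#'   per molecule (zero rows, with a warning, where no sentence exists).
#' @export
embed_table <- function(model, table, max_radius = NULL) {
  stopifnot(inherits(model, "embedding_model"),
            inherits(table, "molecule_table"))
  if (is.null(max_radius)) max_radius <- model$training_meta$max_radius
  sentences <- .table_sentences(table, max_radius)
  out <- matrix(0, nrow(table), model$dimension,
                dimnames = list(table$id,
                                paste0("Mol2Vec-",
                                       seq_len(model$dimension) - 1)))
  empty <- lengths(sentences) == 0
  if (any(empty)) warning(sum(empty), " molecule(s) with empty sentences: ",
                          "zero rows")
  for (i in which(!empty)) {
    out[i, ] <- molecule_vector(model, sentences[[i]])
  }
  out
}

#' Persist / restore an embedding model
#'
#' Two-file artifact: JSON metadata plus a tab-separated identifier/vector
#' table.
#'
#' @param model an \code{embedding_model}.
#' @param dir target directory.
#' @export
save_embedding_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(c(list(dimension = model$dimension),
                         model$training_meta),
                       file.path(dir, "embedding_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  tab <- data.frame(identifier = rownames(model$vectors),
                    model$vectors, check.names = FALSE)
  utils::write.table(tab, file.path(dir, "embedding_vectors.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname save_embedding_model
#' @export
load_embedding_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "embedding_meta.json"),
                              simplifyVector = TRUE)
  tab <- utils::read.table(file.path(dir, "embedding_vectors.tsv"),
                           sep = "\t", header = TRUE, check.names = FALSE)
  vecs <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vecs) <- tab$identifier
  structure(list(dimension = as.integer(meta$dimension), vectors = vecs,
                 unk_vector = colMeans(vecs),
                 training_meta = meta[setdiff(names(meta), "dimension")]),
            class = "embedding_model")
}
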