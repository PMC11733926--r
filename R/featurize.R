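# Descriptor blocks and feature-matrix assembly. A feature matrix is a
# plain numeric matrix: rows aligned to the molecule table (rownames = ids),
# unique column names. The default block set concatenates to a base vector
# of ~11,000 columns per molecule.

.known_blocks <- c("morgan_counts", "path_fingerprint", "maccs_keys",
                   "atom_pair_counts", "ecfp_bits", "physchem_descriptors",
                   "element_fractions", "element_property_stats")

#' Descriptor block specification
#'
#' @param block_name one of \code{morgan_counts}, \code{path_fingerprint},
#'   \code{maccs_keys}, \code{atom_pair_counts}, \code{ecfp_bits},
#'   \code{physchem_descriptors}, \code{element_fractions},
#'   \code{element_property_stats}.
#' @param ... block parameters (\code{radius}, \code{n_bits}, ...).
#' @return A \code{descriptor_block_spec} list.
#' @export
descriptor_block_spec <- function(block_name, ...) {
  if (!block_name %in% .known_blocks) {
    stop("config error: unknown block '", block_name, "'", call. = FALSE)
  }
  params <- list(...)
  defaults <- switch(block_name,
    morgan_counts = list(radius = 3, n_bits = 4096),
    ecfp_bits = list(radius = 2, n_bits = 2048),
    atom_pair_counts = list(n_bits = 2048),
    path_fingerprint = list(),
    maccs_keys = list(),
    physchem_descriptors = list(),
    element_fractions = list(),
    element_property_stats = list(property_table = NULL))
  for (nm in names(params)) {
    if (!nm %in% names(defaults)) {
      stop("config error: unknown parameter '", nm, "' for block ",
           block_name, call. = FALSE)
    }
    defaults[[nm]] <- params[[nm]]
  }
  structure(list(block_name = block_name, params = defaults),
            class = "descriptor_block_spec")
}

#' Default descriptor block set
#'
#' The block composition used to build the ~11,000-column base feature
#' vector: count-based Morgan (radius 3, folded to 2048), binary circular
#' fingerprint (radius 2, 2048 bits), path fingerprint (1024 bits), MACCS
#' keys (166), atom-pair counts (2048), physicochemical descriptors,
#' element fractions and element-property statistics.
#'
#' @return list of \code{descriptor_block_spec}.
#' @export
default_block_set <- function() {
  list(descriptor_block_spec("morgan_counts"),
       descriptor_block_spec("ecfp_bits"),
       descriptor_block_spec("path_fingerprint"),
       descriptor_block_spec("maccs_keys"),
       descriptor_block_spec("atom_pair_counts"),
       descriptor_block_spec("physchem_descriptors"),
       descriptor_block_spec("element_fractions"),
       descriptor_block_spec("element_property_stats"))
}

# shared featurization context so blocks parse each molecule once; an
# SDFset is materialized lazily for the OpenBabel-backed blocks (rows with
# at least one bond: ChemmineR cannot represent bond-free connection tables)
.featurize_ctx <- function(table) {
  stopifnot(inherits(table, "molecule_table"))
  if (nrow(table) == 0) stop("empty table", call. = FALSE)
  p <- .parse_smiles(table$smiles)
  sdf_rows <- which(p$valid & vapply(p$graphs, function(g) {
    !is.null(g) && nrow(g$bonds) >= 1
  }, logical(1)))
  e <- new.env(parent = emptyenv())
  ctx <- list(table = table, valid = p$valid, graphs = p$graphs,
              blocks = p$blocks, sdf_rows = sdf_rows, cache = e)
  ctx
}

.ctx_sdf <- function(ctx) {
  if (is.null(ctx$cache$sdf)) {
    lines <- unlist(lapply(ctx$sdf_rows, function(i) {
      c(ctx$blocks[[i]], "$$$$")
    }))
    ctx$cache$sdf <- ChemmineR::read.SDFset(lines)
    ctx$cache$sdf@ID <- paste0("row_", ctx$sdf_rows)
  }
  ctx$cache$sdf
}

.block_matrix <- function(ctx, spec) {
  n <- nrow(ctx$table)
  bn <- spec$block_name
  par <- spec$params
  per_graph <- function(fun, n_cols, names) {
    out <- matrix(NA_real_, n, n_cols, dimnames = list(ctx$table$id, names))
    for (i in seq_len(n)) {
      mg <- ctx$graphs[[i]]
      if (is.null(mg)) next
      row <- tryCatch(fun(mg, i), error = function(e) rep(NA_real_, n_cols))
      if (length(row) == n_cols) out[i, ] <- row
    }
    out
  }
  if (bn == "morgan_counts") {
    nb <- par$n_bits
    per_graph(function(mg, i) .morgan_count_row(mg, par$radius, nb), nb,
              paste0("fm", par$radius, "-", seq_len(nb) - 1))
  } else if (bn == "ecfp_bits") {
    nb <- par$n_bits
    per_graph(function(mg, i) {
      as.numeric(.morgan_count_row(mg, par$radius, nb) > 0)
    }, nb, paste0("ecfp-", seq_len(nb) - 1))
  } else if (bn == "atom_pair_counts") {
    nb <- par$n_bits
    per_graph(function(mg, i) .atom_pair_row(mg, nb), nb,
              paste0("apair-", seq_len(nb) - 1))
  } else if (bn %in% c("path_fingerprint", "maccs_keys")) {
    if (bn == "path_fingerprint") .ob_fingerprint(ctx, "FP2", 1024, "pathfp")
    else .ob_fingerprint(ctx, "MACCS", 166, "maccs")
  } else if (bn == "physchem_descriptors") {
    props <- tryCatch(ChemmineR::propOB(.ctx_sdf(ctx)),
                      error = function(e) NULL)
    first <- which(ctx$valid)[1]
    proto <- .physchem_graph_row(ctx$graphs[[first]], ctx$table$smiles[first])
    gm <- per_graph(function(mg, i) {
      .physchem_graph_row(mg, ctx$table$smiles[i])
    }, length(proto), names(proto))
    ob <- matrix(NA_real_, n, 7,
                 dimnames = list(ctx$table$id,
                                 c("MolLogP", "MolMR", "MolWt", "TPSA",
                                   "NumHAcceptors", "NumHDonors", "NumF")))
    if (!is.null(props) && nrow(props) == length(ctx$sdf_rows)) {
      ob[ctx$sdf_rows, ] <- cbind(as.numeric(props$logP),
                                  as.numeric(props$MR),
                                  as.numeric(props$MW),
                                  as.numeric(props$TPSA),
                                  as.numeric(props$HBA1),
                                  as.numeric(props$HBD),
                                  as.numeric(props$nF))
    }
    cbind(ob, gm)
  } else if (bn == "element_fractions") {
    syms <- .element_fraction_symbols
    per_graph(function(mg, i) {
      fc <- .formula_counts(mg)
      v <- numeric(length(syms)); names(v) <- syms
      common <- intersect(names(fc), syms)
      v[common] <- fc[common]
      v / max(sum(fc), 1)
    }, length(syms), paste0("frac-", syms))
  } else if (bn == "element_property_stats") {
    pt <- par$property_table
    if (is.null(pt)) pt <- element_properties()
    element_property_stats_rows(ctx, pt)
  } else {
    stop("config error: unknown block '", bn, "'", call. = FALSE)
  }
}

# OpenBabel bit fingerprints (path FP2 and MACCS) for a whole context;
# bond-free molecules have no paths and get all-zero rows
.ob_fingerprint <- function(ctx, type, n_keep, prefix) {
  n <- nrow(ctx$table)
  fp <- tryCatch(as.matrix(ChemmineR::fingerprintOB(.ctx_sdf(ctx), type)),
                 error = function(e) NULL)
  nc <- if (is.null(fp)) n_keep else min(n_keep, ncol(fp))
  out <- matrix(NA_real_, n, nc,
                dimnames = list(ctx$table$id,
                                paste0(prefix, "-", seq_len(nc) - 1)))
  out[ctx$valid, ] <- 0
  if (!is.null(fp)) out[ctx$sdf_rows, ] <- fp[, seq_len(nc), drop = FALSE]
  out
}

# element-property statistics rows: per molecule and property, the
# composition-weighted mean/std/min/max/range over atoms (implicit H
# included). Elements absent from the property table contribute missing
# values for that molecule's statistics.
element_property_stats_rows <- function(ctx, pt) {
  props <- setdiff(colnames(pt), "symbol")
  prop_label <- c(group = "group number", period = "period",
                  mass = "atomic mass",
                  electronegativity = "electronegativity",
                  melting_point = "melting point",
                  covalent_radius = "covalent radius",
                  ionization_energy = "ionization energy",
                  valence_electrons = "valence electrons")
  stats <- c("mean", "std", "min", "max", "range")
  cn <- as.vector(outer(stats, props, function(s, p) {
    paste(s, ifelse(p %in% names(prop_label), prop_label[p], p))
  }))
  n <- nrow(ctx$table)
  out <- matrix(NA_real_, n, length(cn), dimnames = list(ctx$table$id, cn))
  for (i in seq_len(n)) {
    mg <- ctx$graphs[[i]]
    if (is.null(mg)) next
    fc <- .formula_counts(mg)
    known <- names(fc) %in% rownames(pt)
    if (!all(known)) next  # element not covered: leave stats missing
    col <- 0
    for (p in props) {
      vals <- rep(pt[names(fc), p], times = fc)
      m <- mean(vals)
      out[i, col + 1:5] <- c(m, sqrt(mean((vals - m)^2)), min(vals),
                             max(vals), max(vals) - min(vals))
      col <- col + 5
    }
  }
  out
}

#' Compute one descriptor block for a molecule table
#'
#' @param table a \code{molecule_table}.
#' @param spec a \code{\link{descriptor_block_spec}} (or a block name).
#' @return numeric feature matrix (rows = molecules, named columns).
#'   Per-molecule descriptor failures yield missing values, handled later
#'   by \code{\link{clean_features}}.
#' @export
featurize_block <- function(table, spec) {
  if (is.character(spec)) spec <- descriptor_block_spec(spec)
  stopifnot(inherits(spec, "descriptor_block_spec"))
  ctx <- .featurize_ctx(table)
  .block_matrix(ctx, spec)
}

#' Element-property statistic features
#'
#' @param table a \code{molecule_table}.
#' @param property_table data.frame of per-element properties with element
#'   symbols as rownames (default \code{\link{element_properties}}).
#' @return numeric matrix with columns "<stat> <property>" (e.g.
#'   "mean melting point", "std group number").
#' @export
element_property_stats <- function(table, property_table = NULL) {
  if (is.null(property_table)) property_table <- element_properties()
  ctx <- .featurize_ctx(table)
  element_property_stats_rows(ctx, property_table)
}

#' Concatenate descriptor blocks
#'
#' @param blocks list of feature matrices sharing row alignment.
#' @return single feature matrix; duplicate column names across blocks are
#'   repaired by prefixing the block index and reported via a message.
#' @export
concat_blocks <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  nr <- vapply(blocks, nrow, integer(1))
  if (length(unique(nr)) != 1) {
    stop("alignment error: blocks have differing row counts", call. = FALSE)
  }
  out <- do.call(cbind, blocks)
  dup <- duplicated(colnames(out))
  if (any(dup)) {
    message("renamed ", sum(dup), " duplicated column name(s) across blocks")
    colnames(out)[dup] <- paste0("block", cumsum(dup)[dup], ".",
                                 colnames(out)[dup])
  }
  out
}

#' Clean a feature matrix
#'
#' Drops all-missing and zero-variance columns, imputes columns whose
#' missing fraction is at most \code{max_missing_fraction} (median policy
#' by default) and drops the rest. The result is fully finite; the drop
#' report is attached as attribute \code{"drop_report"}.
#'
#' @param X feature matrix.
#' @param max_missing_fraction maximum tolerated missing fraction (default 0.2).
#' @param impute "median" or "zero".
#' @return cleaned numeric matrix.
#' @export
clean_features <- function(X, max_missing_fraction = 0.2,
                           impute = c("median", "zero")) {
  impute <- match.arg(impute)
  X[!is.finite(X)] <- NA_real_
  miss <- colMeans(is.na(X))
  report <- list(all_missing = colnames(X)[miss == 1],
                 too_missing = colnames(X)[miss > max_missing_fraction &
                                             miss < 1],
                 zero_variance = character(0),
                 imputed = colnames(X)[miss > 0 &
                                         miss <= max_missing_fraction])
  keep <- miss <= max_missing_fraction
  X <- X[, keep, drop = FALSE]
  for (jj in which(colMeans(is.na(X)) > 0)) {
    v <- X[, jj]
    fill <- if (impute == "median") stats::median(v, na.rm = TRUE) else 0
    if (!is.finite(fill)) fill <- 0
    X[is.na(v), jj] <- fill
  }
  vars <- apply(X, 2, stats::var)
  zv <- !is.finite(vars) | vars <= 0
  report$zero_variance <- colnames(X)[zv]
  X <- X[, !zv, drop = FALSE]
  if (ncol(X) == 0) stop("empty matrix: all columns dropped", call. = FALSE)
  .check_finite(X)
  attr(X, "drop_report") <- report
  X
}

#' Featurize a molecule table
#'
#' Computes every block in \code{blocks} on a single shared parse of the
#' table and concatenates the results. With the default block set the raw
#' width is ~11,000 columns; pass \code{clean = TRUE} to apply
#' \code{\link{clean_features}} afterwards.
#'
#' @param table a \code{molecule_table}.
#' @param blocks list of block specs (default \code{\link{default_block_set}}).
#' @param clean drop/impute unusable columns (default TRUE).
#' @param max_missing_fraction forwarded to \code{\link{clean_features}}.
#' @return numeric feature matrix.
#' @export
featurize <- function(table, blocks = default_block_set(), clean = TRUE,
                      max_missing_fraction = 0.2) {
  ctx <- .featurize_ctx(table)
  mats <- lapply(blocks, function(spec) {
    if (is.character(spec)) spec <- descriptor_block_spec(spec)
    .block_matrix(ctx, spec)
  })
  X <- concat_blocks(mats)
  if (clean) X <- clean_features(X, max_missing_fraction) else X
}
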