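# SMILES parsing, canonicalization and the internal molecular-graph
# representation. Conversions go through ChemmineOB (OpenBabel); the V2000
# connection tables it emits are parsed here directly, because OpenBabel is
# lenient about malformed SMILES (it silently "repairs" strings like "C(")
# and aborts whole batches on hard errors. A syntactic validator therefore
# screens inputs first, and batch conversions are mapped back by title.

# light syntactic SMILES check: allowed tokens, balanced parentheses and
# brackets, paired ring-closure digits
.smiles_syntax_ok <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    if (grepl("\\s", s)) return(FALSE)
    nob <- gsub("\\[[A-Za-z0-9@+*:-]+\\]", "A", s)
    if (grepl("[][]", nob)) return(FALSE)          # unbalanced brackets
    rest <- gsub("Cl|Br|Si|Se|@|%[0-9]{2}", "", nob)
    if (grepl("[^ABCNOPSFIbcnops0-9()=#$:/.+\\\\~-]", rest)) return(FALSE)
    open <- 0
    for (ch in strsplit(nob, "")[[1]]) {
      if (ch == "(") open <- open + 1
      if (ch == ")") { open <- open - 1; if (open < 0) return(FALSE) }
    }
    if (open != 0) return(FALSE)
    digits <- strsplit(gsub("%[0-9]{2}|[^0-9]", "", rest), "")[[1]]
    if (length(digits) && any(table(digits) %% 2 != 0)) return(FALSE)
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

# split a multi-molecule SDF string into per-record line vectors keyed by title
.split_sdf_text <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  ends <- which(lines == "$$$$")
  start <- 1
  out <- list()
  for (e in ends) {
    rec <- lines[start:(e - 1)]
    if (length(rec) >= 4) out[[trimws(rec[1])]] <- rec
    start <- e + 1
  }
  out
}

# Convert SMILES to molblocks via OpenBabel, robust to individual failures.
# Returns a list parallel to the input (NULL where conversion failed).
.molblock_list <- function(smiles) {
  n <- length(smiles)
  blocks <- vector("list", n)
  ok <- .smiles_syntax_ok(smiles)
  idx <- which(ok)
  if (!length(idx)) return(blocks)
  inp <- paste0(smiles[idx], " t", idx, collapse = "\n")
  txt <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", inp),
                  error = function(e) "")
  recs <- .split_sdf_text(txt)
  got <- match(paste0("t", idx), names(recs))
  for (k in seq_along(idx)) {
    if (!is.na(got[k])) blocks[[idx[k]]] <- recs[[got[k]]]
  }
  # anything the batch dropped (OpenBabel aborts on hard errors): retry singly
  for (i in idx[is.na(got)]) {
    txt <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF",
                                              paste0(smiles[i], " t", i)),
                    error = function(e) "")
    recs <- .split_sdf_text(txt)
    if (paste0("t", i) %in% names(recs)) blocks[[i]] <- recs[[paste0("t", i)]]
  }
  blocks
}

# decode the MDL ctab charge column (0 none, 1..3 => +3..+1, 5..7 => -1..-3)
.decode_ctab_charge <- function(code) {
  ch <- integer(length(code))
  pos <- code >= 1 & code <= 3
  neg <- code >= 5 & code <= 7
  ch[pos] <- 4L - code[pos]
  ch[neg] <- -(code[neg] - 4L)
  ch
}

# Build the internal molecular graph from V2000 molblock lines (heavy atoms
# only). Fields: n, symbol, charge, nH (implicit hydrogens), degree,
# bondsum, bonds (i, j, order), in_ring.
.graph_from_molblock <- function(rec) {
  counts <- rec[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || na < 1) return(NULL)
  atom_lines <- rec[4 + seq_len(na)]
  symbol <- trimws(substr(atom_lines, 32, 34))
  charge <- .decode_ctab_charge(suppressWarnings(
    as.integer(substr(atom_lines, 37, 39))))
  charge[is.na(charge)] <- 0L
  if (is.na(nb)) nb <- 0L
  if (nb > 0) {
    bond_lines <- rec[4 + na + seq_len(nb)]
    bonds <- cbind(i = as.integer(substr(bond_lines, 1, 3)),
                   j = as.integer(substr(bond_lines, 4, 6)),
                   order = as.integer(substr(bond_lines, 7, 9)))
  } else {
    bonds <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("i", "j", "order")))
  }
  # modern charge annotation overrides the ctab column
  for (ln in grep("^M  CHG", rec, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    k <- f[1]
    for (p in seq_len(k)) charge[f[2 * p]] <- f[2 * p + 1]
  }
  degree <- tabulate(c(bonds[, "i"], bonds[, "j"]), nbins = na)
  bondsum <- numeric(na)
  if (nrow(bonds)) for (r in seq_len(nrow(bonds))) {
    o <- bonds[r, "order"]
    bondsum[bonds[r, "i"]] <- bondsum[bonds[r, "i"]] + o
    bondsum[bonds[r, "j"]] <- bondsum[bonds[r, "j"]] + o
  }
  valence <- .default_valence[symbol]
  valence[is.na(valence)] <- 0
  nH <- pmax(0, valence + charge - bondsum)
  in_ring <- rep(FALSE, na)
  ring_edge <- integer(0)
  n_comp <- na
  if (nrow(bonds)) {
    g <- .as_igraph(bonds, na)
    br <- as.integer(igraph::bridges(g))
    ring_edge <- setdiff(seq_len(nrow(bonds)), br)
    in_ring[unique(c(bonds[ring_edge, "i"], bonds[ring_edge, "j"]))] <- TRUE
    n_comp <- igraph::components(g)$no
  }
  list(n = na, symbol = symbol, charge = charge, nH = as.numeric(nH),
       degree = degree, bondsum = bondsum, bonds = bonds, in_ring = in_ring,
       ring_edge = ring_edge, n_components = n_comp, molblock = rec)
}

.as_igraph <- function(bonds, n) {
  g <- igraph::graph_from_edgelist(bonds[, 1:2, drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

# Parse SMILES into molecular graphs. Returns list(graphs, valid, blocks).
.parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  blocks <- .molblock_list(smiles)
  graphs <- lapply(blocks, function(b) {
    if (is.null(b)) NULL else .graph_from_molblock(b)
  })
  valid <- !vapply(graphs, is.null, logical(1))
  list(graphs = graphs, valid = valid, blocks = blocks)
}

# topological (bond-count) distance matrix of a mol graph
.mol_distances <- function(mg) {
  if (mg$n == 1 || nrow(mg$bonds) == 0) {
    d <- matrix(Inf, mg$n, mg$n); diag(d) <- 0
    return(d)
  }
  igraph::distances(.as_igraph(mg$bonds, mg$n))
}

#' Canonicalize SMILES strings
#'
#' Maps every way of writing a molecule to a single canonical SMILES string
#' (OpenBabel canonical form), so that e.g. \code{"OCC"} and \code{"CCO"}
#' become identical. Canonicalization is idempotent.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @export
canonicalize_smiles <- function(smiles) {
  ok <- .smiles_syntax_ok(smiles)
  if (!all(ok)) {
    stop("unparseable SMILES: ",
         paste(utils::head(smiles[!ok], 5L), collapse = ", "), call. = FALSE)
  }
  inp <- paste0(smiles, " t", seq_along(smiles), collapse = "\n")
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", inp),
                  error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  can <- rep(NA_character_, length(smiles))
  for (p in parts) {
    if (length(p) >= 2) {
      i <- suppressWarnings(as.integer(sub("^t", "", trimws(p[2]))))
      if (!is.na(i)) can[i] <- p[1]
    }
  }
  if (anyNA(can)) {
    stop("unparseable SMILES: ",
         paste(utils::head(smiles[is.na(can)], 5L), collapse = ", "),
         call. = FALSE)
  }
  can
}

# canonical SMILES of a molblock record
.molblock_to_smiles <- function(rec) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN",
                              paste0(c(rec, "$$$$"), collapse = "\n")),
    error = function(e) "")
  sub("\t.*$", "", strsplit(out, "\n", fixed = TRUE)[[1]][1])
}

# molblock text for a subset of a graph's atoms (fresh valences become
# implicit hydrogens)
.subgraph_molblock <- function(mg, keep) {
  idx <- which(keep)
  remap <- match(seq_len(mg$n), idx)
  bsel <- mg$bonds[mg$bonds[, 1] %in% idx & mg$bonds[, 2] %in% idx, ,
                   drop = FALSE]
  na <- length(idx); nb <- nrow(bsel)
  fmt <- function(x) formatC(x, width = 3)
  lines <- c("gbfs", "", "",
             paste0(fmt(na), fmt(nb), "  0  0  0  0  0  0  0  0999 V2000"))
  for (k in idx) {
    lines <- c(lines, paste0(sprintf("%10.4f%10.4f%10.4f ", 0, 0, 0),
                             formatC(mg$symbol[k], width = -3),
                             " 0  0  0  0  0  0  0  0  0  0  0  0"))
  }
  if (nb > 0) for (k in seq_len(nb)) {
    lines <- c(lines, paste0(fmt(remap[bsel[k, 1]]), fmt(remap[bsel[k, 2]]),
                             fmt(bsel[k, 3]), "  0  0  0  0"))
  }
  c(lines, "M  END")
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Reduces a molecule to its ring systems plus the linkers connecting them,
#' with side chains removed (substituents double- or triple-bonded to the
#' retained core are kept, following the usual convention for exocyclic
#' carbonyls). Acyclic molecules have an empty scaffold and return \code{""}.
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of canonical scaffold SMILES (\code{""} for
#'   ring-free molecules).
#' @export
murcko_scaffold <- function(smiles) {
  p <- .parse_smiles(smiles)
  if (!all(p$valid)) {
    stop("unparseable SMILES: ",
         paste(utils::head(smiles[!p$valid], 5L), collapse = ", "),
         call. = FALSE)
  }
  out <- character(length(smiles))
  for (m in seq_along(smiles)) {
    mg <- p$graphs[[m]]
    if (!any(mg$in_ring)) { out[m] <- ""; next }
    # ring systems + linkers = the 2-core: iteratively strip terminal atoms
    keep <- rep(TRUE, mg$n)
    repeat {
      deg <- numeric(mg$n)
      if (nrow(mg$bonds)) for (r in seq_len(nrow(mg$bonds))) {
        i <- mg$bonds[r, "i"]; j <- mg$bonds[r, "j"]
        if (keep[i] && keep[j]) { deg[i] <- deg[i] + 1; deg[j] <- deg[j] + 1 }
      }
      drop <- keep & deg <= 1
      if (!any(drop)) break
      keep[drop] <- FALSE
    }
    # retain substituents double/triple-bonded to the core (exocyclic =O etc.)
    if (nrow(mg$bonds)) for (r in seq_len(nrow(mg$bonds))) {
      if (mg$bonds[r, "order"] > 1) {
        i <- mg$bonds[r, "i"]; j <- mg$bonds[r, "j"]
        if (keep[i] && !keep[j] && mg$degree[j] == 1) keep[j] <- TRUE
        if (keep[j] && !keep[i] && mg$degree[i] == 1) keep[i] <- TRUE
      }
    }
    out[m] <- .molblock_to_smiles(.subgraph_molblock(mg, keep))
  }
  out
}
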