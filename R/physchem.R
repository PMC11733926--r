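# Physicochemical descriptor block: OpenBabel bulk properties (Crippen-style
# logP, molar refractivity, TPSA, H-bond counts) plus graph-derived indices
# and hand-coded functional-group counts. Column names follow the
# conventional descriptor vocabulary (MolLogP, fr-COO, BalabanJ, ...).

# adjacency list with bond orders: per atom a matrix with columns (order, j)
.nbr_list <- function(mg) {
  nbr <- vector("list", mg$n)
  if (nrow(mg$bonds)) for (r in seq_len(nrow(mg$bonds))) {
    i <- mg$bonds[r, "i"]; j <- mg$bonds[r, "j"]; o <- mg$bonds[r, "order"]
    nbr[[i]] <- rbind(nbr[[i]], c(o, j))
    nbr[[j]] <- rbind(nbr[[j]], c(o, i))
  }
  nbr
}

# functional-group counts from the kekulized molecular graph
.fr_counts <- function(mg) {
  nbr <- .nbr_list(mg)
  sym <- mg$symbol
  ords <- function(a) if (is.null(nbr[[a]])) numeric(0) else nbr[[a]][, 1]
  js   <- function(a) if (is.null(nbr[[a]])) integer(0) else nbr[[a]][, 2]
  fr <- c("fr-COO" = 0, "fr-Ar-OH" = 0, "fr-OH" = 0, "fr-NH2" = 0,
          "fr-NH1" = 0, "fr-NH0" = 0, "fr-ester" = 0, "fr-ether" = 0,
          "fr-amide" = 0, "fr-ketone" = 0, "fr-aldehyde" = 0,
          "fr-nitrile" = 0, "fr-nitro" = 0, "fr-sulfone" = 0,
          "fr-SH" = 0, "fr-halogen" = 0)
  fr["fr-halogen"] <- sum(sym %in% c("F", "Cl", "Br", "I"))
  for (a in seq_len(mg$n)) {
    o <- ords(a); j <- js(a); sj <- sym[j]
    if (sym[a] == "C") {
      dblO <- j[o == 2 & sj == "O"]
      sngO <- j[o == 1 & sj == "O"]
      sngC <- j[o == 1 & sj == "C"]
      if (length(dblO) == 1) {
        acidO <- sngO[mg$nH[sngO] > 0 | mg$charge[sngO] < 0]
        esterO <- sngO[mg$nH[sngO] == 0 & mg$charge[sngO] == 0 &
                         mg$degree[sngO] == 2]
        if (length(acidO) > 0) fr["fr-COO"] <- fr["fr-COO"] + 1
        else if (length(esterO) > 0) fr["fr-ester"] <- fr["fr-ester"] + 1
        else if (any(o == 1 & sj == "N")) fr["fr-amide"] <- fr["fr-amide"] + 1
        else if (length(sngC) == 2) fr["fr-ketone"] <- fr["fr-ketone"] + 1
        else if (mg$nH[a] >= 1) fr["fr-aldehyde"] <- fr["fr-aldehyde"] + 1
      }
      if (any(o == 3 & sj == "N")) fr["fr-nitrile"] <- fr["fr-nitrile"] + 1
    } else if (sym[a] == "O") {
      if (mg$nH[a] > 0 && length(j) == 1 && sj == "C") {
        carb <- any(ords(j)[sym[js(j)] == "O"] == 2)
        if (!carb) {
          fr["fr-OH"] <- fr["fr-OH"] + 1
          if (mg$in_ring[j]) fr["fr-Ar-OH"] <- fr["fr-Ar-OH"] + 1
        }
      }
      if (mg$degree[a] == 2 && mg$nH[a] == 0 && all(o == 1) &&
          all(sj == "C")) {
        carb <- any(vapply(j, function(b) {
          any(ords(b) == 2 & sym[js(b)] == "O")
        }, logical(1)))
        if (!carb) fr["fr-ether"] <- fr["fr-ether"] + 1
      }
    } else if (sym[a] == "N") {
      dblO <- sum(o == 2 & sj == "O")
      anyO <- sum(sj == "O")
      if ((dblO >= 1 && anyO >= 2) || (mg$charge[a] > 0 && anyO >= 2)) {
        fr["fr-nitro"] <- fr["fr-nitro"] + 1
      } else if (all(o == 1) && !mg$in_ring[a]) {
        amide <- any(vapply(j, function(b) {
          sym[b] == "C" && any(ords(b) == 2 & sym[js(b)] == "O")
        }, logical(1)))
        if (!amide) {
          if (mg$nH[a] >= 2) fr["fr-NH2"] <- fr["fr-NH2"] + 1
          else if (mg$nH[a] == 1) fr["fr-NH1"] <- fr["fr-NH1"] + 1
          else fr["fr-NH0"] <- fr["fr-NH0"] + 1
        }
      }
    } else if (sym[a] == "S") {
      if (mg$nH[a] > 0) fr["fr-SH"] <- fr["fr-SH"] + 1
      if (sum(o == 2 & sj == "O") >= 2) fr["fr-sulfone"] <- fr["fr-sulfone"] + 1
    }
  }
  fr
}

# count aromatic atoms from a canonical SMILES string (bracket-aware)
.aromatic_atom_count <- function(can_smiles) {
  toks <- gregexpr("\\[[^]]*\\]|Cl|Br|Si|Se|[BCNOPSFI]|[cnops]|se",
                   can_smiles)[[1]]
  m <- regmatches(can_smiles, list(toks))[[1]]
  arom <- grepl("^(\\[[^]]*[cnops][^]]*\\]|[cnops]|se)$", m) &
    !grepl("^(Cl|Br|Si|Se)$", m)
  sum(arom)
}

# per-molecule physicochemical descriptor row (graph part)
.physchem_graph_row <- function(mg, can_smiles) {
  dmat <- .mol_distances(mg)
  est <- .estate_indices(mg, dmat)
  nC <- sum(mg$symbol == "C")
  csp3 <- if (nC == 0) 0 else {
    sum(mg$symbol == "C" & mg$bondsum == mg$degree + 0) / nC
  }
  rot <- 0
  if (nrow(mg$bonds)) {
    bridge_edges <- setdiff(seq_len(nrow(mg$bonds)), mg$ring_edge)
    for (r in bridge_edges) {
      i <- mg$bonds[r, "i"]; j <- mg$bonds[r, "j"]
      if (mg$bonds[r, "order"] == 1 && mg$degree[i] >= 2 && mg$degree[j] >= 2)
        rot <- rot + 1
    }
  }
  fc <- .formula_counts(mg)
  c(HeavyAtomCount = mg$n,
    NumRings = max(0, nrow(mg$bonds) - mg$n + mg$n_components),
    NumAromaticAtoms = .aromatic_atom_count(can_smiles),
    FractionCSP3 = csp3,
    NumRotatableBonds = rot,
    BalabanJ = .balaban_j(mg, dmat),
    Ipc = .ipc(mg),
    Chi0 = .chi0(mg),
    Chi1 = .chi1(mg),
    MaxEStateIndex = if (length(est)) max(est) else 0,
    MinEStateIndex = if (length(est)) min(est) else 0,
    MaxAbsEStateIndex = if (length(est)) max(abs(est)) else 0,
    MeanEStateIndex = if (length(est)) mean(est) else 0,
    NumN = sum(mg$symbol == "N"),
    NumO = sum(mg$symbol == "O"),
    NumS = sum(mg$symbol == "S"),
    NumHeteroatoms = sum(!mg$symbol %in% c("C", "H")),
    NumHTotal = sum(mg$nH) + sum(mg$symbol == "H"),
    .fr_counts(mg))
}

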