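# Circular (Morgan/ECFP-style) substructure identifiers, atom-pair codes
# and topological indices, computed on the internal molecular graph.

.atomic_number <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7,
                    O = 8, F = 9, Na = 11, Mg = 12, Al = 13, Si = 14,
                    P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26,
                    Cu = 29, Zn = 30, Se = 34, Br = 35, I = 53)

.z_of <- function(symbol) {
  z <- .atomic_number[symbol]
  z[is.na(z)] <- 0
  unname(z)
}

# Morgan-style circular identifiers: one integer id per atom per radius
# 0..max_radius. Radius-0 ids hash the atom invariant (atomic number,
# heavy degree, implicit H count, formal charge, ring membership); each
# further radius re-hashes the previous id together with the sorted
# (bond order, neighbour id) list, so identifiers are independent of atom
# input order. Returns an n_atoms x (max_radius + 1) matrix; NA where no
# environment exists (isolated atoms at radius >= 1).
.morgan_identifiers <- function(mg, max_radius = 2) {
  n <- mg$n
  ids <- matrix(NA_real_, n, max_radius + 1)
  z <- .z_of(mg$symbol)
  for (a in seq_len(n)) {
    ids[a, 1] <- .hash_ints(c(z[a], mg$degree[a], mg$nH[a],
                              mg$charge[a] + 4, as.integer(mg$in_ring[a])))
  }
  if (max_radius == 0 || nrow(mg$bonds) == 0) return(ids)
  nbr <- vector("list", n)
  for (r in seq_len(nrow(mg$bonds))) {
    i <- mg$bonds[r, "i"]; j <- mg$bonds[r, "j"]; o <- mg$bonds[r, "order"]
    nbr[[i]] <- rbind(nbr[[i]], c(o, j))
    nbr[[j]] <- rbind(nbr[[j]], c(o, i))
  }
  for (rad in seq_len(max_radius)) {
    prev <- ids[, rad]
    for (a in seq_len(n)) {
      nb <- nbr[[a]]
      if (is.null(nb)) next  # isolated atom: no environment at this radius
      pairs <- cbind(nb[, 1], prev[nb[, 2]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      ids[a, rad + 1] <- .hash_ints(c(rad, prev[a], t(pairs)))
    }
  }
  ids
}

# all circular identifiers of a molecule (vector, NA removed)
.morgan_id_vector <- function(mg, max_radius) {
  v <- as.vector(.morgan_identifiers(mg, max_radius))
  v[!is.na(v)]
}

# folded count fingerprint over circular identifiers of radii 0..radius
.morgan_count_row <- function(mg, radius, n_bits) {
  v <- .morgan_id_vector(mg, radius)
  tabulate((v %% n_bits) + 1, nbins = n_bits)
}

# atom-pair codes: hash of (sorted atom types, topological distance);
# type = (atomic number, heavy degree)
.atom_pair_row <- function(mg, n_bits, max_dist = 30) {
  out <- numeric(n_bits)
  if (mg$n < 2) return(out)
  d <- .mol_distances(mg)
  z <- .z_of(mg$symbol)
  type <- z * 8 + pmin(mg$degree, 7)
  for (i in seq_len(mg$n - 1)) {
    for (j in seq((i + 1), mg$n)) {
      dij <- d[i, j]
      if (!is.finite(dij) || dij > max_dist) next
      tt <- sort(c(type[i], type[j]))
      code <- .hash_ints(c(tt, dij)) %% n_bits
      out[code + 1] <- out[code + 1] + 1
    }
  }
  out
}

# ---- topological indices ----------------------------------------------------

# Balaban J = q/(mu+1) * sum over edges 1/sqrt(s_i s_j), s = distance row sums
.balaban_j <- function(mg, d = NULL) {
  q <- nrow(mg$bonds)
  if (q == 0 || mg$n < 2) return(0)
  if (is.null(d)) d <- .mol_distances(mg)
  if (any(!is.finite(d))) d[!is.finite(d)] <- mg$n  # disconnected guard
  s <- rowSums(d)
  mu <- q - mg$n + 1
  acc <- 0
  for (r in seq_len(q)) {
    acc <- acc + 1 / sqrt(s[mg$bonds[r, "i"]] * s[mg$bonds[r, "j"]])
  }
  q / (mu + 1) * acc
}

# Information content of the characteristic-polynomial coefficients of the
# adjacency matrix (hydrogen-suppressed graph); reported on a log scale to
# keep the magnitude usable as a feature.
.ipc <- function(mg) {
  if (mg$n < 2) return(0)
  A <- matrix(0, mg$n, mg$n)
  if (nrow(mg$bonds)) {
    A[mg$bonds[, 1:2, drop = FALSE]] <- 1
    A[mg$bonds[, 2:1, drop = FALSE]] <- 1
  }
  # characteristic polynomial coefficients via eigenvalues
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  co <- 1
  for (l in ev) co <- c(co, 0) - c(0, co * l)
  a <- abs(co)
  a <- a[a > 1e-12]
  s <- sum(a)
  tot <- s * log2(s) - sum(a * log2(a))
  log1p(max(tot, 0))
}

# Kier-Hall electrotopological state indices per atom
.estate_indices <- function(mg, dmat = NULL) {
  if (mg$n == 0) return(numeric(0))
  z <- .z_of(mg$symbol)
  zv <- mg$nH * 0
  ep <- element_properties()
  zv <- ifelse(mg$symbol %in% rownames(ep),
               ep[mg$symbol, "valence_electrons"], 4)
  delta <- pmax(mg$degree, 1)
  deltav <- pmax(zv - mg$nH, 1)
  period <- ifelse(mg$symbol %in% rownames(ep), ep[mg$symbol, "period"], 2)
  intrinsic <- ((2 / period)^2 * deltav + 1) / delta
  if (is.null(dmat)) dmat <- .mol_distances(mg)
  d <- dmat + 1
  d[!is.finite(d)] <- mg$n + 1
  s <- intrinsic
  for (i in seq_len(mg$n)) {
    s[i] <- intrinsic[i] + sum((intrinsic[i] - intrinsic[-i]) / d[i, -i]^2)
  }
  s
}

# simple connectivity chi indices
.chi0 <- function(mg) sum(1 / sqrt(pmax(mg$degree, 1)))
.chi1 <- function(mg) {
  if (nrow(mg$bonds) == 0) return(0)
  sum(1 / sqrt(pmax(mg$degree[mg$bonds[, "i"]], 1) *
               pmax(mg$degree[mg$bonds[, "j"]], 1)))
}

# molecular formula (with implicit hydrogens) as a named count vector
.formula_counts <- function(mg) {
  counts <- table(mg$symbol)
  out <- as.numeric(counts)
  names(out) <- names(counts)
  nh <- sum(mg$nH)
  if (nh > 0) out["H"] <- (if ("H" %in% names(out)) out["H"] else 0) + nh
  out
}
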