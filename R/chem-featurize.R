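# SMILES featurization: attributed molecular graphs and extended-connectivity
# (Morgan) fingerprints. Structure perception (parsing, canonicalization,
# aromaticity, hybridization, hydrogen counting) is delegated to Open Babel
# through ChemmineOB; the ECFP hashing scheme is implemented here.

# Element vocabulary for the one-hot block of the atom-feature scheme. The
# 44-symbol list mirrors the common convolutional featurizer vocabulary used
# for drug-like molecules; anything else falls into the trailing "other" slot.
ATOM_ELEMENTS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb", "other"
)
HYBRIDIZATIONS <- c("sp", "sp2", "sp3", "sp3d", "sp3d2")

# Atomic numbers for the initial fingerprint invariants.
.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Al = 13,
  Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Ti = 22, V = 23,
  Cr = 24, Mn = 25, Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30, Ge = 32,
  As = 33, Se = 34, Br = 35, Zr = 40, Pd = 46, Ag = 47, Cd = 48, In = 49,
  Sn = 50, Sb = 51, I = 53, Yb = 70, Pt = 78, Au = 79, Hg = 80, Tl = 81,
  Pb = 82, Li = 3
)

ob_convert <- function(from, to, source, options = NULL) {
  out <- tryCatch({
    if (is.null(options)) {
      suppressWarnings(ChemmineOB::convertFormat(from, to, source = source))
    } else {
      suppressWarnings(ChemmineOB::convertFormat(from, to, source = source,
                                                 options = options))
    }
  }, error = function(e) "")
  if (length(out) == 0L) "" else out
}

#' Canonicalize a SMILES string
#'
#' Converts any valid SMILES dialect (kekulized, reordered, with explicit
#' hydrogens) to Open Babel's canonical aromatic form, so that identical
#' molecules always map to identical featurizations.
#'
#' @param smiles A single SMILES string.
#' @param strip_salts If `TRUE` (default), multi-fragment inputs (salts,
#'   mixtures) are reduced to their largest fragment by heavy-atom count;
#'   a message is emitted when this happens.
#' @return The canonical SMILES string.
#' @export
canonicalize_smiles <- function(smiles, strip_salts = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(trimws(smiles))) {
    stop("featurization error: empty SMILES input")
  }
  out <- ob_convert("SMI", "CAN", paste0(smiles, "\n"))
  can <- trimws(sub("\t.*$", "", out))
  if (!nzchar(can)) {
    stop("featurization error: unparsable SMILES '", smiles, "'")
  }
  if (strip_salts && grepl(".", can, fixed = TRUE)) {
    frags <- strsplit(can, ".", fixed = TRUE)[[1]]
    sizes <- vapply(frags, function(f) {
      nchar(gsub("[^A-Za-z]", "", f))
    }, numeric(1))
    can <- frags[[which.max(sizes)]]
    message("multi-fragment SMILES '", smiles,
            "': keeping largest fragment '", can, "'")
    can <- canonicalize_smiles(can, strip_salts = FALSE)
  }
  can
}

# Parse Open Babel's V2000 ctab (with explicit hydrogens added) and MOL2
# output for one canonical SMILES. Returns elements, bonds, formal charges,
# aromatic flags, hybridization, hydrogen counts -- the raw perception the
# featurizers build on.
perceive_molecule <- function(can) {
  # gen2D: writing ctabs without coordinates triggers an Open Babel warning
  sdf <- ob_convert("SMI", "SDF", paste0(can, "\n"),
                    options = data.frame(names = c("h", "gen2D"),
                                         args = c("", ""),
                                         stringsAsFactors = FALSE))
  if (!nzchar(sdf)) stop("featurization error: unparsable SMILES '", can, "'")
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  counts <- lines[4L]
  n_at <- as.integer(substr(counts, 1L, 3L))
  n_bd <- as.integer(substr(counts, 4L, 6L))
  if (is.na(n_at) || n_at < 1L) {
    stop("featurization error: no atoms parsed from '", can, "'")
  }
  atom_lines <- lines[5:(4 + n_at)]
  elements_all <- trimws(substr(atom_lines, 32L, 34L))
  bonds_all <- if (n_bd > 0L) {
    bl <- lines[(5 + n_at):(4 + n_at + n_bd)]
    cbind(as.integer(substr(bl, 1L, 3L)),
          as.integer(substr(bl, 4L, 6L)),
          as.integer(substr(bl, 7L, 9L)))
  } else {
    matrix(integer(0), 0L, 3L)
  }
  charges <- integer(n_at)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1L]
    for (j in seq_len(k)) {
      charges[f[2L * j]] <- f[2L * j + 1L]
    }
  }

  heavy <- which(elements_all != "H")
  if (length(heavy) == 0L) {
    stop("featurization error: no heavy atoms in '", can, "'")
  }
  if (!identical(heavy, seq_along(heavy))) {
    stop("featurization error: unexpected atom ordering for '", can, "'")
  }
  n <- length(heavy)

  # Hydrogen count and heavy-atom bond list.
  n_h <- integer(n)
  hb <- matrix(integer(0), 0L, 3L)
  for (i in seq_len(nrow(bonds_all))) {
    u <- bonds_all[i, 1L]; w <- bonds_all[i, 2L]; o <- bonds_all[i, 3L]
    uh <- elements_all[u] == "H"; wh <- elements_all[w] == "H"
    if (uh && wh) next
    if (uh) { n_h[w] <- n_h[w] + 1L; next }
    if (wh) { n_h[u] <- n_h[u] + 1L; next }
    hb <- rbind(hb, c(min(u, w), max(u, w), o))
  }

  # MOL2 for aromaticity and hybridization; the heavy-atom order matches the
  # SDF conversion because both parse the same canonical SMILES.
  mol2 <- ob_convert("SMI", "MOL2", paste0(can, "\n"),
                     options = data.frame(names = "gen2D", args = "",
                                          stringsAsFactors = FALSE))
  m2 <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  a0 <- which(m2 == "@<TRIPOS>ATOM")
  b0 <- which(m2 == "@<TRIPOS>BOND")
  atom_rows <- m2[(a0 + 1L):(b0 - 1L)]
  fields <- lapply(strsplit(trimws(atom_rows), "\\s+"), identity)
  m2_elem <- vapply(fields, function(f) sub("\\..*$", "", f[6L]), character(1))
  m2_type <- vapply(fields, function(f) f[6L], character(1))
  if (!identical(m2_elem[seq_len(n)], elements_all[seq_len(n)])) {
    stop("featurization error: perception mismatch for '", can, "'")
  }
  suffix <- sub("^[^.]*\\.?", "", m2_type[seq_len(n)])
  aromatic <- suffix == "ar"
  # aromatic bonds can involve atoms typed otherwise (e.g., N.pl3 in pyrrole)
  m2_bonds <- m2[(b0 + 1L):length(m2)]
  m2_bonds <- m2_bonds[nzchar(trimws(m2_bonds))]
  for (ln in m2_bonds) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (identical(f[4L], "ar")) {
      u <- as.integer(f[2L]); w <- as.integer(f[3L])
      if (u <= n) aromatic[u] <- TRUE
      if (w <= n) aromatic[w] <- TRUE
    }
  }
  hyb <- vapply(suffix, function(s) {
    switch(s,
      "1" = "sp", "2" = "sp2", "ar" = "sp2", "am" = "sp2", "pl3" = "sp2",
      "cat" = "sp2", "co2" = "sp2", "3" = "sp3", "4" = "sp3",
      "o" = "sp3", "o2" = "sp3", "t" = "sp3", "other"
    )
  }, character(1), USE.NAMES = FALSE)

  list(
    n = n,
    elements = elements_all[seq_len(n)],
    bonds = hb,                 # heavy-heavy bonds: from, to, kekulized order
    charges = charges[seq_len(n)],
    aromatic = aromatic,
    hybridization = hyb,
    n_h = n_h
  )
}

one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  i <- match(value, levels)
  if (is.na(i)) i <- length(levels)
  v[i] <- 1
  v
}

# 75-dimensional atom feature vector: element one-hot (44), degree 0-10 (11),
# implicit valence 0-6 (7), formal charge (1), radical electrons (1),
# hybridization one-hot (5), aromaticity (1), total hydrogens 0-4 (5).
atom_feature_row <- function(elem, degree, n_h, charge, hyb, aromatic) {
  c(
    one_hot(elem, ATOM_ELEMENTS),
    one_hot(as.character(min(degree, 10L)), as.character(0:10)),
    one_hot(as.character(min(n_h, 6L)), as.character(0:6)),
    charge,
    0,  # radical electrons: not perceived for drug-like inputs
    one_hot(hyb, HYBRIDIZATIONS),
    as.numeric(aromatic),
    one_hot(as.character(min(n_h, 4L)), as.character(0:4))
  )
}

#' Convert a SMILES string to an attributed molecular graph
#'
#' Builds the hydrogen-suppressed heavy-atom graph of a molecule: nodes are
#' heavy atoms, edges are bonds, and each node carries a 75-dimensional
#' feature vector (element, degree, implicit valence, formal charge, radical
#' electrons, hybridization, aromaticity, hydrogen count). The input is
#' canonicalized first, so equivalent SMILES dialects yield identical graphs.
#'
#' @param smiles A single SMILES string.
#' @param drug_id Optional stable identifier stored with the graph.
#' @return An object of class `molecular_graph` with elements `n_atoms`,
#'   `elements`, `edges` (two-column matrix of undirected bonds),
#'   `bond_orders` (kekulized order per edge, 4 = aromatic), `adjacency`,
#'   `features` (`n_atoms` x 75), `aromatic`, `degree`, `n_h`,
#'   `formal_charge`, `hybridization`, `smiles`, `canonical_smiles`,
#'   `drug_id`.
#' @examples
#' g <- smiles_to_graph("c1ccccc1")
#' g$n_atoms        # 6
#' all(g$aromatic)  # TRUE
#' @export
smiles_to_graph <- function(smiles, drug_id = NULL) {
  can <- canonicalize_smiles(smiles)
  pc <- perceive_molecule(can)
  n <- pc$n

  A <- matrix(0, n, n)
  if (nrow(pc$bonds) > 0L) {
    A[pc$bonds[, 1:2, drop = FALSE]] <- 1
    A[pc$bonds[, 2:1, drop = FALSE]] <- 1
  }
  degree <- as.integer(rowSums(A))

  feats <- t(vapply(seq_len(n), function(i) {
    atom_feature_row(pc$elements[i], degree[i], pc$n_h[i], pc$charges[i],
                     pc$hybridization[i], pc$aromatic[i])
  }, numeric(75L)))

  orders <- pc$bonds[, 3L]
  if (length(orders)) {
    arom_edge <- pc$aromatic[pc$bonds[, 1L]] & pc$aromatic[pc$bonds[, 2L]]
    orders[arom_edge] <- 4L
  }

  structure(list(
    n_atoms = n,
    elements = pc$elements,
    edges = pc$bonds[, 1:2, drop = FALSE],
    bond_orders = as.integer(orders),
    adjacency = A,
    features = feats,
    aromatic = pc$aromatic,
    degree = degree,
    n_h = pc$n_h,
    formal_charge = pc$charges,
    hybridization = pc$hybridization,
    smiles = smiles,
    canonical_smiles = can,
    drug_id = drug_id
  ), class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph>", x$canonical_smiles, "-", x$n_atoms, "atoms,",
      nrow(x$edges), "bonds\n")
  invisible(x)
}

# Deterministic integer hash chain over the Mersenne prime 2^31 - 1. The
# multiplier keeps intermediate products below 2^53 so double arithmetic
# stays exact.
hash_chain <- function(h, xs) {
  for (x in xs) h <- (h * 69069 + x + 1) %% 2147483647
  h
}

#' Convert a SMILES string to an extended-connectivity fingerprint
#'
#' Computes a hashed circular-substructure (Morgan) fingerprint. At the
#' defaults (2,048 bits, radius 3) this is the ECFP6 representation. Atom
#' identifiers start from element, degree, hydrogen count, formal charge and
#' aromaticity, then are iteratively combined with sorted
#' (bond order, neighbor identifier) pairs out to the requested radius;
#' identifiers covering an already-seen atom environment are dropped and the
#' rest are folded into the bit vector.
#'
#' @param smiles A single SMILES string.
#' @param d Fingerprint length in bits (default 2048).
#' @param radius Morgan radius (default 3, i.e. diameter 6).
#' @param drug_id Optional identifier stored with the fingerprint.
#' @return An object of class `fingerprint`: list with `bits` (0/1 integer
#'   vector of length `d`), `d`, `radius`, `drug_id`.
#' @examples
#' fp <- smiles_to_fingerprint("CCO")
#' length(fp$bits)  # 2048
#' @export
smiles_to_fingerprint <- function(smiles, d = 2048L, radius = 3L,
                                  drug_id = NULL) {
  stopifnot(d >= 1L, radius >= 0L)
  can <- canonicalize_smiles(smiles)
  pc <- perceive_molecule(can)
  n <- pc$n

  nbrs <- vector("list", n)
  border <- vector("list", n)
  if (nrow(pc$bonds) > 0L) {
    arom_edge <- pc$aromatic[pc$bonds[, 1L]] & pc$aromatic[pc$bonds[, 2L]]
    ord <- ifelse(arom_edge, 4L, pc$bonds[, 3L])
    for (i in seq_len(nrow(pc$bonds))) {
      u <- pc$bonds[i, 1L]; w <- pc$bonds[i, 2L]
      nbrs[[u]] <- c(nbrs[[u]], w); border[[u]] <- c(border[[u]], ord[i])
      nbrs[[w]] <- c(nbrs[[w]], u); border[[w]] <- c(border[[w]], ord[i])
    }
  }

  inv <- vapply(seq_len(n), function(i) {
    z <- .atomic_numbers[[pc$elements[i]]]
    if (is.null(z)) z <- 0
    hash_chain(2166136261 %% 2147483647,
               c(z, length(nbrs[[i]]), pc$n_h[i], pc$charges[i] + 8,
                 as.integer(pc$aromatic[i])))
  }, numeric(1))

  env <- lapply(seq_len(n), function(i) i)   # atoms covered by each feature
  ids <- inv
  seen_env <- new.env(parent = emptyenv())
  keep <- numeric(0)
  register <- function(id, atoms) {
    key <- paste(sort(atoms), collapse = ",")
    if (is.null(seen_env[[key]])) {
      assign(key, TRUE, envir = seen_env)
      keep <<- c(keep, id)
    }
  }
  for (i in seq_len(n)) register(ids[i], env[[i]])

  if (radius >= 1L) {
    for (k in seq_len(radius)) {
      new_inv <- numeric(n)
      new_env <- vector("list", n)
      for (i in seq_len(n)) {
        if (length(nbrs[[i]]) > 0L) {
          pairs <- cbind(border[[i]], inv[nbrs[[i]]])
          o <- order(pairs[, 1L], pairs[, 2L])
          flat <- as.vector(t(pairs[o, , drop = FALSE]))
        } else {
          flat <- numeric(0)
        }
        new_inv[i] <- hash_chain(k, c(inv[i], flat))
        new_env[[i]] <- sort(unique(c(env[[i]],
                                      unlist(env[nbrs[[i]]], use.names = FALSE))))
      }
      inv <- new_inv
      env <- new_env
      for (i in seq_len(n)) register(inv[i], env[[i]])
    }
  }

  bits <- integer(d)
  bits[unique(as.integer(keep %% d)) + 1L] <- 1L

  structure(list(bits = bits, d = as.integer(d), radius = as.integer(radius),
                 drug_id = drug_id, canonical_smiles = can),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint>", x$d, "bits, radius", x$radius, "-", sum(x$bits),
      "bits set\n")
  invisible(x)
}

#' Serialize a molecular graph to JSON
#'
#' Writes node features, the edge list and provenance in a plain JSON layout
#' for downstream tooling.
#'
#' @param graph A `molecular_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "molecular_graph"))
  jsonlite::write_json(list(
    drug_id = graph$drug_id,
    smiles = graph$canonical_smiles,
    n_atoms = graph$n_atoms,
    elements = graph$elements,
    edges = graph$edges,
    node_features = graph$features
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write fingerprints as 0/1 CSV rows
#'
#' @param fingerprints List of `fingerprint` objects.
#' @param path Output CSV path; one row per drug, first column `drug_id`.
#' @return `path`, invisibly.
#' @export
write_fingerprints_csv <- function(fingerprints, path) {
  m <- do.call(rbind, lapply(fingerprints, function(f) f$bits))
  df <- data.frame(
    drug_id = vapply(fingerprints, function(f) {
      if (is.null(f$drug_id)) NA_character_ else as.character(f$drug_id)
    }, character(1)),
    m, check.names = FALSE
  )
  colnames(df) <- c("drug_id", paste0("bit_", seq_len(ncol(m))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
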