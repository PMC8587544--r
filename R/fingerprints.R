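# Circular (ECFP4-style) bit fingerprints, Tanimoto similarity and the
# graph encoding consumed by the neural-fingerprint classifier.
#
# Bit indices come from folding an internal integer hash of circular atom
# environments; they are deterministic for a given molecular graph but are
# implementation-specific, so nothing downstream (and no test) relies on a
# particular bit being set -- only on similarity values and invariances.

.HASH_MOD <- 2^26   # keeps h * 37 + x inside double precision

.hash_ints <- function(xs) {
  h <- 5381
  for (x in xs) h <- (h * 37 + (x %% .HASH_MOD) + 1) %% .HASH_MOD
  as.integer(h)
}

.ELEMENT_NUM <- c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L,
                  S = 16L, Cl = 17L, Br = 35L, I = 53L)

#' Construct a bit fingerprint
#'
#' @param on_bits integer vector of set bit indices (0-based).
#' @param length total bit count.
#' @return object of class `lig_fp`.
#' @export
bit_fp <- function(on_bits, length = 2048L) {
  on_bits <- sort(unique(as.integer(on_bits)))
  if (any(on_bits < 0L | on_bits >= length))
    stop("bit index out of range [0, length)")
  structure(list(length = as.integer(length), on_bits = on_bits),
            class = "lig_fp")
}

#' @export
print.lig_fp <- function(x, ...) {
  cat(sprintf("<lig_fp> %d/%d bits set\n", length(x$on_bits), x$length))
  invisible(x)
}

#' Circular fingerprint of diameter 4 (ECFP4-style)
#'
#' Morgan-style iterative hashing of atom environments to radius 2 (the
#' conventional "4" refers to diameter). The initial atom invariant encodes
#' element, degree, hydrogen count, formal charge, aromaticity and ring
#' membership; each iteration folds in the sorted (bond, neighbor-invariant)
#' multiset. Identifiers from all radii are folded onto `length` bits.
#' Deterministic and invariant to input atom numbering; the fingerprint of a
#' disconnected molecule is the union of its fragments' fingerprints.
#'
#' @param mol a `lig_mol` (or SMILES string, parsed on the fly).
#' @param length bit count (default 2048).
#' @return a `lig_fp`.
#' @export
ecfp4 <- function(mol, length = 2048L) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "lig_mol"))
  n <- n_atoms(mol)
  adj <- .adjacency(mol)
  bkey <- as.list(.bond_index(mol))
  in_ring <- logical(n)
  if (nrow(mol$bonds)) {
    rb <- mol$bonds[mol$bonds$ring, , drop = FALSE]
    in_ring[unique(c(rb$a1, rb$a2))] <- TRUE
  }
  deg <- lengths(adj)
  inv <- vapply(seq_len(n), function(a) .hash_ints(c(
    .ELEMENT_NUM[[mol$atoms$element[a]]], deg[a], mol$atoms$hcount[a],
    mol$atoms$charge[a] + 8L, as.integer(mol$atoms$aromatic[a]),
    as.integer(in_ring[a])
  )), integer(1))
  ids <- unique(inv)
  for (radius in 1:2) {
    new_inv <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      if (!length(nb)) return(.hash_ints(c(radius, inv[a])))
      pair <- vapply(nb, function(b) {
        bi <- bkey[[paste(min(a, b), max(a, b), sep = "-")]]
        code <- if (mol$bonds$aromatic[bi]) 4L else as.integer(mol$bonds$order[bi])
        code * .HASH_MOD + inv[b]
      }, numeric(1))
      pair <- sort(pair)
      .hash_ints(c(radius, inv[a],
                   as.vector(rbind(pair %/% .HASH_MOD, pair %% .HASH_MOD))))
    }, integer(1))
    inv <- new_inv
    ids <- c(ids, unique(inv))
  }
  bit_fp(unique(ids %% as.integer(length)), length)
}

#' Tanimoto similarity of two bit fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|}; the empty/empty case is defined as 0.
#'
#' @param a,b `lig_fp` objects of equal length.
#' @return numeric in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "lig_fp"), inherits(b, "lig_fp"))
  if (a$length != b$length) stop("fingerprint length mismatch")
  un <- length(union(a$on_bits, b$on_bits))
  if (un == 0L) return(0)
  length(intersect(a$on_bits, b$on_bits)) / un
}

#' Maximum Tanimoto similarity to a reference set (novelty score)
#'
#' The novelty convention of ligand-based screening: a query compound's
#' similarity to the nearest known active. Lower values mean more novel
#' chemotypes.
#'
#' @param query a `lig_fp`.
#' @param references non-empty list of `lig_fp`.
#' @return numeric in \[0, 1\].
#' @export
max_tanimoto_novelty <- function(query, references) {
  if (!length(references)) stop("reference fingerprint list is empty")
  max(vapply(references, function(r) tanimoto(query, r), numeric(1)))
}

# ---------------------------------------------------------------------------
# Graph encoding for the neural-fingerprint network

.GE_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "other")

#' Encode a molecule as a graph for the neural-fingerprint network
#'
#' Atom features: element one-hot (C/N/O/S/F/Cl/other), degree, attached
#' hydrogen count, aromatic flag. Bond features: order one-hot (single,
#' double, triple), aromatic flag, ring flag. Adjacency is returned as
#' neighbor lists plus the index of the connecting bond.
#'
#' @param mol a `lig_mol` (or SMILES string).
#' @return object of class `lig_graph` with elements `atom_features`
#'   (matrix n_atoms x 10), `bond_features` (matrix n_bonds x 5),
#'   `neighbors` (list of integer vectors), `neighbor_bonds` (list of
#'   integer vectors, parallel to `neighbors`).
#' @export
encode_graph <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "lig_mol"))
  n <- n_atoms(mol)
  adj <- .adjacency(mol)
  bkey <- .bond_index(mol)
  el <- ifelse(mol$atoms$element %in% .GE_ELEMENTS, mol$atoms$element, "other")
  one_hot <- outer(el, .GE_ELEMENTS, `==`) * 1
  af <- cbind(one_hot, degree = lengths(adj), hcount = mol$atoms$hcount,
              aromatic = as.numeric(mol$atoms$aromatic))
  colnames(af) <- c(.GE_ELEMENTS, "degree", "hcount", "aromatic")
  nb <- nrow(mol$bonds)
  bf <- matrix(0, nb, 5,
               dimnames = list(NULL, c("single", "double", "triple",
                                       "aromatic", "ring")))
  if (nb) {
    bf[, "single"] <- as.numeric(mol$bonds$order == 1 & !mol$bonds$aromatic)
    bf[, "double"] <- as.numeric(mol$bonds$order == 2)
    bf[, "triple"] <- as.numeric(mol$bonds$order == 3)
    bf[, "aromatic"] <- as.numeric(mol$bonds$aromatic)
    bf[, "ring"] <- as.numeric(mol$bonds$ring)
  }
  neighbor_bonds <- lapply(seq_len(n), function(a) {
    vapply(adj[[a]], function(b)
      unname(bkey[[paste(min(a, b), max(a, b), sep = "-")]]), integer(1))
  })
  structure(list(atom_features = af, bond_features = bf,
                 neighbors = adj, neighbor_bonds = neighbor_bonds),
            class = "lig_graph")
}

# ---------------------------------------------------------------------------
# Fingerprint cache serialization (TSV with hex-encoded bit sets)

.fp_to_hex <- function(fp) {
  bytes <- integer(ceiling(fp$length / 8))
  for (b in fp$on_bits) {
    i <- b %/% 8L + 1L
    bytes[i] <- bitwOr(bytes[i], bitwShiftL(1L, b %% 8L))
  }
  paste(sprintf("%02x", bytes), collapse = "")
}

.fp_from_hex <- function(hex, length) {
  bytes <- strtoi(substring(hex, seq(1, nchar(hex), 2), seq(2, nchar(hex), 2)),
                  base = 16L)
  on <- integer(0)
  for (i in seq_along(bytes)) {
    if (bytes[i] == 0L) next
    for (j in 0:7) if (bitwAnd(bytes[i], bitwShiftL(1L, j)))
      on <- c(on, (i - 1L) * 8L + j)
  }
  bit_fp(on[on < length], length)
}

#' Write fingerprints to a TSV cache
#'
#' Columns: id, length, hex (little-endian byte order within the hex string).
#'
#' @param fps named list of `lig_fp` (names are compound ids).
#' @param path output file.
#' @export
write_fp_cache <- function(fps, path) {
  stopifnot(length(fps) == 0L || !is.null(names(fps)))
  df <- data.frame(id = names(fps),
                   length = vapply(fps, function(f) f$length, integer(1)),
                   hex = vapply(fps, .fp_to_hex, character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fingerprint TSV cache
#'
#' @param path file written by [write_fp_cache()]; a missing file yields an
#'   empty list (callers then recompute).
#' @return named list of `lig_fp`.
#' @export
read_fp_cache <- function(path) {
  if (!file.exists(path)) return(stats::setNames(list(), character(0)))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character"))
  fps <- lapply(seq_len(nrow(df)),
                function(i) .fp_from_hex(df$hex[i], df$length[i]))
  stats::setNames(fps, df$id)
}
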