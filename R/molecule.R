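# Molecular graph container and a SMILES (subset) reader/writer.
#
# The package carries its own light molecule layer because every downstream
# stage (fingerprints, descriptors, pharmacophore perception) needs direct
# access to the annotated graph. The supported chemistry is the organic
# subset (B, C, N, O, P, S, F, Cl, Br, I) with aromatic lowercase forms,
# charges, explicit hydrogen counts, branches and ring closures -- the
# subset that covers typical screening libraries. Stereo markers are
# accepted and ignored (2D/topological treatment throughout).

.ELEMENT_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.453, Br = 79.904, I = 126.904
)

.DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2, Cl = 1, Br = 1, I = 1
)

#' Construct a molecule object
#'
#' A molecule is an annotated graph: an atom table, a bond table and an
#' optional list of 3D conformers. Most users will obtain molecules from
#' [parse_smiles()] or [read_sdf()]; this constructor is exported for the
#' synthetic generators, which build molecules coordinate-first.
#'
#' @param atoms data.frame with columns `element` (character), `aromatic`
#'   (logical), `charge` (integer), `hcount` (integer, total attached
#'   hydrogens, implicit + explicit).
#' @param bonds data.frame with columns `a1`, `a2` (1-based atom indices),
#'   `order` (1, 2 or 3), `aromatic` (logical). A `ring` column is computed
#'   if absent.
#' @param conformers list of numeric matrices, one row per heavy atom,
#'   columns x/y/z in Angstroms.
#' @return an object of class `lig_mol`.
#' @export
lig_mol <- function(atoms, bonds = NULL, conformers = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "aromatic", "charge", "hcount") %in% names(atoms)))
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(),
                        order = numeric(), aromatic = logical())
  }
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  bonds$a1 <- as.integer(bonds$a1)
  bonds$a2 <- as.integer(bonds$a2)
  n <- nrow(atoms)
  if (nrow(bonds) > 0L && (max(bonds$a1, bonds$a2) > n || min(bonds$a1, bonds$a2) < 1L))
    stop("bond endpoint out of range")
  bad <- !atoms$element %in% names(.ELEMENT_MASS)
  if (any(bad)) stop("unsupported element(s): ",
                     paste(unique(atoms$element[bad]), collapse = ", "))
  conformers <- lapply(conformers, function(cf) {
    if (!is.matrix(cf) || nrow(cf) != n || ncol(cf) != 3L)
      stop("each conformer must be an n_atoms x 3 coordinate matrix")
    dimnames(cf) <- NULL
    cf
  })
  mol <- structure(list(atoms = atoms, bonds = bonds, conformers = conformers),
                   class = "lig_mol")
  mol$bonds$ring <- .ring_bonds(mol)
  mol
}

#' @export
print.lig_mol <- function(x, ...) {
  cat(sprintf("<lig_mol> %d atoms, %d bonds, %d conformer(s)\n",
              nrow(x$atoms), nrow(x$bonds), length(x$conformers)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

# neighbor lists: list of integer vectors, index = atom
.adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# bond index lookup keyed "a-b" with a < b
.bond_index <- function(mol) {
  if (!nrow(mol$bonds)) return(character(0))
  key <- paste(pmin(mol$bonds$a1, mol$bonds$a2),
               pmax(mol$bonds$a1, mol$bonds$a2), sep = "-")
  stats::setNames(seq_along(key), key)
}

# A bond is a ring bond iff it is not a bridge: removing it leaves its
# endpoints connected. Molecules are small; a BFS per bond is fine.
.ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(logical(0))
  adj <- .adjacency(mol)
  vapply(seq_len(nb), function(i) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    seen <- logical(n_atoms(mol)); seen[a] <- TRUE
    queue <- a
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == a && w == b) next
        if (v == b && w == a) next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    seen[b]
  }, logical(1))
}

# Smallest ring through each ring bond (BFS shortest path avoiding the bond),
# deduplicated by atom set. Returns list of integer vectors (atom indices).
mol_rings <- function(mol, max_size = 8L) {
  rb <- which(mol$bonds$ring)
  if (!length(rb)) return(list())
  adj <- .adjacency(mol)
  rings <- list(); seen_keys <- character(0)
  for (i in rb) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    # BFS from a to b not using bond i
    n <- n_atoms(mol)
    prev <- rep(NA_integer_, n); prev[a] <- 0L
    queue <- a; found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if ((v == a && w == b) || (v == b && w == a)) next
        if (is.na(prev[w])) {
          prev[w] <- v
          if (w == b) { found <- TRUE; break }
          queue <- c(queue, w)
        }
      }
    }
    if (!found) next
    path <- b
    while (path[1] != a) path <- c(prev[path[1]], path)
    if (length(path) > max_size) next
    key <- paste(sort(path), collapse = ",")
    if (!key %in% seen_keys) {
      seen_keys <- c(seen_keys, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

# ---------------------------------------------------------------------------
# SMILES parsing

.ORGANIC_TOKENS <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I",
                     "b", "c", "n", "o", "p", "s")

# target valence given element and formal charge; used for implicit H
.target_valence <- function(element, charge) {
  v <- .DEFAULT_VALENCE[[element]]
  if (element %in% c("N", "O", "P", "S", "C", "B")) v <- v + charge
  max(v, 0)
}

# Implicit hydrogen count for one atom given its incident bond orders and
# aromatic flags. Aromatic atoms use the sigma-count + 1 (delocalized pi)
# convention, clipped at zero, so bare `n` never carries hydrogen and
# fusion carbons get none. Aliphatic N/P/S bump to the next valence state
# when over-bonded (amine oxides, sulfones). Returns NA when the valence is
# genuinely impossible.
.implied_h <- function(element, charge, aromatic, orders, arflags) {
  v <- .target_valence(element, charge)
  if (aromatic) {
    nsigma <- sum(ifelse(arflags, 1, orders))
    return(max(0L, as.integer(v - nsigma - 1L)))
  }
  bsum <- sum(ifelse(arflags, 1.5, orders))
  while (bsum > v + 1e-9 && element %in% c("N", "P", "S")) v <- v + 2
  if (bsum > v + 1e-9) return(NA_integer_)
  max(0L, as.integer(floor(v - bsum + 1e-9)))
}

#' Parse a SMILES string
#'
#' Supports the organic subset, bracket atoms with charges and explicit H
#' counts, branches, ring closures (including `%nn`), and bond symbols
#' `- = # :`. Stereo bond markers `/` and `\` are read as single bonds;
#' tetrahedral `@` marks are ignored. Aromaticity is taken from lowercase
#' input (no kekulization is attempted); implicit hydrogens are assigned
#' from standard valences adjusted by formal charge.
#'
#' @param smiles character scalar.
#' @return a `lig_mol`, or an error of class `ligfunnel_parse_error` when the
#'   string is not valid (unclosed rings/branches, bad tokens, over-valence).
#' @examples
#' m <- parse_smiles("c1ccccc1O")   # phenol
#' m$atoms$element
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    .parse_fail(smiles, "empty or non-character SMILES")
  s <- smiles
  i <- 1L; nmax <- nchar(s)
  atoms <- list(); bonds <- list()
  prev_stack <- integer(0)   # branch stack
  prev <- NA_integer_
  pending_bond <- NA_character_
  ring_open <- list()        # digit -> list(atom, bond)

  add_atom <- function(element, aromatic, charge, hcount, h_explicit) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic,
                                         charge = charge, hcount = hcount,
                                         h_explicit = h_explicit)
    length(atoms)
  }
  add_bond <- function(a, b, sym) {
    ar_a <- atoms[[a]]$aromatic; ar_b <- atoms[[b]]$aromatic
    if (is.na(sym)) {
      if (ar_a && ar_b) { ord <- 1; aromatic <- TRUE }
      else { ord <- 1; aromatic <- FALSE }
    } else {
      aromatic <- sym == ":"
      ord <- switch(sym, "-" = 1, "/" = 1, "\\" = 1, "=" = 2, "#" = 3, ":" = 1)
    }
    bonds[[length(bonds) + 1L]] <<- list(a1 = a, a2 = b, order = ord,
                                         aromatic = aromatic)
  }

  while (i <= nmax) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      if (is.na(prev)) .parse_fail(smiles, "branch before any atom")
      prev_stack <- c(prev_stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(prev_stack)) .parse_fail(smiles, "unmatched ')'")
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch; i <- i + 1L
    } else if (ch == "." ) {
      prev <- NA_integer_; pending_bond <- NA_character_; i <- i + 1L
    } else if (grepl("[0-9%]", ch)) {
      if (ch == "%") {
        digit <- substr(s, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", digit)) .parse_fail(smiles, "bad %nn ring closure")
        i <- i + 3L
      } else { digit <- ch; i <- i + 1L }
      if (is.na(prev)) .parse_fail(smiles, "ring closure before any atom")
      if (!is.null(ring_open[[digit]])) {
        op <- ring_open[[digit]]
        if (op$atom == prev) .parse_fail(smiles, "self ring closure")
        sym <- if (!is.na(pending_bond)) pending_bond else op$bond
        add_bond(op$atom, prev, sym)
        ring_open[[digit]] <- NULL
      } else {
        ring_open[[digit]] <- list(atom = prev, bond = pending_bond)
      }
      pending_bond <- NA_character_
    } else if (ch == "[") {
      close <- regexpr("]", substr(s, i, nmax), fixed = TRUE)
      if (close < 0) .parse_fail(smiles, "unclosed bracket atom")
      body <- substr(s, i + 1L, i + close - 2L)
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-IK-PR-Zacnops][a-z]?)(@{0,2})(H[0-9]*)?(\\+{1,3}|-{1,3}|[+-][0-9])?$",
        body))[[1]]
      if (!length(m)) .parse_fail(smiles, paste0("bad bracket atom [", body, "]"))
      sym <- m[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      element <- if (aromatic) toupper(sym) else sym
      if (!element %in% names(.ELEMENT_MASS))
        .parse_fail(smiles, paste0("unsupported element ", sym))
      htok <- m[5]
      hcount <- if (htok == "") 0L
                else if (htok == "H") 1L
                else as.integer(substr(htok, 2L, nchar(htok)))
      ctok <- m[6]
      charge <- if (ctok == "") 0L
                else if (grepl("^[+-][0-9]$", ctok))
                  as.integer(substr(ctok, 2L, 2L)) *
                    (if (substr(ctok, 1L, 1L) == "-") -1L else 1L)
                else nchar(ctok) * (if (substr(ctok, 1L, 1L) == "-") -1L else 1L)
      idx <- add_atom(element, aromatic, charge, hcount, TRUE)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- NA_character_
      prev <- idx
      i <- i + close
    } else {
      tok <- NULL
      for (t in .ORGANIC_TOKENS) {
        if (substr(s, i, i + nchar(t) - 1L) == t) { tok <- t; break }
      }
      if (is.null(tok)) .parse_fail(smiles, paste0("unexpected character '", ch, "'"))
      aromatic <- tok %in% c("b", "c", "n", "o", "p", "s")
      element <- if (aromatic) toupper(tok) else tok
      idx <- add_atom(element, aromatic, 0L, NA_integer_, FALSE)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- NA_character_
      prev <- idx
      i <- i + nchar(tok)
    }
  }
  open_digits <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_digits))
    .parse_fail(smiles, paste0("unclosed ring bond(s): ",
                               paste(open_digits, collapse = ",")))
  if (length(prev_stack)) .parse_fail(smiles, "unclosed branch")
  if (!length(atoms)) .parse_fail(smiles, "no atoms")

  at <- data.frame(
    element = vapply(atoms, `[[`, character(1), "element"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    hcount = vapply(atoms, `[[`, integer(1), "hcount"),
    stringsAsFactors = FALSE
  )
  h_explicit <- vapply(atoms, `[[`, logical(1), "h_explicit")
  bd <- if (length(bonds)) data.frame(
    a1 = vapply(bonds, `[[`, numeric(1), "a1"),
    a2 = vapply(bonds, `[[`, numeric(1), "a2"),
    order = vapply(bonds, `[[`, numeric(1), "order"),
    aromatic = vapply(bonds, `[[`, logical(1), "aromatic")
  ) else NULL

  # implicit hydrogens for organic-subset atoms
  for (k in seq_len(nrow(at))) {
    if (!h_explicit[k]) {
      sel <- if (is.null(bd)) logical(0) else (bd$a1 == k | bd$a2 == k)
      h <- .implied_h(at$element[k], at$charge[k], at$aromatic[k],
                      if (is.null(bd)) numeric(0) else bd$order[sel],
                      if (is.null(bd)) logical(0) else bd$aromatic[sel])
      if (is.na(h))
        .parse_fail(smiles, sprintf("valence exceeds maximum for %s",
                                    at$element[k]))
      at$hcount[k] <- h
    }
  }
  lig_mol(at, bd)
}

.parse_fail <- function(smiles, msg) {
  stop(structure(class = c("ligfunnel_parse_error", "error", "condition"),
                 list(message = sprintf("SMILES parse error in %s: %s",
                                        deparse(substitute(smiles, parent.frame())), msg),
                      call = NULL, smiles = smiles, reason = msg)))
}

#' Try to parse a SMILES string
#'
#' @param smiles character scalar.
#' @return the `lig_mol` on success, `NULL` on parse failure.
#' @export
try_parse_smiles <- function(smiles) {
  tryCatch(parse_smiles(smiles),
           ligfunnel_parse_error = function(e) NULL,
           error = function(e) NULL)
}

# ---------------------------------------------------------------------------
# Canonical ranking and SMILES writing

# Initial atom invariant string (element, charge, H count, aromatic, degree).
.atom_invariant0 <- function(mol) {
  deg <- integer(n_atoms(mol))
  if (nrow(mol$bonds)) {
    tb <- table(c(mol$bonds$a1, mol$bonds$a2))
    deg[as.integer(names(tb))] <- as.integer(tb)
  }
  paste(mol$atoms$element, mol$atoms$charge, mol$atoms$hcount,
        as.integer(mol$atoms$aromatic), deg, sep = "|")
}

# Iterative partition refinement: rank atoms by (current rank, sorted
# neighbor (bond, rank) pairs) until stable.
.refine_ranks <- function(mol, ranks, adj, bkey) {
  repeat {
    sig <- vapply(seq_len(n_atoms(mol)), function(a) {
      nb <- adj[[a]]
      if (!length(nb)) return(sprintf("%06d#", ranks[a]))
      bs <- vapply(nb, function(b) {
        bi <- bkey[[paste(min(a, b), max(a, b), sep = "-")]]
        sprintf("%g%s:%06d", mol$bonds$order[bi],
                if (mol$bonds$aromatic[bi]) "a" else ".", ranks[b])
      }, character(1))
      sprintf("%06d#%s", ranks[a], paste(sort(bs), collapse = ","))
    }, character(1))
    new <- match(sig, sort(unique(sig)))
    if (identical(new, ranks)) return(ranks)
    ranks <- new
  }
}

#' Canonical atom ranks
#'
#' Morgan-style partition refinement with deterministic tie-breaking. Atoms
#' that remain tied after refinement are (in practice) related by a graph
#' automorphism, so breaking the tie on any member yields the same canonical
#' form; this is the standard heuristic and is property-tested rather than
#' proven.
#'
#' @param mol a `lig_mol`.
#' @return integer vector, a permutation of `1..n_atoms`.
#' @export
canonical_ranks <- function(mol) {
  n <- n_atoms(mol)
  adj <- .adjacency(mol)
  bkey <- as.list(.bond_index(mol))
  sig0 <- .atom_invariant0(mol)
  ranks <- match(sig0, sort(unique(sig0)))
  ranks <- .refine_ranks(mol, ranks, adj, bkey)
  while (anyDuplicated(ranks)) {
    tb <- table(ranks)
    tied <- as.integer(names(tb)[tb > 1])
    r <- min(tied)
    members <- which(ranks == r)
    # promote one member of the lowest tied cell; scale others up
    ranks <- ranks * 2L
    ranks[members[1]] <- ranks[members[1]] - 1L
    ranks <- match(ranks, sort(unique(ranks)))
    ranks <- .refine_ranks(mol, ranks, adj, bkey)
  }
  ranks
}

#' Write a molecule as canonical SMILES
#'
#' The canonical form is internal to this package (deterministic for a given
#' molecular graph, invariant to input atom order); it is not guaranteed to
#' match any other toolkit's canonical string.
#'
#' @param mol a `lig_mol`.
#' @return character scalar SMILES.
#' @export
write_smiles <- function(mol) {
  n <- n_atoms(mol)
  if (!n) stop("empty molecule")
  ranks <- canonical_ranks(mol)
  adj <- .adjacency(mol)
  bkey <- as.list(.bond_index(mol))
  adj <- lapply(seq_len(n), function(a) {
    nb <- adj[[a]]
    nb[order(ranks[nb])]
  })

  comp <- .components(mol)
  pieces <- character(0)
  for (cid in sort(unique(comp))) {
    members <- which(comp == cid)
    root <- members[which.min(ranks[members])]
    pieces <- c(pieces, .write_component(mol, root, adj, bkey, ranks))
  }
  paste(pieces, collapse = ".")
}

.components <- function(mol) {
  n <- n_atoms(mol)
  adj <- .adjacency(mol)
  comp <- rep(NA_integer_, n); cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

.write_component <- function(mol, root, adj, bkey, ranks) {
  n <- n_atoms(mol)
  parent <- rep(NA_integer_, n)
  visited <- logical(n)
  back_keys <- character(0)
  dfs <- function(v) {
    visited[v] <<- TRUE
    for (w in adj[[v]]) {
      if (!visited[w]) { parent[w] <<- v; dfs(w) }
      else if (!isTRUE(parent[v] == w)) {
        key <- paste(min(v, w), max(v, w), sep = "-")
        if (!key %in% back_keys) back_keys <<- c(back_keys, key)
      }
    }
  }
  dfs(root)
  # incident back-edge keys per atom, ordered by rank of the far endpoint
  incident <- lapply(seq_len(n), function(v) {
    if (!length(back_keys)) return(character(0))
    ends <- strsplit(back_keys, "-", fixed = TRUE)
    mine <- vapply(ends, function(e) v %in% as.integer(e), logical(1))
    keys <- back_keys[mine]
    if (!length(keys)) return(character(0))
    far <- vapply(strsplit(keys, "-", fixed = TRUE), function(e) {
      e <- as.integer(e); if (e[1] == v) e[2] else e[1]
    }, integer(1))
    keys[order(ranks[far])]
  })
  digit_map <- new.env(parent = emptyenv())
  next_digit <- 1L
  emit <- function(v) {
    out <- .atom_token(mol, v)
    for (key in incident[[v]]) {
      first <- !exists(key, envir = digit_map)
      if (first) {
        assign(key, next_digit, envir = digit_map)
        next_digit <<- next_digit + 1L
      }
      d <- get(key, envir = digit_map)
      bs <- if (first) .bond_token(mol, bkey[[key]]) else ""
      dd <- if (d > 9) paste0("%", d) else as.character(d)
      out <- paste0(out, bs, dd)
    }
    kids <- adj[[v]][!is.na(parent[adj[[v]]]) & parent[adj[[v]]] == v]
    for (j in seq_along(kids)) {
      w <- kids[j]
      bs <- .bond_token(mol, bkey[[paste(min(v, w), max(v, w), sep = "-")]])
      sub <- emit(w)
      out <- if (j < length(kids)) paste0(out, "(", bs, sub, ")")
             else paste0(out, bs, sub)
    }
    out
  }
  emit(root)
}

.atom_token <- function(mol, v) {
  el <- mol$atoms$element[v]
  ar <- mol$atoms$aromatic[v]
  ch <- mol$atoms$charge[v]
  hc <- mol$atoms$hcount[v]
  sym <- if (ar) tolower(el) else el
  # can we write it bare (organic subset, neutral, implicit H reproduces)?
  if (ch == 0L && el %in% names(.DEFAULT_VALENCE)) {
    sel <- if (nrow(mol$bonds)) mol$bonds$a1 == v | mol$bonds$a2 == v else logical(0)
    implied <- .implied_h(el, 0L, ar, mol$bonds$order[sel], mol$bonds$aromatic[sel])
    if (!is.na(implied) && implied == hc) return(sym)
  }
  htok <- if (hc == 0L) "" else if (hc == 1L) "H" else paste0("H", hc)
  ctok <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
          else sprintf("%+d", ch)
  paste0("[", sym, htok, ctok, "]")
}

.bond_token <- function(mol, bi) {
  a1 <- mol$bonds$a1[bi]; a2 <- mol$bonds$a2[bi]
  if (mol$bonds$aromatic[bi]) return("")
  ord <- mol$bonds$order[bi]
  both_ar <- mol$atoms$aromatic[a1] && mol$atoms$aromatic[a2]
  if (ord == 1) { if (both_ar) "-" else "" }
  else if (ord == 2) "="
  else if (ord == 3) "#"
  else stop("bad bond order")
}

#' Canonical structure key for molecule identity
#'
#' Two molecules compare equal iff their annotated graphs are isomorphic
#' (element, charge, hydrogen count, aromaticity, bond orders).
#'
#' @param mol a `lig_mol`.
#' @return character scalar.
#' @export
mol_identity <- function(mol) write_smiles(mol)

# ---------------------------------------------------------------------------
# Substructure matching (backtracking monomorphism on small graphs).
# Atom compatibility: same element and aromatic flag; pattern charge 0 matches
# any charge unless strict. Bond compatibility: same aromatic flag and order.

#' Test whether a molecule contains a substructure
#'
#' Plain subgraph matching (no query-language extensions): pattern atoms
#' match on element and aromaticity, pattern bonds on order and aromaticity.
#' Hydrogen counts are not constrained, so a pattern written without explicit
#' hydrogens matches substituted positions.
#'
#' @param mol a `lig_mol` to search in.
#' @param pattern a `lig_mol` (typically from [parse_smiles()]).
#' @return logical scalar.
#' @export
has_substructure <- function(mol, pattern) {
  np <- n_atoms(pattern); nm <- n_atoms(mol)
  if (np > nm) return(FALSE)
  adj_m <- .adjacency(mol); adj_p <- .adjacency(pattern)
  bk_m <- as.list(.bond_index(mol)); bk_p <- as.list(.bond_index(pattern))
  atom_ok <- function(pa, ma) {
    pattern$atoms$element[pa] == mol$atoms$element[ma] &&
      pattern$atoms$aromatic[pa] == mol$atoms$aromatic[ma]
  }
  bond_ok <- function(pb, mb) {
    pattern$bonds$aromatic[pb] == mol$bonds$aromatic[mb] &&
      (pattern$bonds$aromatic[pb] || pattern$bonds$order[pb] == mol$bonds$order[mb])
  }
  # order pattern atoms so each (after the first) touches an earlier one
  ord <- integer(0); left <- seq_len(np)
  while (length(left)) {
    if (!length(ord)) nxt <- left[1]
    else {
      cand <- left[vapply(left, function(p) any(adj_p[[p]] %in% ord), logical(1))]
      nxt <- if (length(cand)) cand[1] else left[1]
    }
    ord <- c(ord, nxt); left <- setdiff(left, nxt)
  }
  map <- rep(NA_integer_, np)
  used <- logical(nm)
  try_at <- function(k) {
    if (k > np) return(TRUE)
    pa <- ord[k]
    anchors <- adj_p[[pa]][adj_p[[pa]] %in% ord[seq_len(k - 1L)]]
    cands <- if (length(anchors)) {
      ma0 <- map[anchors[1]]
      adj_m[[ma0]]
    } else seq_len(nm)
    for (ma in cands) {
      if (used[ma] || !atom_ok(pa, ma)) next
      ok <- TRUE
      for (pn in anchors) {
        mb <- map[pn]
        keym <- paste(min(ma, mb), max(ma, mb), sep = "-")
        bi_m <- bk_m[[keym]]
        if (is.null(bi_m)) { ok <- FALSE; break }
        keyp <- paste(min(pa, pn), max(pa, pn), sep = "-")
        if (!bond_ok(bk_p[[keyp]], bi_m)) { ok <- FALSE; break }
      }
      if (!ok) next
      map[pa] <<- ma; used[ma] <<- TRUE
      if (try_at(k + 1L)) return(TRUE)
      map[pa] <<- NA_integer_; used[ma] <<- FALSE
    }
    FALSE
  }
  try_at(1L)
}

#' Permute the atoms of a molecule
#'
#' Utility for invariance testing: returns the same molecule with atoms
#' renumbered by `perm` (atom `i` of the result is atom `perm[i]` of the
#' input).
#'
#' @param mol a `lig_mol`.
#' @param perm a permutation of `1..n_atoms`.
#' @return a `lig_mol`.
#' @export
permute_atoms <- function(mol, perm) {
  stopifnot(sort(perm) == seq_len(n_atoms(mol)))
  inv <- order(perm)
  at <- mol$atoms[perm, , drop = FALSE]
  rownames(at) <- NULL
  bd <- mol$bonds
  if (nrow(bd)) { bd$a1 <- inv[bd$a1]; bd$a2 <- inv[bd$a2] }
  cf <- lapply(mol$conformers, function(m) m[perm, , drop = FALSE])
  lig_mol(at, bd[, c("a1", "a2", "order", "aromatic")], cf)
}
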