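# Structure file readers/writers: SMILES files (.smi) and SDF V2000.
#
# SDF convention used throughout: heavy atoms only, with implicit hydrogen
# counts recomputed on read from standard valences; aromatic systems are
# written with bond type 4 (no kekulization). Data fields round-trip as
# character strings.

#' Read a SMILES file
#'
#' One record per line: `SMILES<whitespace>ID`. Missing ids are replaced by
#' `mol<line>`. Unparseable lines are reported, not silently dropped.
#'
#' @param path input file.
#' @return list with `records` (named list of `lig_mol`, names = ids) and
#'   `rejected` (data.frame id/smiles/reason).
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- list(); rejected <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    smi <- parts[1]
    id <- if (length(parts) >= 2L) parts[2] else sprintf("mol%d", i)
    m <- try_parse_smiles(smi)
    if (is.null(m)) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(id = id, smiles = smi, reason = "unparseable SMILES")
    } else {
      records[[id]] <- m
    }
  }
  list(records = records,
       rejected = if (length(rejected)) do.call(rbind, rejected)
                  else data.frame(id = character(), smiles = character(),
                                  reason = character()))
}

#' Write a SMILES file
#'
#' @param mols named list of `lig_mol` (names are ids).
#' @param path output file.
#' @export
write_smi <- function(mols, path) {
  stopifnot(!is.null(names(mols)))
  writeLines(paste(vapply(mols, write_smiles, character(1)), names(mols)),
             path)
  invisible(path)
}

#' Read an SDF (V2000) file
#'
#' Reads heavy-atom structures, one conformer per entry; entries sharing a
#' title are merged into one molecule with multiple conformers when their
#' graphs are identical. Bond type 4 is read as aromatic. `M  CHG` lines
#' are honored. Data fields (`> <name>`) are returned as strings.
#'
#' @param path input file.
#' @return list of entries, each `list(id, mol, fields)` where `mol` carries
#'   the conformer(s).
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split on $$$$
  breaks <- c(0L, which(trimws(lines) == "$$$$"))
  entries <- list()
  for (k in seq_len(length(breaks) - 1L)) {
    block <- lines[(breaks[k] + 1L):(breaks[k + 1L] - 1L)]
    if (!length(block) || all(!nzchar(trimws(block)))) next
    entries[[length(entries) + 1L]] <- .parse_sdf_block(block)
  }
  entries
}

.parse_sdf_block <- function(block) {
  id <- trimws(block[1])
  counts <- block[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) stop("malformed SDF counts line")
  atom_lines <- block[5:(4 + na)]
  coords <- t(vapply(atom_lines, function(l) c(
    as.numeric(substr(l, 1, 10)), as.numeric(substr(l, 11, 20)),
    as.numeric(substr(l, 21, 30))), numeric(3)))
  rownames(coords) <- NULL
  element <- trimws(substr(atom_lines, 31, 34))
  bonds <- NULL
  if (nb > 0L) {
    bond_lines <- block[(5 + na):(4 + na + nb)]
    bonds <- data.frame(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      type = as.integer(substr(bond_lines, 7, 9))
    )
    bonds <- data.frame(a1 = bonds$a1, a2 = bonds$a2,
                        order = ifelse(bonds$type == 4L, 1, bonds$type),
                        aromatic = bonds$type == 4L)
  }
  charge <- integer(na)
  rest <- block[-seq_len(4 + na + nb)]
  for (l in grep("^M  CHG", rest, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "[ ]+")[[1]])
    nset <- toks[1]
    for (j in seq_len(nset)) charge[toks[2 * j]] <- toks[2 * j + 1L]
  }
  aromatic <- logical(na)
  if (!is.null(bonds) && nrow(bonds)) {
    ar <- bonds[bonds$aromatic, , drop = FALSE]
    aromatic[unique(c(ar$a1, ar$a2))] <- TRUE
  }
  hcount <- vapply(seq_len(na), function(a) {
    sel <- if (is.null(bonds)) logical(0) else bonds$a1 == a | bonds$a2 == a
    h <- .implied_h(element[a], charge[a], aromatic[a],
                    if (is.null(bonds)) numeric(0) else bonds$order[sel],
                    if (is.null(bonds)) logical(0) else bonds$aromatic[sel])
    if (is.na(h)) 0L else h
  }, integer(1))
  atoms <- data.frame(element = element, aromatic = aromatic,
                      charge = charge, hcount = hcount,
                      stringsAsFactors = FALSE)
  mol <- lig_mol(atoms, bonds, list(coords))
  # data fields
  fields <- list()
  fi <- grep("^> ", rest)
  for (i in fi) {
    nm <- sub("^> *<([^>]*)>.*$", "\\1", rest[i])
    val <- if (i + 1L <= length(rest)) rest[i + 1L] else ""
    fields[[nm]] <- trimws(val)
  }
  list(id = id, mol = mol, fields = fields)
}

#' Write molecules to an SDF (V2000) file
#'
#' One entry per conformer; molecules without conformers get all-zero
#' coordinates (flat entry). Aromatic bonds are written as type 4.
#'
#' @param mols named list of `lig_mol`.
#' @param path output file.
#' @param fields optional named list (per molecule id) of named field lists.
#' @export
write_sdf <- function(mols, path, fields = NULL) {
  stopifnot(!is.null(names(mols)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(mols)) {
    mol <- mols[[id]]
    cfs <- if (length(mol$conformers)) mol$conformers
           else list(matrix(0, n_atoms(mol), 3))
    for (cf in cfs) {
      writeLines(c(id, "  ligfunnel", ""), con)
      na <- n_atoms(mol); nb <- nrow(mol$bonds)
      writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb), con)
      for (a in seq_len(na)) {
        writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                           cf[a, 1], cf[a, 2], cf[a, 3],
                           mol$atoms$element[a]), con)
      }
      if (nb) for (b in seq_len(nb)) {
        type <- if (mol$bonds$aromatic[b]) 4L else as.integer(mol$bonds$order[b])
        writeLines(sprintf("%3d%3d%3d  0", mol$bonds$a1[b], mol$bonds$a2[b],
                           type), con)
      }
      chg <- which(mol$atoms$charge != 0L)
      if (length(chg)) {
        writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                          paste(sprintf("%4d%4d", chg, mol$atoms$charge[chg]),
                                collapse = "")), con)
      }
      writeLines("M  END", con)
      fl <- if (!is.null(fields)) fields[[id]] else NULL
      if (!is.null(fl)) for (nm in names(fl)) {
        writeLines(c(sprintf(">  <%s>", nm), as.character(fl[[nm]]), ""), con)
      }
      writeLines("$$$$", con)
    }
  }
  invisible(path)
}
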