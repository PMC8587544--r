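# Physicochemical descriptors used for property-matched decoy selection.
# The logP here is a coarse atom-contribution estimate (documented as such);
# it is used for matching compounds against each other under a +/- window,
# where internal consistency matters more than absolute accuracy.

#' Molecular weight (Da)
#'
#' Average atomic masses, hydrogens included via per-atom H counts.
#'
#' @param mol a `lig_mol`.
#' @return numeric scalar, Daltons.
#' @export
mol_weight <- function(mol) {
  sum(.ELEMENT_MASS[mol$atoms$element]) +
    sum(mol$atoms$hcount) * .ELEMENT_MASS[["H"]]
}

#' Hydrogen bond donor count
#'
#' Number of N or O atoms bearing at least one hydrogen.
#'
#' @param mol a `lig_mol`.
#' @return integer.
#' @export
count_hbd <- function(mol) {
  sum(mol$atoms$element %in% c("N", "O") & mol$atoms$hcount > 0L)
}

#' Hydrogen bond acceptor count
#'
#' Number of N or O atoms that are not positively charged. This is the
#' simple Lipinski-style count; no aromatic-nitrogen lone-pair bookkeeping.
#'
#' @param mol a `lig_mol`.
#' @return integer.
#' @export
count_hba <- function(mol) {
  sum(mol$atoms$element %in% c("N", "O") & mol$atoms$charge <= 0L)
}

#' Rotatable bond count
#'
#' Single, non-ring, non-aromatic bonds between two heavy atoms that each
#' carry at least one further heavy neighbor (terminal bonds excluded).
#' Amide bonds are not special-cased.
#'
#' @param mol a `lig_mol`.
#' @return integer.
#' @export
count_rotatable <- function(mol) {
  if (!nrow(mol$bonds)) return(0L)
  deg <- integer(n_atoms(mol))
  tb <- table(c(mol$bonds$a1, mol$bonds$a2))
  deg[as.integer(names(tb))] <- as.integer(tb)
  with(mol$bonds, sum(order == 1 & !aromatic & !ring &
                        deg[a1] >= 2L & deg[a2] >= 2L))
}

# per-element/environment logP increments (Crippen-flavored, coarse)
.LOGP_CONTRIB <- c(
  C_aromatic = 0.29, C_aliphatic = 0.14, N = -0.60, O = -0.45,
  S = 0.25, P = -0.20, F = 0.20, Cl = 0.65, Br = 0.85, I = 1.10, B = 0.05
)

#' Estimated logP (octanol/water partition)
#'
#' Coarse atom-contribution estimate: each heavy atom adds an increment
#' keyed by element (aromatic vs aliphatic carbon distinguished) and each
#' polar hydrogen (on N/O) subtracts 0.3. Intended for relative
#' property-window matching, not absolute prediction.
#'
#' @param mol a `lig_mol`.
#' @return numeric scalar.
#' @export
estimate_logp <- function(mol) {
  key <- ifelse(mol$atoms$element == "C",
                ifelse(mol$atoms$aromatic, "C_aromatic", "C_aliphatic"),
                mol$atoms$element)
  polar_h <- sum(mol$atoms$hcount[mol$atoms$element %in% c("N", "O")])
  sum(.LOGP_CONTRIB[key], na.rm = TRUE) - 0.3 * polar_h
}

#' Descriptor table for a list of molecules
#'
#' @param mols list of `lig_mol`.
#' @return data.frame with columns mw, logp, hbd, hba, rotb.
#' @export
descriptor_table <- function(mols) {
  data.frame(
    mw = vapply(mols, mol_weight, numeric(1)),
    logp = vapply(mols, estimate_logp, numeric(1)),
    hbd = vapply(mols, function(m) as.numeric(count_hbd(m)), numeric(1)),
    hba = vapply(mols, function(m) as.numeric(count_hba(m)), numeric(1)),
    rotb = vapply(mols, function(m) as.numeric(count_rotatable(m)), numeric(1))
  )
}
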