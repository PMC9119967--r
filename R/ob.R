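# Bridge to OpenBabel through ChemmineOB's SWIG bindings.
#
# ChemmineOB exports only a handful of high-level helpers, but its namespace
# carries the full OpenBabel API. We use it to read SMILES into an OBMol and
# query per-atom/per-bond perception (input atom order is preserved, implicit
# hydrogens are counted, aromaticity and ring membership are perceived).

.ob <- new.env(parent = emptyenv())

ob_ns <- function() {
  if (is.null(.ob$ns)) .ob$ns <- getNamespace("ChemmineOB")
  .ob$ns
}

# Parse a SMILES string; returns NULL when OpenBabel rejects it.
# atoms: data.frame(atomic_num, formal_charge, num_hs, spin, aromatic, in_ring)
# bonds: data.frame(a1, a2, order, aromatic, in_ring)  (1-based atom indices)
ob_read_smiles <- function(smiles) {
  OB <- ob_ns()
  conv <- OB$OBConversion()
  OB$OBConversion_SetInFormat(conv, "smi")
  mol <- OB$OBMol()
  ok <- suppressWarnings(OB$OBConversion_ReadString(conv, mol, smiles))
  if (!isTRUE(ok) || OB$OBMol_NumAtoms(mol) < 1L) return(NULL)
  n <- OB$OBMol_NumAtoms(mol)
  m <- OB$OBMol_NumBonds(mol)
  atoms <- data.frame(
    atomic_num    = integer(n),
    formal_charge = integer(n),
    num_hs        = integer(n),
    spin          = integer(n),
    aromatic      = logical(n),
    in_ring       = logical(n)
  )
  for (i in seq_len(n)) {
    a <- OB$OBMol_GetAtom(mol, i)
    atoms$atomic_num[i]    <- OB$OBAtom_GetAtomicNum(a)
    atoms$formal_charge[i] <- OB$OBAtom_GetFormalCharge(a)
    atoms$num_hs[i]        <- OB$OBAtom_GetImplicitHCount(a)
    atoms$spin[i]          <- OB$OBAtom_GetSpinMultiplicity(a)
    atoms$aromatic[i]      <- OB$OBAtom_IsAromatic(a)
    atoms$in_ring[i]       <- OB$OBAtom_IsInRing(a)
  }
  if (m > 0L) {
    bonds <- data.frame(
      a1 = integer(m), a2 = integer(m), order = integer(m),
      aromatic = logical(m), in_ring = logical(m)
    )
    for (j in seq_len(m)) {
      b <- OB$OBMol_GetBond(mol, j - 1L)
      bonds$a1[j]       <- OB$OBBond_GetBeginAtomIdx(b)
      bonds$a2[j]       <- OB$OBBond_GetEndAtomIdx(b)
      bonds$order[j]    <- OB$OBBond_GetBondOrder(b)
      bonds$aromatic[j] <- OB$OBBond_IsAromatic(b)
      bonds$in_ring[j]  <- OB$OBBond_IsInRing(b)
    }
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                        aromatic = logical(0), in_ring = logical(0))
  }
  # Hydrogens written explicitly in the SMILES (e.g. "[H]" tokens) are folded
  # into their heavy neighbour's count; heavy-atom graphs never carry H nodes.
  is_h <- atoms$atomic_num == 1L
  if (any(is_h)) {
    keep <- which(!is_h)
    remap <- integer(nrow(atoms)); remap[keep] <- seq_along(keep)
    for (j in seq_len(nrow(bonds))) {
      if (is_h[bonds$a1[j]] && !is_h[bonds$a2[j]])
        atoms$num_hs[bonds$a2[j]] <- atoms$num_hs[bonds$a2[j]] + 1L
      if (is_h[bonds$a2[j]] && !is_h[bonds$a1[j]])
        atoms$num_hs[bonds$a1[j]] <- atoms$num_hs[bonds$a1[j]] + 1L
    }
    bonds <- bonds[!is_h[bonds$a1] & !is_h[bonds$a2], , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL; rownames(bonds) <- NULL
  }
  list(atoms = atoms, bonds = bonds)
}

#' Count SMARTS matches in a molecule
#'
#' @param smiles A SMILES string.
#' @param smarts A SMARTS pattern.
#' @return Number of (non-unique) matches; 0 when the molecule does not
#'   contain the pattern.
#' @export
smarts_matches <- function(smiles, smarts) {
  OB <- ob_ns()
  conv <- OB$OBConversion()
  OB$OBConversion_SetInFormat(conv, "smi")
  mol <- OB$OBMol()
  if (!isTRUE(suppressWarnings(OB$OBConversion_ReadString(conv, mol, smiles))))
    stop(sprintf("unparseable SMILES: '%s'", smiles), call. = FALSE)
  sp <- OB$OBSmartsPattern()
  if (!OB$OBSmartsPattern_Init(sp, smarts))
    stop(sprintf("invalid SMARTS: '%s'", smarts), call. = FALSE)
  OB$OBSmartsPattern_Match(sp, mol)
  OB$OBSmartsPattern_NumMatches(sp)
}

#' Canonical SMILES
#'
#' Canonicalizes a SMILES string with OpenBabel. Used as the molecular
#' identity key in dataset curation and screening exclusion.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES; `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) ""
    )
    out <- trimws(sub("\t.*$", "", out))
    out <- sub("\\s.*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}
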