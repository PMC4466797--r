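# Thin bridge to OpenBabel through ChemmineOB's SWIG bindings.
#
# ChemmineOB exports a high-level API (prop_OB, smartsSearch_OB, ...) but the
# operations this package needs -- persistent molecule handles that also work
# for single-atom molecules, atom-level SMARTS match indices, per-atom
# Gasteiger charges and bond tables -- are only reachable through the
# SWIG-generated OpenBabel wrappers living in the ChemmineOB namespace.
# All such access is funnelled through this file.

.obEnv <- new.env(parent = emptyenv())

.ob <- function() {
  if (is.null(.obEnv$ns)) .obEnv$ns <- getNamespace("ChemmineOB")
  .obEnv$ns
}

#' Parse SMILES strings into OpenBabel molecule handles
#'
#' Returns a list of external molecule handles, with `NULL` for strings that
#' OpenBabel rejects. Handles stay valid for the lifetime of the R session.
#'
#' @param smiles character vector of SMILES strings.
#' @return list of molecule handles (or `NULL` where parsing failed).
#' @keywords internal
obParseSmiles <- function(smiles) {
  OB <- .ob()
  conv <- OB$OBConversion()
  OB$OBConversion_SetInFormat(conv, "smi")
  lapply(smiles, function(s) {
    mol <- OB$OBMol()
    ok <- suppressWarnings(OB$OBConversion_ReadString(conv, mol, s))
    if (isTRUE(ok) && OB$OBMol_NumAtoms(mol) > 0) mol else NULL
  })
}

# Compile a SMARTS pattern; NULL if it does not parse.
obCompileSmarts <- function(smarts) {
  OB <- .ob()
  sp <- OB$OBSmartsPattern()
  if (!isTRUE(OB$OBSmartsPattern_Init(sp, smarts))) return(NULL)
  sp
}

# Unique substructure matches of a compiled pattern in one molecule:
# a list of integer vectors of (1-based) atom indices; empty list if no match.
obMatchAtoms <- function(pattern, mol) {
  OB <- .ob()
  OB$OBSmartsPattern_Match(pattern, mol)
  OB$OBSmartsPattern_GetUMapList(pattern)
}

obMatchCount <- function(pattern, mol) {
  length(obMatchAtoms(pattern, mol))
}

# Extract the heavy-atom graph of a molecule: per-atom element, formal charge,
# implicit hydrogen count, aromatic flag and Gasteiger partial charge, plus a
# bond table (1-based atom indices, integer order, aromatic flag).
obMolGraph <- function(mol) {
  OB <- .ob()
  n <- OB$OBMol_NumAtoms(mol)
  z <- integer(n); fc <- integer(n); hyd <- integer(n)
  arom <- logical(n); pch <- numeric(n)
  for (i in seq_len(n)) {
    a <- OB$OBMol_GetAtom(mol, i)
    z[i] <- OB$OBAtom_GetAtomicNum(a)
    fc[i] <- OB$OBAtom_GetFormalCharge(a)
    hyd[i] <- OB$OBAtom_GetImplicitHCount(a)
    arom[i] <- OB$OBAtom_IsAromatic(a)
    pch[i] <- OB$OBAtom_GetPartialCharge(a)
  }
  nb <- OB$OBMol_NumBonds(mol)
  from <- integer(nb); to <- integer(nb); ord <- integer(nb)
  barom <- logical(nb); bring <- logical(nb)
  for (i in seq_len(nb)) {
    b <- OB$OBMol_GetBond(mol, i - 1L)
    from[i] <- OB$OBBond_GetBeginAtomIdx(b)
    to[i] <- OB$OBBond_GetEndAtomIdx(b)
    ord[i] <- OB$OBBond_GetBondOrder(b)
    barom[i] <- OB$OBBond_IsAromatic(b)
    bring[i] <- OB$OBBond_IsInRing(b)
  }
  list(nAtoms = n, Z = z, formalCharge = fc, implicitH = hyd,
       aromatic = arom, partialCharge = pch,
       bonds = data.frame(from = from, to = to, order = ord,
                          aromatic = barom, inRing = bring))
}

obMolWeight <- function(mol) .ob()$OBMol_GetMolWt(mol)

obTotalCharge <- function(mol) .ob()$OBMol_GetTotalCharge(mol)

# logP and TPSA through ChemmineOB's exported descriptor interface.
obLogpTpsa <- function(mols) {
  p <- ChemmineOB::prop_OB(mols)
  data.frame(logp = p$logP, tpsa = p$TPSA)
}
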