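# Internal OpenBabel helpers.
#
# ChemmineOB exposes the full SWIG-wrapped OpenBabel API in its namespace but
# exports only a handful of high-level entry points; the low-level accessors
# used here (atom/bond traversal, SMARTS matching with match maps) are reached
# through the namespace. Patterns are compiled once and cached in `the$smarts`.

ob <- function() getNamespace("ChemmineOB")

# Parse a single SMILES into an OBMol reference, or NULL if unparseable.
ob_parse_smiles <- function(smiles, title = "") {
  mols <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol(
      "SMILES", paste(smiles, title), identity
    )),
    error = function(e) NULL
  )
  if (is.null(mols) || length(mols) == 0) return(NULL)
  mols[[1]]
}

ob_valid_smiles <- function(smiles) {
  !vapply(smiles, function(s) is.null(ob_parse_smiles(s)), logical(1))
}

ob_add_hydrogens <- function(mol) {
  OB <- ob()
  OB$OBMol_AddHydrogens(mol)
  mol
}

# Atom table: 1-based OpenBabel atom indices.
ob_atoms <- function(mol) {
  OB <- ob()
  n <- OB$OBMol_NumAtoms(mol)
  out <- tibble(
    idx = seq_len(n), z = integer(n), aromatic = logical(n),
    n_implicit_h = integer(n), charge = integer(n), in_ring = logical(n)
  )
  for (i in seq_len(n)) {
    a <- OB$OBMol_GetAtom(mol, i)
    out$z[i] <- OB$OBAtom_GetAtomicNum(a)
    out$aromatic[i] <- OB$OBAtom_IsAromatic(a)
    out$n_implicit_h[i] <- OB$OBAtom_GetImplicitHCount(a)
    out$charge[i] <- OB$OBAtom_GetFormalCharge(a)
    out$in_ring[i] <- OB$OBAtom_IsInRing(a)
  }
  out
}

ob_bonds <- function(mol) {
  OB <- ob()
  n <- OB$OBMol_NumBonds(mol)
  out <- tibble(
    begin = integer(n), end = integer(n), order = integer(n),
    aromatic = logical(n), in_ring = logical(n)
  )
  for (i in seq_len(n)) {
    b <- OB$OBMol_GetBond(mol, i - 1L)
    out$begin[i] <- OB$OBBond_GetBeginAtomIdx(b)
    out$end[i] <- OB$OBBond_GetEndAtomIdx(b)
    out$order[i] <- OB$OBBond_GetBondOrder(b)
    out$aromatic[i] <- OB$OBBond_IsAromatic(b)
    out$in_ring[i] <- OB$OBBond_IsInRing(b)
  }
  out
}

ob_compile_smarts <- function(smarts) {
  if (is.null(the$smarts)) the$smarts <- new.env(parent = emptyenv())
  sp <- the$smarts[[smarts]]
  if (is.null(sp)) {
    OB <- ob()
    sp <- OB$OBSmartsPattern()
    if (!OB$OBSmartsPattern_Init(sp, smarts)) {
      abort(paste0("invalid SMARTS pattern: ", smarts))
    }
    the$smarts[[smarts]] <- sp
  }
  sp
}

# Unique match maps as a list of integer vectors of atom indices.
ob_smarts_maps <- function(mol, smarts) {
  OB <- ob()
  sp <- ob_compile_smarts(smarts)
  OB$OBSmartsPattern_Match(sp, mol)
  um <- OB$OBSmartsPattern_GetUMapList(sp)
  k <- length(um)
  if (k == 0) return(list())
  lapply(seq_len(k), function(i) as.integer(um[[i]]))
}

ob_smarts_count <- function(mol, smarts) {
  length(ob_smarts_maps(mol, smarts))
}

# Atoms at which `smarts` matches rooted (its first atom mapped to the atom),
# obtained by wrapping the pattern in a recursive-SMARTS environment so every
# reported map is a single root atom. This sidesteps OpenBabel's deduplication
# of automorphic maps, which would otherwise hide valid roots on symmetric
# molecules.
ob_smarts_root_atoms <- function(mol, smarts) {
  maps <- ob_smarts_maps(mol, paste0("[$(", smarts, ")]"))
  if (length(maps) == 0) return(integer())
  sort(unique(vapply(maps, `[[`, integer(1), 1L)))
}
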