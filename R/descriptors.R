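#' Compute the physicochemical descriptor panel
#'
#' Computes, per compound, the descriptors consumed by the drug-likeness rule
#' panels: molecular weight, heavy / heavy-aromatic / total atom counts,
#' carbon and heteroatom counts, ring count (smallest set of smallest rings),
#' fraction of sp3 carbons, rotatable bonds, pharmacophore H-bond
#' acceptor/donor counts, the Lipinski atom-count readings (N+O atoms;
#' H on N or O), Ertl topological polar surface area, Wildman-Crippen WlogP
#' and molar refractivity, and Moriguchi MlogP.
#'
#' XlogP is not computed structurally: by default it is proxied by WlogP and
#' flagged in `xlogp_proxied`; an `xlogp` column on the input (externally
#' computed values) overrides the proxy. The Muegge XlogP window (-2..5) is
#' wide, so the proxy rarely flips a verdict, and the flag keeps it auditable.
#'
#' Hydrogens are materialised before any counting; aromaticity follows the
#' OpenBabel perception model. Descriptors that cannot be computed for a
#' structure are returned as `NA` with a warning, never silently zeroed.
#' Panels are cached per SMILES within the session.
#'
#' @param compounds tibble with `smiles` (and usually `id`) columns, as
#'   returned by [read_library()], or a character vector of SMILES.
#' @return A tibble with one row per compound: `id`, `smiles`, and the panel
#'   columns `mw`, `heavy_atoms`, `heavy_aromatic_atoms`, `fraction_csp3`,
#'   `rotatable_bonds`, `hba`, `hbd`, `lipinski_no`, `lipinski_nhoh`,
#'   `molar_refractivity`, `tpsa`, `wlogp`, `mlogp`, `xlogp`,
#'   `xlogp_proxied`, `total_atoms`, `carbons`, `heteroatoms`, `rings`.
#' @examples
#' compute_descriptors(tibble::tibble(id = "glu",
#'   smiles = "N[C@@H](CCC(O)=O)C(O)=O"))
#' @export
compute_descriptors <- function(compounds) {
  if (is.character(compounds)) {
    compounds <- tibble(id = compounds, smiles = compounds)
  }
  stopifnot("smiles" %in% names(compounds))
  if (!"id" %in% names(compounds)) compounds$id <- compounds$smiles
  rows <- lapply(seq_len(nrow(compounds)), function(i) {
    p <- descriptor_panel_one(compounds$smiles[i])
    p$id <- compounds$id[i]
    if ("xlogp" %in% names(compounds) && !is.na(compounds$xlogp[i])) {
      p$xlogp <- compounds$xlogp[i]
      p$xlogp_proxied <- FALSE
    }
    p
  })
  relocate(bind_rows(rows), "id", "smiles")
}

descriptor_panel_one <- function(smiles) {
  if (is.null(the$panels)) the$panels <- new.env(parent = emptyenv())
  hit <- the$panels[[smiles]]
  if (!is.null(hit)) return(hit)

  mol <- ob_parse_smiles(smiles)
  if (is.null(mol)) abort(paste0("unparseable SMILES: ", smiles))
  atoms <- ob_atoms(mol)
  bonds <- ob_bonds(mol)
  heavy <- atoms$z > 1L

  safely_num <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      warn(paste0(what, " unavailable for ", smiles, ": ",
                  conditionMessage(e)))
      NA_real_
    })
  }

  carbons <- sum(atoms$z == 6L)
  n_components <- graph_components(nrow(atoms), bonds)
  no_idx <- which(atoms$z %in% c(7L, 8L))
  h_on <- function(i) {
    atoms$n_implicit_h[i] +
      sum((bonds$begin == i & atoms$z[bonds$end] == 1L) |
            (bonds$end == i & atoms$z[bonds$begin] == 1L))
  }

  obprops <- ChemmineOB::prop_OB(list(mol))
  cr <- safely_num("WlogP/MR", crippen_logp_mr(smiles))

  panel <- tibble(
    smiles = smiles,
    mw = as.numeric(obprops$MW),
    heavy_atoms = sum(heavy),
    heavy_aromatic_atoms = sum(heavy & atoms$aromatic),
    fraction_csp3 = if (carbons == 0) 0 else
      length(ob_smarts_root_atoms(mol, "[CX4]")) / carbons,
    rotatable_bonds = ob_smarts_count(mol, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"),
    hba = as.integer(obprops$HBA2),
    hbd = as.integer(obprops$HBD),
    lipinski_no = length(no_idx),
    lipinski_nhoh = if (length(no_idx)) sum(vapply(no_idx, h_on, numeric(1)))
      else 0L,
    molar_refractivity = if (length(cr) == 2) cr[["mr"]] else NA_real_,
    tpsa = as.numeric(obprops$TPSA),
    wlogp = if (length(cr) == 2) cr[["wlogp"]] else NA_real_,
    mlogp = safely_num("MlogP", mlogp(smiles)),
    total_atoms = nrow(atoms) + sum(atoms$n_implicit_h),
    carbons = carbons,
    heteroatoms = sum(heavy & atoms$z != 6L),
    rings = max(0L, sum(heavy[bonds$begin] & heavy[bonds$end]) -
                  sum(heavy) + n_components)
  )
  panel$xlogp <- panel$wlogp
  panel$xlogp_proxied <- TRUE
  the$panels[[smiles]] <- panel
  panel
}

graph_components <- function(n, bonds) {
  if (n == 0) return(0L)
  comp <- seq_len(n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$begin[k]; b <- bonds$end[k]
    ra <- a; while (comp[ra] != ra) ra <- comp[ra]
    rb <- b; while (comp[rb] != rb) rb <- comp[rb]
    if (ra != rb) comp[rb] <- ra
  }
  roots <- vapply(seq_len(n), function(i) {
    r <- i; while (comp[r] != r) r <- comp[r]; r
  }, integer(1))
  length(unique(roots))
}
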