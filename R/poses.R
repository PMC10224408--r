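#' Read docking poses
#'
#' Reads a pose file in PDB format (ATOM/HETATM records, one or more
#' MODEL/ENDMDL frames) or the minimal PDBQT dialect (the trailing partial
#' charge / atom-type columns are ignored). Parsing is delegated to the
#' bio3d PDB reader; PDBQT input is reduced to its PDB-compatible columns
#' first. Residue numbers are preserved verbatim.
#'
#' @param path pose file (`.pdb` or `.pdbqt`).
#' @return tibble with one row per atom per frame: `model`, `eleno`,
#'   `name`, `resname`, `resno`, `element`, `x`, `y`, `z`.
#' @export
read_poses <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "leadsieve_io_error")
  src <- path
  if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    keep <- grepl("^(ATOM|HETATM|MODEL|ENDMDL|TER|END)", lines)
    lines <- substr(lines[keep], 1, 66)
    src <- tempfile(fileext = ".pdb")
    on.exit(unlink(src))
    writeLines(lines, src)
  }
  pdb <- bio3d::read.pdb(src, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  ele <- atoms$elesy
  missing_ele <- is.na(ele) | !nzchar(trimws(ele))
  if (any(missing_ele)) {
    # atom2ele messages each name->element mapping; those are expected here
    ele[missing_ele] <- suppressWarnings(
      bio3d::atom2ele(atoms$elety[missing_ele])
    )
  }
  nm <- max(1L, nrow(pdb$xyz))
  frames <- lapply(seq_len(nm), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    tibble(
      model = m, eleno = atoms$eleno, name = trimws(atoms$elety),
      resname = trimws(atoms$resid), resno = atoms$resno,
      element = toupper(trimws(ele)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  })
  bind_rows(frames)
}

pose_heavy <- function(pose) {
  filter(pose, .data$element != "H")
}

directed_min_rmsd <- function(a, b) {
  # mean over atoms of a of the squared distance to the nearest same-element
  # atom of b; the per-atom minimum is independent (not a bijection)
  d2 <- vapply(seq_len(nrow(a)), function(i) {
    cand <- b[b$element == a$element[i], ]
    min((cand$x - a$x[i])^2 + (cand$y - a$y[i])^2 + (cand$z - a$z[i])^2)
  }, numeric(1))
  sqrt(mean(d2))
}

#' Symmetry-corrected RMSD between two poses
#'
#' Computes the distance between two poses of the same molecule in a shared
#' docking frame (no superposition), over heavy atoms only:
#'
#' * `rmsd_lb` -- the symmetry-corrected lower bound
#'   `max(RMSD'(a,b), RMSD'(b,a))`, where `RMSD'(a,b)` is the root mean
#'   over atoms of `a` of the squared distance to the nearest atom of `b`
#'   with the same element type (a per-atom minimum, not a one-to-one
#'   matching);
#' * `rmsd_ub` -- the identity-correspondence RMSD, requiring the two poses
#'   to list the same elements in the same order (`NA` otherwise).
#'
#' `rmsd_lb` is symmetric in its arguments, zero iff the per-element
#' coordinate multisets coincide, and never exceeds `rmsd_ub`.
#'
#' @param a,b pose tibbles ([read_poses()] frames) with `element`, `x`,
#'   `y`, `z`.
#' @return one-row tibble: `rmsd_lb`, `rmsd_ub` (Angstroms).
#' @export
rmsd_symmetry <- function(a, b) {
  a <- pose_heavy(a); b <- pose_heavy(b)
  if (nrow(a) == 0 || nrow(b) == 0) abort("empty pose")
  if (!identical(sort(a$element), sort(b$element))) {
    abort("poses differ in heavy-atom element composition")
  }
  lb <- max(directed_min_rmsd(a, b), directed_min_rmsd(b, a))
  ub <- if (identical(a$element, b$element)) {
    sqrt(mean((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))
  } else {
    NA_real_
  }
  tibble(rmsd_lb = lb, rmsd_ub = ub)
}

#' Polar contacts between a ligand pose and a receptor
#'
#' Finds (ligand polar atom or polar hydrogen, receptor polar atom) pairs
#' whose Euclidean distance lies inside the inclusive window, the range
#' conventionally read as hydrogen-bond contact distances. Polar atoms are
#' N, O and S; a ligand hydrogen is polar when its nearest heavy atom
#' within covalent range (1.2 A) is polar. Both poses must be in the same
#' frame.
#'
#' @param ligand,receptor pose tibbles.
#' @param window inclusive distance window in Angstroms.
#' @return tibble of contacts: ligand atom columns (`ligand_name`,
#'   `ligand_element`), receptor columns (`resname`, `resno`,
#'   `receptor_name`), and `distance`. Empty when there are none.
#' @export
polar_contacts <- function(ligand, receptor, window = c(1.49, 2.81)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  polar <- c("N", "O", "S")
  lig_heavy <- ligand$element %in% polar
  lig_h <- ligand$element == "H"
  if (any(lig_h)) {
    heavy <- ligand[ligand$element != "H", ]
    lig_h[lig_h] <- vapply(which(lig_h), function(i) {
      d2 <- (heavy$x - ligand$x[i])^2 + (heavy$y - ligand$y[i])^2 +
        (heavy$z - ligand$z[i])^2
      j <- which.min(d2)
      length(j) == 1 && d2[j] <= 1.2^2 && heavy$element[j] %in% polar
    }, logical(1))
  }
  lig <- ligand[lig_heavy | lig_h, ]
  rec <- receptor[receptor$element %in% polar, ]
  if (nrow(lig) == 0 || nrow(rec) == 0) {
    return(tibble(ligand_name = character(), ligand_element = character(),
                  resname = character(), resno = integer(),
                  receptor_name = character(), distance = numeric()))
  }
  pairs <- tidyr::expand_grid(i = seq_len(nrow(lig)), j = seq_len(nrow(rec)))
  d <- sqrt((lig$x[pairs$i] - rec$x[pairs$j])^2 +
              (lig$y[pairs$i] - rec$y[pairs$j])^2 +
              (lig$z[pairs$i] - rec$z[pairs$j])^2)
  keep <- d >= window[1] & d <= window[2]
  tibble(
    ligand_name = lig$name[pairs$i[keep]],
    ligand_element = lig$element[pairs$i[keep]],
    resname = rec$resname[pairs$j[keep]],
    resno = rec$resno[pairs$j[keep]],
    receptor_name = rec$name[pairs$j[keep]],
    distance = d[keep]
  )
}

#' Count active torsions in a ligand
#'
#' Counts rotatable (active-torsion) bonds with the standard pattern:
#' non-ring single bonds between two heavy atoms, each bearing at least one
#' further heavy neighbour; bonds to phosphorus count like any other.
#'
#' @param smiles ligand SMILES.
#' @return list with `n` (count) and `bonds`, a tibble of the two atom
#'   indices and element symbols per torsion.
#' @examples
#' count_active_torsions("CCCC")$n  # 1
#' @export
count_active_torsions <- function(smiles) {
  mol <- ob_parse_smiles(smiles)
  if (is.null(mol)) abort(paste0("unparseable SMILES: ", smiles))
  atoms <- ob_atoms(mol)
  maps <- ob_smarts_maps(mol, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")
  sym <- c("6" = "C", "7" = "N", "8" = "O", "15" = "P", "16" = "S")
  bonds <- bind_rows(lapply(maps, function(m) {
    tibble(atom1 = m[1], atom2 = m[2],
           element1 = sym[as.character(atoms$z[m[1]])] %||% "?",
           element2 = sym[as.character(atoms$z[m[2]])] %||% "?")
  }))
  if (nrow(bonds) == 0) {
    bonds <- tibble(atom1 = integer(), atom2 = integer(),
                    element1 = character(), element2 = character())
  }
  list(n = length(maps), bonds = bonds)
}
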