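# Moriguchi logP (MlogP).
#
# The 13-parameter regression of Moriguchi et al. (1992), the lipophilicity
# estimate behind the Lipinski panel's "MlogP <= 4.15" bound:
#
#   MlogP = -1.014 + 1.244 CX^0.6 - 1.017 NO^0.9 + 0.406 PRX - 0.145 UB^0.8
#           + 0.511 HB + 0.268 POL - 2.215 AMP + 0.912 ALK - 0.392 RNG
#           - 3.684 QN + 0.474 NO2 + 1.582 NCS + 0.773 BLM
#
# The structural descriptors are perceived from the connection table. Where
# the original descriptor definitions leave perception open, the reading
# implemented here is documented inline and in the methods vignette; the
# package applies it consistently.

mlogp_features <- function(smiles) {
  mol <- ob_parse_smiles(smiles)
  if (is.null(mol)) abort(paste0("unparseable SMILES: ", smiles))
  atoms <- ob_atoms(mol)
  bonds <- ob_bonds(mol)

  # CX: carbons plus halogens, halogens weighted F 0.5, Cl 1, Br 1.5, I 2
  w <- c(`6` = 1, `9` = 0.5, `17` = 1, `35` = 1.5, `53` = 2)
  cx <- sum(w[as.character(atoms$z)], na.rm = TRUE)

  no <- sum(atoms$z %in% c(7L, 8L))

  # PRX: proximity of N/O pairs - bonded pair 2, geminal (two bonds apart) 1;
  # a carboxamide/urea N-C(=O) pair is promoted from 1 to 2.
  d <- graph_distances(nrow(atoms), bonds)
  noi <- which(atoms$z %in% c(7L, 8L))
  prx <- 0
  if (length(noi) > 1) {
    for (i in seq_along(noi)[-1]) {
      for (j in seq_len(i - 1)) {
        dij <- d[noi[i], noi[j]]
        if (!is.finite(dij)) next
        if (dij == 1) prx <- prx + 2
        if (dij == 2) prx <- prx + 1
      }
    }
  }
  prx <- prx + ob_smarts_count(mol, "[NX3][CX3]=[OX1]")

  # NO2 groups (either nitro writing)
  n_no2 <- ob_smarts_count(mol, "[$([NX3](=O)=O),$([NX3+](=O)[O-])]")

  # UB: unsaturated (double/triple) bonds, nitro N=O bonds excluded
  ub <- sum(bonds$order >= 2L) - ob_smarts_count(mol, "[$([NX3](=O)=O),$([NX3+](=O)[O-])]=[OX1]")

  # HB: intramolecular hydrogen bond, perceived as an ortho aromatic
  # donor/acceptor pair (OH/NH beside C=O, NO2 or OH)
  hb_pats <- c(
    "c([OX2H,NX3H1,NX3H2])c[CX3]=[OX1]",
    "c([OX2H,NX3H1,NX3H2])c[$([NX3](=O)=O),$([NX3+](=O)[O-])]",
    "c([OX2H])c[OX2H]"
  )
  hb <- as.numeric(any(vapply(hb_pats, function(p) ob_smarts_count(mol, p) > 0, logical(1))))

  # POL: polar substituents on aromatic rings - an exocyclic neighbour of an
  # aromatic atom that is a heteroatom, or a carbon double-bonded to N/O or
  # carrying a nitrile
  pol_pats <- c(
    "c!@[#7,#8,#16,#15,F,Cl,Br,I]",
    "c!@[CX3]=[OX1,NX2]",
    "c!@[CX2]#[NX1]"
  )
  pol <- sum(vapply(pol_pats, function(p) length(ob_smarts_root_atoms(mol, p)) , integer(1)))
  # root counting de-duplicates per aromatic attachment atom within a pattern
  # but a heteroatom substituent can also match the carbonyl pattern root; the
  # patterns above are mutually exclusive on the substituent atom, so the sum
  # counts each substituent once.

  # AMP: amphoteric character - alpha-amino acid 1; amino- or
  # pyridine-carboxylic aromatic acid 0.5
  amp <- 0
  if (ob_smarts_count(mol, "[NX3;H2,H1;!$(NC=O)][CX4][CX3](=[OX1])[OX2H]") > 0) {
    amp <- 1
  } else if (ob_smarts_count(mol, "c[CX3](=[OX1])[OX2H]") > 0 &&
             (ob_smarts_count(mol, "[NX3;H2,H1]c") > 0 ||
              ob_smarts_count(mol, "n") > 0)) {
    amp <- 0.5
  }

  # ALK: hydrocarbon (C/H only) with no aromatic system and at most one
  # double bond, no triple bond
  alk <- as.numeric(
    all(atoms$z == 6L) && !any(atoms$aromatic) &&
      sum(bonds$order == 2L) <= 1L && !any(bonds$order >= 3L)
  )

  # RNG: ring structures other than pure benzenoid (all-carbon aromatic) rings
  ring_atoms <- which(atoms$in_ring)
  rng <- as.numeric(length(ring_atoms) > 0 &&
                      any(!atoms$aromatic[ring_atoms] | atoms$z[ring_atoms] != 6L))

  # QN: quaternary nitrogen 1, N-oxide 0.5
  qn <- 0
  if (ob_smarts_count(mol, "[NX4,NX4+]") > 0) {
    qn <- 1
  } else if (ob_smarts_count(mol, "[NX3+;!$([NX3+](=O)[O-])][OX1-]") > 0 ||
             ob_smarts_count(mol, "[nX3+][OX1-]") > 0) {
    qn <- 0.5
  }

  # NCS: isothiocyanate 1 each, thiocyanate 0.5 each
  ncs <- ob_smarts_count(mol, "[NX2]=C=[SX1]") +
    0.5 * ob_smarts_count(mol, "[SX2][CX2]#[NX1]")

  # BLM: beta-lactam ring
  blm <- as.numeric(ob_smarts_count(mol, "[#7]1[#6](=[OX1])[#6][#6]1") > 0)

  c(cx = cx, no = no, prx = prx, ub = ub, hb = hb, pol = pol, amp = amp,
    alk = alk, rng = rng, qn = qn, no2 = n_no2, ncs = ncs, blm = blm)
}

mlogp_from_features <- function(f) {
  -1.014 + 1.244 * f[["cx"]]^0.6 - 1.017 * f[["no"]]^0.9 +
    0.406 * f[["prx"]] - 0.145 * f[["ub"]]^0.8 + 0.511 * f[["hb"]] +
    0.268 * f[["pol"]] - 2.215 * f[["amp"]] + 0.912 * f[["alk"]] -
    0.392 * f[["rng"]] - 3.684 * f[["qn"]] + 0.474 * f[["no2"]] +
    1.582 * f[["ncs"]] + 0.773 * f[["blm"]]
}

mlogp <- function(smiles) {
  mlogp_from_features(mlogp_features(smiles))
}

# All-pairs shortest path lengths on the molecular graph (BFS per atom).
graph_distances <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$begin[k]; b <- bonds$end[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(d[s, nxt])]
      if (length(nxt)) d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}
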