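# Shared helpers: benign annotation rows, tiny libraries, independent oracles.

benign_annotation <- function(id) {
  flags <- c(
    "mutagenicity", "genotoxic_carcinogenicity",
    "nongenotoxic_carcinogenicity", "tumorigenesis", "irritation_corrosion",
    "reproductive_effect", "dna_binding_alert", "protein_binding_alert"
  )
  ann <- tibble::tibble(
    id = id, cramer_class = "I", solubility_class = "soluble",
    gi_absorption = "high", bbb_permeant = FALSE, pgp_interaction = FALSE,
    overall_druglikeness = 0.95, lead_likeness_pass = TRUE, sa_score = 5,
    bioavailability_score = 0.55, clogp = 2, clogd = 1, basic_pka = 7
  )
  for (f in flags) ann[[f]] <- FALSE
  for (iso in c("1a2", "2c19", "2c9", "2d6", "3a4")) {
    ann[[paste0("cyp", iso, "_inhibition")]] <- FALSE
  }
  for (route in c("ip", "iv", "oral", "sc")) {
    ann[[paste0("ld50_", route)]] <- 1500
    ann[[paste0("ld50_", route, "_in_ad")]] <- TRUE
  }
  for (b in c("gpcr_ligand", "ion_channel_modulator", "kinase_inhibitor",
              "nuclear_receptor_ligand", "protease_inhibitor",
              "enzyme_inhibitor")) {
    ann[[paste0("bioactivity_", b)]] <- -0.2
  }
  ann
}

# library of n copies of a clean drug-like template
clean_library <- function(ids) {
  tibble::tibble(id = ids, smiles = "COc1ccc2cc(C(C)C(=O)O)ccc2c1",
                 name = NA_character_)
}

make_pose <- function(elements, coords, names = NULL) {
  tibble::tibble(
    model = 1L, eleno = seq_along(elements),
    name = names %||% paste0(elements, seq_along(elements)),
    resname = "LIG", resno = 1L, element = elements,
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force directed min-match RMSD oracle (independent of the package's
# vectorised implementation): explicit double loop over the distance matrix
oracle_rmsd_lb <- function(a, b) {
  a <- a[a$element != "H", ]
  b <- b[b$element != "H", ]
  dir <- function(p, q) {
    tot <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        if (q$element[j] == p$element[i]) {
          d2 <- (p$x[i] - q$x[j])^2 + (p$y[i] - q$y[j])^2 +
            (p$z[i] - q$z[j])^2
          if (d2 < best) best <- d2
        }
      }
      tot <- tot + best
    }
    sqrt(tot / nrow(p))
  }
  max(dir(a, b), dir(b, a))
}
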