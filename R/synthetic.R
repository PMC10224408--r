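#' Fixture specification for the synthetic-data generator
#'
#' Describes a synthetic screening study: library size, target retention,
#' per-step elimination quotas, annotation noise, and the docking-fixture
#' shape. The defaults emulate the study conditions of the screening worked
#' example: a 123-member library of which 9 survive (7.3%), generated with
#' seed 42. Per-step quotas front-load attrition into the early toxicity
#' steps, the usual shape when whole structural classes fall to toxicity
#' alerts.
#'
#' @param n_compounds library size.
#' @param n_retained number of survivors the cascade must retain.
#' @param seed integer seed; all generation randomness derives from it.
#' @param step_quotas named integer vector (names are step ids `"1"`-`"10"`)
#'   summing to `n_compounds - n_retained`.
#' @param dock docking-fixture shape: `n_clusters`, `elements_per_cluster`,
#'   `energy_mean` (scalar or per-cluster), `energy_sd`.
#' @param pose pose-fixture shape: `elements` (heavy-atom skeleton) and
#'   `jitter_sd` (Angstroms).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_compounds = 123, n_retained = 9, seed = 42,
                         step_quotas = c(`1` = 30, `2` = 25, `3` = 12,
                                         `4` = 8, `5` = 7, `6` = 5, `7` = 8,
                                         `8` = 6, `9` = 8, `10` = 5),
                         dock = list(n_clusters = 3, elements_per_cluster = 10,
                                     energy_mean = c(-8.1, -7.6, -6.8),
                                     energy_sd = 0.4),
                         pose = list(elements = c("C", "C", "C", "C", "O",
                                                  "O", "N", "P"),
                                     jitter_sd = 0.3)) {
  if (is.null(names(step_quotas)) && length(step_quotas) > 0) {
    names(step_quotas) <- seq_along(step_quotas)
  }
  step_quotas <- step_quotas[step_quotas > 0]
  if (!all(names(step_quotas) %in% as.character(1:10))) {
    abort("step_quotas names must be step ids 1-10")
  }
  if (n_retained < 0 || n_retained > n_compounds) {
    abort("n_retained must lie in [0, n_compounds]")
  }
  if (sum(step_quotas) != n_compounds - n_retained) {
    abort(paste0("infeasible quotas: steps eliminate ", sum(step_quotas),
                 " but n_compounds - n_retained = ",
                 n_compounds - n_retained))
  }
  structure(
    list(n_compounds = n_compounds, n_retained = n_retained, seed = seed,
         step_quotas = step_quotas, dock = dock, pose = pose),
    class = "fixture_spec"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Template molecules spanning the rule-panel boundaries, with the violation
# profile role each cascade-step target needs. Profiles are re-derived from
# the package's own descriptor panel at generation time, so generation fails
# loudly (rather than silently missing quotas) if a template stops
# qualifying for its role.
fixture_templates <- function() {
  tibble(
    name = c("naproxen", "ibuprofen", "salbutamol", "atenolol",
             "hydrazine", "methylhydrazine", "propane", "butane",
             "undecylbenzene", "dodecylbenzene",
             "decylbenzene", "octamine_c8", "decaol"),
    smiles = c(
      "COc1ccc2cc(C(C)C(=O)O)ccc2c1",
      "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
      "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",
      "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
      "NN", "CNN", "CCC", "CCCC",
      "CCCCCCCCCCCc1ccccc1", "CCCCCCCCCCCCc1ccccc1",
      "CCCCCCCCCCc1ccccc1", "CCCCCCCCNCCNCCNCCNCCNCCN",
      "OCC(O)C(O)C(O)C(O)C(O)C(O)C(O)C(O)CO"
    )
  )
}

template_roles <- function() {
  list(
    clean = function(v) v$lipinski_violations == 0 & v$ghose_violations == 0 &
      v$veber_violations == 0 & v$muegge_violations == 0,
    ghose4 = function(v) v$ghose_violations == 4 & v$muegge_violations >= 1 &
      v$lipinski_violations == 0 & v$veber_violations == 0,
    ghose3 = function(v) v$ghose_violations == 3 & v$muegge_violations >= 2 &
      v$lipinski_violations == 0 & v$veber_violations == 0,
    ghose_low = function(v) v$ghose_violations >= 1 & v$ghose_violations <= 2 &
      v$muegge_violations >= 1,
    ghose0_muegge2 = function(v) v$ghose_violations == 0 &
      v$muegge_violations >= 2 & v$veber_violations == 0,
    # Step-2 rule route: breaks Lipinski and Veber, and its panel-driven MPO
    # components (MW, TPSA, HBD) are poor enough that a basic pKa above 9
    # pins the CNS MPO total below 4 whatever the lipophilicity inputs.
    lipveb = function(v) v$lipinski_violations >= 1 &
      v$veber_violations >= 1 & v$d_mw + v$d_tpsa + v$d_hbd <= 1
  )
}

# Step target -> template role and annotation adjustments
step_role <- c(`4` = "ghose4", `5` = "ghose3", `6` = "ghose_low",
               `7` = "ghose_low", `8` = "ghose_low", `9` = "ghose_low",
               `10` = "ghose0_muegge2")

taxonomy_ids <- function(n) {
  stopifnot(n <= 625)
  i <- seq_len(n) - 1L
  paste0(i %% 5 + 1L,
         LETTERS[(i %/% 25) %% 5 + 1L],
         letters[(i %/% 125) %% 5 + 1L],
         (i %/% 5) %% 5 + 1L)
}

flag_names <- function() {
  c("mutagenicity", "genotoxic_carcinogenicity",
    "nongenotoxic_carcinogenicity", "tumorigenesis", "irritation_corrosion",
    "reproductive_effect", "dna_binding_alert", "protein_binding_alert")
}

#' Generate a synthetic compound library with annotations
#'
#' Builds a seeded library whose cascade outcome is fixed by construction:
#' each compound is assigned a target (retained, or eliminated at step k per
#' the fixture quotas), given a template structure whose rule-violation
#' profile fits that target, and annotated so that exactly the targeted
#' step's predicate is the first to fire. Assignment is deterministic given
#' the seed; stochastic noise is layered only onto fields that cannot flip
#' the targeted outcome. By default the generated library is verified by
#' running the cascade and checking the quotas, so an infeasibility aborts
#' generation instead of surfacing downstream.
#'
#' The library emulates the screening study's statistical shape (size,
#' taxonomy-coded ids, rule-boundary spread of the structures), not its
#' chemistry: templates are ordinary reference molecules, and passing
#' fixtures says nothing about any particular real compound series.
#'
#' @param spec a [fixture_spec()].
#' @param verify run the cascade and check quotas (default `TRUE`).
#' @return list: `compounds`, `annotations`, `targets` (tibble of compound
#'   id and targeted step, `NA` for retained), `spec`.
#' @examples
#' fx <- gen_library(fixture_spec(n_compounds = 10, n_retained = 10,
#'   step_quotas = integer()))
#' nrow(fx$compounds)
#' @export
gen_library <- function(spec = fixture_spec(), verify = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  tpl <- fixture_templates()
  panels <- compute_descriptors(rename(tpl, id = "name"))
  viol <- count_rule_violations(evaluate_rules(panels))
  mpo_parts <- cns_mpo(tibble(
    clogp = 0, clogd = 0, basic_pka = 0,
    mw = panels$mw, tpsa = panels$tpsa, hbd = panels$hbd
  ))
  viol <- bind_cols(viol[match(panels$id, viol$id), ],
                    mpo_parts[, c("d_mw", "d_tpsa", "d_hbd")])
  roles <- template_roles()
  role_members <- lapply(roles, function(f) viol$id[f(viol)])
  needed_roles <- unique(c(
    "clean",
    unname(step_role[names(spec$step_quotas)[
      names(spec$step_quotas) %in% names(step_role)]]),
    if ("2" %in% names(spec$step_quotas)) "lipveb"
  ))
  for (r in needed_roles) {
    if (length(role_members[[r]]) == 0) {
      abort(paste0("generation infeasible: no template with profile '", r,
                   "'"))
    }
  }

  n <- spec$n_compounds
  targets <- c(
    rep(as.integer(names(spec$step_quotas)), spec$step_quotas),
    rep(NA_integer_, spec$n_retained)
  )
  flags <- flag_names()

  with_seed(spec$seed, {
    targets <- sample(targets)
    ids <- taxonomy_ids(n)
    role_count <- new.env(parent = emptyenv())
    pick <- function(role) {
      members <- role_members[[role]]
      k <- (role_count[[role]] %||% 0L)
      role_count[[role]] <- k + 1L
      members[(k %% length(members)) + 1L]
    }
    s2_variant <- 0L
    s10_variant <- 0L

    rows <- vector("list", n)
    smiles_of <- setNames(tpl$smiles, tpl$name)
    for (i in seq_len(n)) {
      tgt <- targets[i]
      ann <- list(
        id = ids[i], cramer_class = "I",
        solubility_class = sample(c("highly", "soluble", "moderately"), 1),
        gi_absorption = "high",
        bbb_permeant = runif(1) < 0.3, pgp_interaction = FALSE,
        overall_druglikeness = runif(1, 0.92, 0.99),
        lead_likeness_pass = TRUE,
        sa_score = runif(1, 4.2, 6.5),
        bioavailability_score = 0.55,
        clogp = runif(1, 1, 3), clogd = runif(1, 0, 1.5),
        basic_pka = runif(1, 5, 7.5)
      )
      for (f in flags) ann[[f]] <- FALSE
      for (isoform in c("1a2", "2c19", "2c9", "2d6", "3a4")) {
        ann[[paste0("cyp", isoform, "_inhibition")]] <- FALSE
      }
      for (route in c("ip", "iv", "oral", "sc")) {
        ann[[paste0("ld50_", route)]] <- round(runif(1, 300, 5500), 1)
        ann[[paste0("ld50_", route, "_in_ad")]] <- runif(1) < 0.9
      }
      for (b in c("gpcr_ligand", "ion_channel_modulator", "kinase_inhibitor",
                  "nuclear_receptor_ligand", "protease_inhibitor",
                  "enzyme_inhibitor")) {
        ann[[paste0("bioactivity_", b)]] <- round(rnorm(1, -0.2, 0.4), 2)
      }

      template <- pick("clean")
      if (is.na(tgt)) {
        # retained: benign defaults as-is
      } else if (tgt == 1L) {
        on_flags <- sample(flags, sample(2:4, 1))
        for (f in on_flags) ann[[f]] <- TRUE
        ann$cramer_class <- sample(c("II", "III"), 1)
      } else if (tgt == 2L) {
        v <- s2_variant %% 4L
        s2_variant <- s2_variant + 1L
        if (v == 0L) {
          ann$solubility_class <- sample(c("poorly", "insoluble"), 1)
        } else if (v == 1L) {
          iso <- sample(c("1a2", "2c19", "2c9", "2d6", "3a4"), 1)
          ann[[paste0("cyp", iso, "_inhibition")]] <- TRUE
        } else if (v == 2L) {
          ann$pgp_interaction <- TRUE
        } else {
          template <- pick("lipveb")
          ann$basic_pka <- runif(1, 9.2, 10)  # drags CNS MPO below 4
        }
      } else if (tgt == 3L) {
        ann$cramer_class <- "III"
        ann[[sample(flags, 1)]] <- TRUE
        ann$overall_druglikeness <- runif(1, 0.6, 0.88)
      } else if (tgt %in% 4:10) {
        template <- pick(step_role[[as.character(tgt)]])
        if (tgt == 4L) {
          ann$cramer_class <- sample(c("II", "III"), 1)
        } else if (tgt %in% c(5L, 7L)) {
          ann$cramer_class <- "III"
        } else if (tgt == 6L) {
          ann$cramer_class <- "III"
          ann$sa_score <- runif(1, 1.1, 1.9)
        } else if (tgt == 8L) {
          ann$gi_absorption <- "low"
        } else if (tgt == 9L) {
          ann$sa_score <- runif(1, 1.2, 3.8)
        } else if (tgt == 10L) {
          ann$cramer_class <- "III"
          if (s10_variant %% 2L == 0L) {
            ann$sa_score <- runif(1, 1.5, 2.8)
          } else {
            ann$overall_druglikeness <- runif(1, 0.2, 0.45)
          }
          s10_variant <- s10_variant + 1L
        }
      }
      rows[[i]] <- c(ann, list(.template = template))
    }

    templates_used <- vapply(rows, function(r) r$.template, character(1))
    compounds <- tibble(
      id = ids,
      smiles = unname(smiles_of[templates_used]),
      name = templates_used
    )
    ann_tbl <- bind_rows(lapply(rows, function(r) {
      as_tibble(r[setdiff(names(r), ".template")])
    }))
    # column order per schema
    schema_cols <- annotation_schema()$column
    ann_tbl <- ann_tbl[, c(intersect(schema_cols, names(ann_tbl)),
                           setdiff(names(ann_tbl), schema_cols))]
    out <- list(
      compounds = compounds,
      annotations = ann_tbl,
      targets = tibble(id = ids, step = targets),
      spec = spec
    )
  })

  if (verify) {
    res <- run_cascade(out$compounds, out$annotations)
    got <- out$targets |> left_join(res$records[, c("id", "step", "outcome")],
                                    by = "id", suffix = c("_want", "_got"))
    bad <- got$id[!identical_na(got$step_want, got$step_got)]
    if (length(bad)) {
      abort(paste0("generation failed to meet quotas: compound ", bad[1],
                   " targeted step ",
                   got$step_want[got$id == bad[1]], " but landed at ",
                   got$step_got[got$id == bad[1]]))
    }
  }
  out
}

identical_na <- function(a, b) {
  (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
}

#' Generate docking fixtures
#'
#' Seeded cluster energetics and jittered poses with the statistical shape
#' docking post-processing expects: per-cluster element energies drawn from
#' a normal distribution around the cluster mean, a cluster binding free
#' energy defined as its lowest element energy, and one pose per element --
#' a fixed heavy-atom skeleton plus Gaussian coordinate jitter. A
#' permuted-atom-order duplicate of the first pose is included for RMSD
#' symmetry checks.
#'
#' @param spec a [fixture_spec()] (only `dock`, `pose` and `seed` are used).
#' @return list: `clusters` (long tibble: `cluster`, `element`, `energy`,
#'   `dg`), `poses` (tibble: `cluster`, `element`, `name`, `element_symbol`
#'   ... coordinates), `permuted_pose` (atom-order permutation of the first
#'   pose), `spec`.
#' @export
gen_dock_fixtures <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  d <- spec$dock
  p <- spec$pose
  mean_e <- rep(d$energy_mean, length.out = d$n_clusters)
  with_seed(spec$seed + 1L, {
    clusters <- bind_rows(lapply(seq_len(d$n_clusters), function(k) {
      e <- rnorm(d$elements_per_cluster, mean_e[k], d$energy_sd)
      tibble(cluster = k, element = seq_along(e), energy = e,
             dg = min(e))
    }))
    skeleton <- tibble(
      element = p$elements,
      x = seq_along(p$elements) * 1.5,
      y = rep_len(c(0, 0.8), length(p$elements)),
      z = 0
    )
    poses <- bind_rows(lapply(seq_len(d$n_clusters), function(k) {
      bind_rows(lapply(seq_len(d$elements_per_cluster), function(el) {
        tibble(
          cluster = k, element_id = el,
          name = paste0(skeleton$element, seq_len(nrow(skeleton))),
          element = skeleton$element,
          x = skeleton$x + rnorm(nrow(skeleton), 0, p$jitter_sd),
          y = skeleton$y + rnorm(nrow(skeleton), 0, p$jitter_sd),
          z = skeleton$z + rnorm(nrow(skeleton), 0, p$jitter_sd)
        )
      }))
    }))
    first <- poses |> filter(.data$cluster == 1, .data$element_id == 1)
    same <- split(seq_len(nrow(first)), first$element)
    perm <- seq_len(nrow(first))
    swappable <- Filter(function(ix) length(ix) >= 2, same)
    if (length(swappable)) {
      ix <- swappable[[1]][1:2]
      perm[ix] <- rev(perm[ix])
    }
    permuted <- first[perm, ]
    list(clusters = clusters, poses = poses, permuted_pose = permuted,
         spec = spec)
  })
}

#' Write docking fixtures to disk
#'
#' Emits the cluster table as CSV and each cluster's poses as a multi-MODEL
#' PDB file (plus the permuted duplicate), the same formats the docking
#' post-processing readers consume.
#'
#' @param fixtures result of [gen_dock_fixtures()].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_dock_fixtures <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl_path <- file.path(dir, "clusters.csv")
  readr::write_csv(fixtures$clusters, cl_path)
  paths <- list(clusters = cl_path)
  for (k in unique(fixtures$poses$cluster)) {
    path <- file.path(dir, paste0("cluster", k, ".pdb"))
    pk <- fixtures$poses |> filter(.data$cluster == k)
    lines <- unlist(lapply(split(pk, pk$element_id), function(m) {
      c(sprintf("MODEL     %4d", m$element_id[1]),
        pdb_atom_lines(m), "ENDMDL")
    }), use.names = FALSE)
    writeLines(c(lines, "END"), path)
    paths[[paste0("cluster", k)]] <- path
  }
  perm_path <- file.path(dir, "pose_permuted.pdb")
  writeLines(c(pdb_atom_lines(fixtures$permuted_pose), "END"), perm_path)
  paths$permuted <- perm_path
  invisible(paths)
}

pdb_atom_lines <- function(atoms) {
  sprintf(
    "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)), substr(atoms$name, 1, 4), "LIG", 1L,
    atoms$x, atoms$y, atoms$z, atoms$element
  )
}
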