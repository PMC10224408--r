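#' Screening cascade configuration
#'
#' The ten-step elimination cascade removes reactive, toxic or otherwise
#' unpromising library members in a fixed order; a compound is eliminated at
#' the FIRST step whose predicate holds and is never revisited. The default
#' predicates are:
#'
#' 1. at least `tox_classes_step1` (2) positive toxicity flags;
#' 2. breaks Lipinski and Veber with CNS MPO below `cnsmpo_min` (4), OR is
#'    poorly soluble / insoluble, OR inhibits any CYP isoform, OR interacts
#'    with P-gp;
#' 3. Cramer class III with at least one toxicity flag and overall
#'    drug-likeness not exceeding `druglikeness_step3` (0.90);
#' 4. all four Ghose criteria violated, and Cramer class II/III or at least
#'    one Muegge violation;
#' 5. at least three Ghose and two Muegge violations, Cramer III;
#' 6. Cramer III, at least one Ghose and one Muegge violation, synthetic
#'    accessibility below `sa_step6` (2);
#' 7. Cramer III, at least one Ghose and one Muegge violation, any SA;
#' 8. at least one Ghose and one Muegge violation with low GI absorption;
#' 9. at least one Ghose and one Muegge violation with SA below
#'    `sa_step9` (4), any Cramer class;
#' 10. Cramer III with at least two Muegge violations and SA below
#'    `sa_step10` (3) or overall drug-likeness below
#'    `druglikeness_step10` (0.5).
#'
#' Two switches resolve ambiguities in the narrative step wording:
#' `step2_strict_and` conjoins all Step-2 clauses instead of the default
#' disjunction of the rule-based and annotation-based parts, and
#' `step4_muegge_with_ghose` attaches Step 4's Muegge alternative to the
#' Ghose clause rather than (default) to the Cramer clause. A predicate
#' clause whose annotation field is missing evaluates as not triggered and
#' the compound is tagged with a warning: compounds are never eliminated on
#' absent evidence.
#'
#' @param ... threshold or switch overrides (see defaults above).
#' @param steps integer vector of enabled step ids, in order.
#' @param rule_overrides passed to [rule_bounds()].
#' @return object of class `cascade_config`.
#' @export
cascade_config <- function(..., steps = 1:10, rule_overrides = NULL) {
  cfg <- list(
    tox_classes_step1 = 2,
    cnsmpo_min = 4,
    druglikeness_step3 = 0.90,
    sa_step6 = 2,
    sa_step9 = 4,
    sa_step10 = 3,
    druglikeness_step10 = 0.5,
    step2_strict_and = FALSE,
    step4_muegge_with_ghose = FALSE,
    steps = steps,
    rule_overrides = rule_overrides,
    toxicity_flags = c(
      "mutagenicity", "genotoxic_carcinogenicity",
      "nongenotoxic_carcinogenicity", "tumorigenesis",
      "irritation_corrosion", "reproductive_effect",
      "dna_binding_alert", "protein_binding_alert"
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown cascade_config fields: ",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "cascade_config")
}

#' Read / write a cascade configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_cascade_config()] returns a `cascade_config`;
#'   [write_cascade_config()] returns `path` invisibly.
#' @export
read_cascade_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(cascade_config, raw)
}

#' @rdname read_cascade_config
#' @param config a `cascade_config`.
#' @export
write_cascade_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Clause bookkeeping: each step predicate returns, per compound, fired
# (TRUE/FALSE, never NA) plus human-readable triggered clauses. NA clause
# values count as FALSE and add a warning.
clause <- function(value, field, observed, bound) {
  list(value = value, field = field, observed = observed, bound = bound)
}

na_false <- function(x) !is.na(x) & x

#' Run the elimination cascade
#'
#' Joins the compound library with its descriptor-derived rule violations
#' and annotations, then applies the configured steps in order with
#' eliminated-at-first-match semantics. Every compound receives exactly one
#' outcome and an audit record of the clauses that triggered it.
#'
#' @param compounds compound tibble ([read_library()]).
#' @param annotations annotation tibble ([read_annotations()]).
#' @param config a [cascade_config()].
#' @param panels optional precomputed descriptor tibble; computed from
#'   `compounds` when omitted.
#' @return object of class `cascade_result`: a list with `records` (tibble:
#'   `id`, `outcome`, `step`, `triggered`, `warnings`), `summary`
#'   (a [screening_summary()] tibble), `data` (the joined working table)
#'   and `config`.
#' @examples
#' fx <- gen_library(fixture_spec(n_compounds = 20, n_retained = 17,
#'   step_quotas = c(`1` = 1, `3` = 1, `9` = 1)))
#' res <- run_cascade(fx$compounds, fx$annotations)
#' res$summary
#' @export
run_cascade <- function(compounds, annotations, config = cascade_config(),
                        panels = NULL) {
  stopifnot(inherits(config, "cascade_config"))
  if (nrow(compounds) == 0) {
    warn("empty compound library")
    return(new_cascade_result(
      tibble(id = character(), outcome = character(), step = integer(),
             triggered = list(), warnings = list()),
      tibble(), config))
  }
  if (is.null(panels)) panels <- compute_descriptors(compounds)
  rules <- evaluate_rules(panels, rule_bounds(config$rule_overrides))
  viol <- count_rule_violations(rules)
  dat <- compounds |>
    left_join(panels[, setdiff(names(panels), "smiles")], by = "id") |>
    left_join(viol, by = "id") |>
    left_join(annotations, by = "id")

  dat$n_tox_flags <- rowSums(
    as.matrix(dat[, intersect(config$toxicity_flags, names(dat))]),
    na.rm = TRUE
  )
  dat$any_cyp <- apply(
    as.matrix(dat[, grep("^cyp.*_inhibition$", names(dat))]), 1,
    function(r) any(na_false(r))
  )
  mpo_in <- tibble(clogp = dat$clogp, clogd = dat$clogd, mw = dat$mw,
                   tpsa = dat$tpsa, hbd = dat$hbd, basic_pka = dat$basic_pka)
  dat$cns_mpo <- cns_mpo(mpo_in)$cns_mpo

  n <- nrow(dat)
  outcome <- rep("retained", n)
  step <- rep(NA_integer_, n)
  triggered <- vector("list", n)
  warnings <- vector("list", n)

  preds <- cascade_step_predicates(config)
  for (s in config$steps) {
    pred <- preds[[as.character(s)]]
    if (is.null(pred)) abort(paste0("no predicate for step ", s))
    res <- pred(dat)
    hit <- which(outcome == "retained" & res$fired)
    for (i in hit) {
      outcome[i] <- "eliminated"
      step[i] <- s
      triggered[[i]] <- res$clauses[[i]]
    }
    miss <- which(outcome == "retained" & res$missing != "")
    for (i in miss) {
      warnings[[i]] <- unique(c(warnings[[i]], res$missing[i]))
    }
  }
  records <- tibble(
    id = dat$id, outcome = outcome, step = step,
    triggered = triggered,
    warnings = lapply(warnings, function(w) w %||% character())
  )
  new_cascade_result(records, dat, config)
}

new_cascade_result <- function(records, data, config) {
  structure(
    list(records = records,
         summary = screening_summary(records),
         data = data, config = config),
    class = "cascade_result"
  )
}

# Build the list of step predicate closures for a config. Each takes the
# joined working table and returns list(fired, clauses, missing).
cascade_step_predicates <- function(cfg) {
  # helper evaluating a conjunction of named clause vectors with NA->FALSE
  conj <- function(...) {
    parts <- list(...)
    fired <- Reduce(`&`, lapply(parts, function(p) na_false(p$value)))
    list(parts = parts, fired = fired)
  }
  missing_fields <- function(dat, fields) {
    vapply(seq_len(nrow(dat)), function(i) {
      miss <- fields[vapply(fields, function(f) is.na(dat[[f]][i]), logical(1))]
      if (length(miss)) paste0("missing annotation: ",
                               paste(miss, collapse = ", ")) else ""
    }, character(1))
  }
  describe <- function(parts, i) {
    hits <- list()
    for (p in parts) {
      if (isTRUE(na_false(p$value)[i])) {
        hits[[length(hits) + 1]] <-
          tibble(field = p$field, observed = as.character(p$observed[i]),
                 bound = p$bound)
      }
    }
    if (length(hits)) bind_rows(hits) else
      tibble(field = character(), observed = character(), bound = character())
  }
  finalize <- function(dat, fired, parts, fields) {
    list(
      fired = fired,
      clauses = lapply(seq_len(nrow(dat)), function(i) {
        if (fired[i]) describe(parts, i) else NULL
      }),
      missing = missing_fields(dat, fields)
    )
  }

  list(
    `1` = function(dat) {
      c1 <- clause(dat$n_tox_flags >= cfg$tox_classes_step1,
                   "n_tox_flags", dat$n_tox_flags,
                   paste0(">= ", cfg$tox_classes_step1))
      finalize(dat, na_false(c1$value), list(c1), character())
    },
    `2` = function(dat) {
      lip <- clause(dat$lipinski_violations >= 1, "lipinski_violations",
                    dat$lipinski_violations, ">= 1")
      veb <- clause(dat$veber_violations >= 1, "veber_violations",
                    dat$veber_violations, ">= 1")
      mpo <- clause(dat$cns_mpo < cfg$cnsmpo_min, "cns_mpo", dat$cns_mpo,
                    paste0("< ", cfg$cnsmpo_min))
      sol <- clause(dat$solubility_class %in% c("poorly", "insoluble") &
                      !is.na(dat$solubility_class),
                    "solubility_class", dat$solubility_class,
                    "poorly/insoluble")
      cyp <- clause(dat$any_cyp, "cyp_inhibition", dat$any_cyp, "any isoform")
      pgp <- clause(dat$pgp_interaction, "pgp_interaction",
                    dat$pgp_interaction, "TRUE")
      rulepart <- na_false(lip$value) & na_false(veb$value) &
        na_false(mpo$value)
      fired <- if (cfg$step2_strict_and) {
        rulepart & na_false(sol$value) & na_false(cyp$value) &
          na_false(pgp$value)
      } else {
        rulepart | na_false(sol$value) | na_false(cyp$value) |
          na_false(pgp$value)
      }
      finalize(dat, fired, list(lip, veb, mpo, sol, cyp, pgp),
               c("solubility_class", "pgp_interaction"))
    },
    `3` = function(dat) {
      cr <- clause(dat$cramer_class == "III", "cramer_class",
                   dat$cramer_class, "III")
      fl <- clause(dat$n_tox_flags >= 1, "n_tox_flags", dat$n_tox_flags,
                   ">= 1")
      dl <- clause(dat$overall_druglikeness <= cfg$druglikeness_step3,
                   "overall_druglikeness", dat$overall_druglikeness,
                   paste0("<= ", cfg$druglikeness_step3))
      p <- conj(cr, fl, dl)
      finalize(dat, p$fired, p$parts,
               c("cramer_class", "overall_druglikeness"))
    },
    `4` = function(dat) {
      gh <- clause(dat$ghose_violations == 4, "ghose_violations",
                   dat$ghose_violations, "= 4")
      cr <- clause(dat$cramer_class %in% c("II", "III") &
                     !is.na(dat$cramer_class),
                   "cramer_class", dat$cramer_class, "II or III")
      mg <- clause(dat$muegge_violations >= 1, "muegge_violations",
                   dat$muegge_violations, ">= 1")
      fired <- if (cfg$step4_muegge_with_ghose) {
        (na_false(gh$value) | na_false(mg$value)) & na_false(cr$value)
      } else {
        na_false(gh$value) & (na_false(cr$value) | na_false(mg$value))
      }
      finalize(dat, fired, list(gh, cr, mg), "cramer_class")
    },
    `5` = function(dat) {
      p <- conj(
        clause(dat$ghose_violations >= 3, "ghose_violations",
               dat$ghose_violations, ">= 3"),
        clause(dat$muegge_violations >= 2, "muegge_violations",
               dat$muegge_violations, ">= 2"),
        clause(dat$cramer_class == "III", "cramer_class", dat$cramer_class,
               "III")
      )
      finalize(dat, p$fired, p$parts, "cramer_class")
    },
    `6` = function(dat) {
      p <- conj(
        clause(dat$cramer_class == "III", "cramer_class", dat$cramer_class,
               "III"),
        clause(dat$ghose_violations >= 1, "ghose_violations",
               dat$ghose_violations, ">= 1"),
        clause(dat$muegge_violations >= 1, "muegge_violations",
               dat$muegge_violations, ">= 1"),
        clause(dat$sa_score < cfg$sa_step6, "sa_score", dat$sa_score,
               paste0("< ", cfg$sa_step6))
      )
      finalize(dat, p$fired, p$parts, c("cramer_class", "sa_score"))
    },
    `7` = function(dat) {
      p <- conj(
        clause(dat$cramer_class == "III", "cramer_class", dat$cramer_class,
               "III"),
        clause(dat$ghose_violations >= 1, "ghose_violations",
               dat$ghose_violations, ">= 1"),
        clause(dat$muegge_violations >= 1, "muegge_violations",
               dat$muegge_violations, ">= 1")
      )
      finalize(dat, p$fired, p$parts, "cramer_class")
    },
    `8` = function(dat) {
      p <- conj(
        clause(dat$ghose_violations >= 1, "ghose_violations",
               dat$ghose_violations, ">= 1"),
        clause(dat$muegge_violations >= 1, "muegge_violations",
               dat$muegge_violations, ">= 1"),
        clause(dat$gi_absorption == "low", "gi_absorption",
               dat$gi_absorption, "low")
      )
      finalize(dat, p$fired, p$parts, "gi_absorption")
    },
    `9` = function(dat) {
      p <- conj(
        clause(dat$ghose_violations >= 1, "ghose_violations",
               dat$ghose_violations, ">= 1"),
        clause(dat$muegge_violations >= 1, "muegge_violations",
               dat$muegge_violations, ">= 1"),
        clause(dat$sa_score < cfg$sa_step9, "sa_score", dat$sa_score,
               paste0("< ", cfg$sa_step9))
      )
      finalize(dat, p$fired, p$parts, "sa_score")
    },
    `10` = function(dat) {
      cr <- clause(dat$cramer_class == "III", "cramer_class",
                   dat$cramer_class, "III")
      mg <- clause(dat$muegge_violations >= 2, "muegge_violations",
                   dat$muegge_violations, ">= 2")
      sa <- clause(dat$sa_score < cfg$sa_step10, "sa_score", dat$sa_score,
                   paste0("< ", cfg$sa_step10))
      dl <- clause(dat$overall_druglikeness < cfg$druglikeness_step10,
                   "overall_druglikeness", dat$overall_druglikeness,
                   paste0("< ", cfg$druglikeness_step10))
      fired <- na_false(cr$value) & na_false(mg$value) &
        (na_false(sa$value) | na_false(dl$value))
      finalize(dat, fired, list(cr, mg, sa, dl),
               c("cramer_class", "sa_score", "overall_druglikeness"))
    }
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  s <- x$summary
  cat("Screening cascade result\n")
  cat("  compounds:", s$n_total, " retained:", s$n_retained,
      paste0("(", s$retention_pct, "%)\n"))
  steps <- x$records |> filter(.data$outcome == "eliminated") |>
    dplyr::count(.data$step)
  if (nrow(steps)) {
    cat("  eliminated per step:",
        paste(paste0("S", steps$step, ":", steps$n), collapse = " "), "\n")
  }
  invisible(x)
}

#' Tidy a cascade result
#'
#' One row per compound with its outcome, elimination step, and the
#' triggering clauses collapsed to a readable string; broom-style.
#'
#' @param x a `cascade_result`.
#' @param ... unused.
#' @return tibble.
#' @method tidy cascade_result
#' @export
tidy.cascade_result <- function(x, ...) {
  x$records |>
    mutate(clauses = vapply(.data$triggered, function(tr) {
      if (is.null(tr) || nrow(tr) == 0) return(NA_character_)
      paste0(tr$field, "=", tr$observed, " [", tr$bound, "]",
             collapse = "; ")
    }, character(1))) |>
    select("id", "outcome", "step", "clauses")
}

#' Summarise a cascade result
#'
#' @inheritParams tidy.cascade_result
#' @return one-row tibble: totals, retention percentage, per-step counts.
#' @method glance cascade_result
#' @export
glance.cascade_result <- function(x, ...) {
  x$summary
}

#' Plot cascade attrition by step
#'
#' @param object a `cascade_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cascade_result
#' @export
autoplot.cascade_result <- function(object, ...) {
  counts <- object$records |>
    filter(.data$outcome == "eliminated") |>
    dplyr::count(.data$step)
  ggplot2::ggplot(counts, ggplot2::aes(x = factor(.data$step), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "elimination step", y = "compounds eliminated",
                  title = "Cascade attrition by step") +
    ggplot2::theme_minimal()
}
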