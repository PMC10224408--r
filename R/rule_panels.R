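#' Drug-likeness rule bounds
#'
#' The criteria of the five rule panels, with the printed bounds:
#' Lipinski (MW <= 500, MlogP <= 4.15, N or O atoms <= 10, NH or OH <= 5),
#' Ghose (160 <= MW <= 480, -0.4 <= WlogP <= 5.6, 40 <= MR <= 130,
#' 20 <= atoms <= 70, all atoms counting hydrogens), Veber (RB <= 10,
#' TPSA <= 140), Egan (WlogP <= 5.88, TPSA <= 131.6) and Muegge
#' (200 <= MW <= 600, -2 <= XlogP <= 5, TPSA <= 150, rings <= 7,
#' carbons > 4, heteroatoms > 1, RB <= 15, HBA <= 10, HBD <= 5).
#' All comparisons are inclusive on the printed bound except the two Muegge
#' counts printed with a strict `>`.
#'
#' @param overrides named list replacing individual bounds; names are
#'   `"<rule>.<field>"` and values are `c(lower, upper)` with `-Inf`/`Inf`
#'   for open sides (e.g. `list(lipinski.mw = c(-Inf, 450))`).
#' @return tibble with columns `rule`, `field`, `lower`, `upper`,
#'   `lower_strict` (the strict-`>` Muegge counts).
#' @export
rule_bounds <- function(overrides = NULL) {
  b <- function(rule, field, lower, upper, lower_strict = FALSE) {
    tibble(rule = rule, field = field, lower = lower, upper = upper,
           lower_strict = lower_strict)
  }
  tab <- bind_rows(
    b("lipinski", "mw", -Inf, 500),
    b("lipinski", "mlogp", -Inf, 4.15),
    b("lipinski", "lipinski_no", -Inf, 10),
    b("lipinski", "lipinski_nhoh", -Inf, 5),
    b("ghose", "mw", 160, 480),
    b("ghose", "wlogp", -0.4, 5.6),
    b("ghose", "molar_refractivity", 40, 130),
    b("ghose", "total_atoms", 20, 70),
    b("veber", "rotatable_bonds", -Inf, 10),
    b("veber", "tpsa", -Inf, 140),
    b("egan", "wlogp", -Inf, 5.88),
    b("egan", "tpsa", -Inf, 131.6),
    b("muegge", "mw", 200, 600),
    b("muegge", "xlogp", -2, 5),
    b("muegge", "tpsa", -Inf, 150),
    b("muegge", "rings", -Inf, 7),
    b("muegge", "carbons", 4, Inf, lower_strict = TRUE),
    b("muegge", "heteroatoms", 1, Inf, lower_strict = TRUE),
    b("muegge", "rotatable_bonds", -Inf, 15),
    b("muegge", "hba", -Inf, 10),
    b("muegge", "hbd", -Inf, 5)
  )
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    hit <- tab$rule == parts[1] & tab$field == parts[2]
    if (!any(hit)) abort(paste0("unknown rule bound: ", key))
    tab$lower[hit] <- overrides[[key]][1]
    tab$upper[hit] <- overrides[[key]][2]
  }
  tab
}

#' Evaluate the drug-likeness rule panels
#'
#' Evaluates every criterion of every rule against a descriptor panel.
#' A criterion whose descriptor is `NA` is marked indeterminate (`pass = NA`)
#' with a warning, and is excluded from violation counts downstream.
#'
#' @param panels descriptor tibble from [compute_descriptors()].
#' @param bounds criterion table from [rule_bounds()].
#' @return Long tibble: `id`, `rule`, `field`, `observed`, `lower`, `upper`,
#'   `pass`. Deterministic row order (panel order, then rule table order).
#' @seealso [count_rule_violations()]
#' @export
evaluate_rules <- function(panels, bounds = rule_bounds()) {
  long <- tidyr::expand_grid(id = panels$id, bounds)
  long$observed <- as.numeric(mapply(function(id, field) {
    panels[[field]][match(id, panels$id)]
  }, long$id, long$field))
  long$pass <- ifelse(
    is.na(long$observed), NA,
    (ifelse(long$lower_strict, long$observed > long$lower,
            long$observed >= long$lower)) &
      long$observed <= long$upper
  )
  if (anyNA(long$pass)) {
    warn(paste0("indeterminate criteria for: ",
                paste(unique(long$id[is.na(long$pass)]), collapse = ", ")))
  }
  as_tibble(long[, c("id", "rule", "field", "observed", "lower", "upper",
                     "lower_strict", "pass")])
}

#' Per-rule violation counts
#'
#' @param rules long criterion tibble from [evaluate_rules()].
#' @return Wide tibble: `id` plus `<rule>_violations` columns. Indeterminate
#'   criteria are not counted either way.
#' @export
count_rule_violations <- function(rules) {
  rules |>
    group_by(.data$id, .data$rule) |>
    summarise(violations = sum(!.data$pass, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "rule", values_from = "violations",
                       names_glue = "{rule}_violations") |>
    select("id", "lipinski_violations", "ghose_violations",
           "veber_violations", "egan_violations", "muegge_violations")
}

#' CNS MPO desirability breakpoints
#'
#' Piecewise-linear desirability knots for the six-parameter CNS
#' multiparameter-optimization score. Monotone-decreasing ramps for ClogP
#' (3 to 5), ClogD (2 to 4), MW (360 to 500 Da), H-bond donors (0.5 to 3.5)
#' and the most basic pKa (8 to 10); a hump for TPSA (zero desirability at
#' or below 20 A^2, fully desirable between 40 and 90, zero at or above
#' 120). Swap in alternative knots to change the scheme.
#'
#' @return named list of two-column matrices (x, desirability).
#' @export
cns_mpo_breakpoints <- function() {
  ramp_down <- function(a, b) cbind(x = c(a, b), d = c(1, 0))
  list(
    clogp = ramp_down(3, 5),
    clogd = ramp_down(2, 4),
    mw = ramp_down(360, 500),
    tpsa = cbind(x = c(20, 40, 90, 120), d = c(0, 1, 1, 0)),
    hbd = ramp_down(0.5, 3.5),
    basic_pka = ramp_down(8, 10)
  )
}

#' CNS multiparameter-optimization score
#'
#' Sums six piecewise-linear desirabilities (each in \[0, 1\]) over ClogP,
#' ClogD, MW, TPSA, HBD and the most basic pKa; the total lies in \[0, 6\]
#' and the screening cascade's Step 2 uses the `>= 4` reading. A row with
#' any missing component has an indeterminate (`NA`) total.
#'
#' @param inputs tibble (or named list coerced to one) with columns `clogp`,
#'   `clogd`, `mw`, `tpsa`, `hbd`, `basic_pka`.
#' @param breakpoints desirability knots, see [cns_mpo_breakpoints()].
#' @return tibble with the six component desirabilities (`d_clogp`, ...)
#'   and `cns_mpo` total.
#' @examples
#' cns_mpo(tibble::tibble(clogp = 2, clogd = 1, mw = 300, tpsa = 70,
#'   hbd = 0, basic_pka = 7))  # total 6
#' @export
cns_mpo <- function(inputs, breakpoints = cns_mpo_breakpoints()) {
  inputs <- as_tibble(inputs)
  needed <- names(breakpoints)
  missing_cols <- setdiff(needed, names(inputs))
  if (length(missing_cols)) {
    abort(paste0("cns_mpo inputs lack: ", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(.rows = nrow(inputs))
  for (comp in needed) {
    k <- breakpoints[[comp]]
    v <- inputs[[comp]]
    out[[paste0("d_", comp)]] <- ifelse(
      is.na(v), NA_real_,
      stats::approx(k[, 1], k[, 2], xout = pmin(pmax(v, k[1, 1]), k[nrow(k), 1]),
                    rule = 2, ties = "ordered")$y
    )
  }
  out$cns_mpo <- rowSums(as.matrix(out))
  out
}

#' Interpret a bioactivity score
#'
#' A score above 0.0 marks a compound active for that target class, a score
#' between -0.5 and 0.0 (inclusive) moderately active, and below -0.5
#' inactive. Highlighting mirrors the reporting convention: one star above
#' 0.2, two stars above 0.5.
#'
#' @param score numeric vector of bioactivity scores.
#' @return tibble with `score`, `category` (active/moderate/inactive) and
#'   `highlight` (none/star/double_star).
#' @examples
#' interpret_bioactivity(c(0.87, 0, -0.6))
#' @export
interpret_bioactivity <- function(score) {
  stopifnot(is.numeric(score), all(is.finite(score)))
  tibble(
    score = score,
    category = dplyr::case_when(
      score > 0 ~ "active",
      score >= -0.5 ~ "moderate",
      TRUE ~ "inactive"
    ),
    highlight = dplyr::case_when(
      score > 0.5 ~ "double_star",
      score > 0.2 ~ "star",
      TRUE ~ "none"
    )
  )
}
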