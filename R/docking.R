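#' Physical constants for the inhibition-constant formula
#'
#' Defaults as conventionally printed for docking post-processing: the gas
#' constant R = 1.98719 cal/(mol K), T = 298.15 K, and the exponential base
#' truncated to 2.7182. Set `e_base = exp(1)` for the exact base; for
#' binding free energies up to 20 kcal/mol in magnitude the two differ by
#' well under 0.1%.
#'
#' @param R gas constant, cal/(mol K).
#' @param T_k absolute temperature, K.
#' @param e_base exponential base.
#' @return named list of constants.
#' @export
dock_constants <- function(R = 1.98719, T_k = 298.15, e_base = 2.7182) {
  list(R = R, T_k = T_k, e_base = e_base)
}

#' Inhibition constant from binding free energy
#'
#' `Ki = base^((dg * 1000) / (R * T))` with `dg` in kcal/mol (the factor
#' 1000 converts to cal/mol). Strictly increasing in `dg`; `dg = 0` gives 1.
#' The formula yields a dimensionless number, conventionally read as a molar
#' concentration.
#'
#' @param dg binding free energy, kcal/mol (negative for favourable binding).
#' @param constants see [dock_constants()].
#' @return numeric vector of Ki values.
#' @examples
#' ki_from_dg(-8.1)  # about 1.155e-06
#' @export
ki_from_dg <- function(dg, constants = dock_constants()) {
  stopifnot(is.numeric(dg), all(is.finite(dg)))
  constants$e_base^((dg * 1000) / (constants$R * constants$T_k))
}

#' FullFitness of a docking cluster
#'
#' The mean of the most favourable 30% of the cluster's element energies
#' (each element energy being the system's total energy plus a solvation
#' term). The element count is `k = max(1, round_half_up(fraction * N))`,
#' so singleton clusters return their only energy; the result is invariant
#' to input order and translation-equivariant.
#'
#' @param energies numeric vector of element energies, kcal/mol.
#' @param fraction fraction of most favourable (lowest) energies averaged.
#' @return mean of the `k` lowest energies.
#' @examples
#' fullfitness(seq(-10, -1))  # mean of -10, -9, -8
#' @export
fullfitness <- function(energies, fraction = 0.30) {
  if (length(energies) == 0) abort("empty energy list")
  stopifnot(is.numeric(energies), all(is.finite(energies)),
            fraction > 0, fraction <= 1)
  k <- max(1L, as.integer(round_half_up(fraction * length(energies))))
  mean(sort(energies)[seq_len(k)])
}

#' Read a docking cluster table
#'
#' Long-format CSV: one row per cluster element with columns `cluster`,
#' `element`, `energy` and (repeated per cluster, or on any one row)
#' `dg`. Computes per-cluster FullFitness and Ki.
#'
#' @param path CSV path.
#' @param constants Ki constants, see [dock_constants()].
#' @param fraction FullFitness fraction.
#' @return tibble: `cluster`, `n_elements`, `dg`, `fullfitness`, `ki`.
#' @export
read_cluster_table <- function(path, constants = dock_constants(),
                               fraction = 0.30) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("cluster", "element", "energy", "dg")
  if (!all(needed %in% names(df))) {
    abort(paste0("cluster table needs columns: ",
                 paste(needed, collapse = ", ")))
  }
  df |>
    group_by(.data$cluster) |>
    summarise(
      n_elements = dplyr::n(),
      dg = .data$dg[!is.na(.data$dg)][1],
      fullfitness = fullfitness(.data$energy, fraction),
      .groups = "drop"
    ) |>
    mutate(ki = ki_from_dg(.data$dg, constants))
}

#' Select the most probable binding site
#'
#' The cluster with the lowest binding free energy; ties break to the
#' lowest cluster id, with a message logging the tie.
#'
#' @param clusters tibble with `cluster` and `dg` columns
#'   (e.g. from [read_cluster_table()]).
#' @return the winning cluster id.
#' @examples
#' select_binding_site(tibble::tibble(cluster = c(1, 6, 33),
#'   dg = c(-8.1, -7.6, -6.8)))  # 1
#' @export
select_binding_site <- function(clusters) {
  stopifnot(all(c("cluster", "dg") %in% names(clusters)))
  if (nrow(clusters) == 0) abort("no clusters")
  best <- clusters$cluster[clusters$dg == min(clusters$dg)]
  if (length(best) > 1) {
    inform(paste0("dg tie between clusters ",
                  paste(best, collapse = ", "), "; picking lowest id"))
  }
  min(best)
}
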