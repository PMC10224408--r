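#' Acute-toxicity band tables
#'
#' Category bands for rat LD50 values (mg/kg). The default oral table uses
#' the GHS/OECD acute oral bands with inclusive upper bounds: Class 1 up to
#' 5, Class 2 up to 50, Class 3 up to 300, Class 4 up to 2000, Class 5 up to
#' 5000, and Non-Toxic above. Band tables for the intraperitoneal,
#' intravenous and subcutaneous routes follow a route-specific scheme that
#' is not part of the default configuration; classification for those routes
#' needs a user-supplied table (see [classify_ld50()]).
#'
#' @param route one of `"oral"`, `"ip"`, `"iv"`, `"sc"`.
#' @return tibble with `label` and `upper` (mg/kg, inclusive), ordered by
#'   increasing bound, the final row `Inf`; or `NULL` when no default table
#'   exists for the route.
#' @export
tox_band_table <- function(route = c("oral", "ip", "iv", "sc")) {
  route <- match.arg(route)
  if (route != "oral") return(NULL)
  tibble(
    label = c(paste("Class", 1:5), "Non-Toxic"),
    upper = c(5, 50, 300, 2000, 5000, Inf)
  )
}

#' Read a band table from YAML
#'
#' The YAML holds a list of `label:` / `upper:` pairs in increasing bound
#' order; the final band may omit `upper` (read as unbounded).
#'
#' @param path YAML file path.
#' @return band tibble as in [tox_band_table()].
#' @export
read_band_table <- function(path) {
  raw <- yaml::read_yaml(path)
  tab <- tibble(
    label = vapply(raw, function(x) as.character(x$label), character(1)),
    upper = vapply(raw, function(x) {
      if (is.null(x$upper)) Inf else as.numeric(x$upper)
    }, numeric(1))
  )
  validate_band_table(tab)
  tab
}

validate_band_table <- function(table) {
  if (is.unsorted(table$upper, strictly = TRUE)) {
    abort("band upper bounds must be strictly increasing")
  }
  if (anyDuplicated(table$label)) abort("band labels must be unique")
  invisible(table)
}

#' Classify an LD50 into an acute-toxicity category
#'
#' Assigns the label of the first band whose (inclusive) upper bound is at
#' least the LD50 -- a monotone step function of dose. The
#' applicability-domain flag, when given, is appended to the label verbatim
#' and never alters the class. Routes without a default table return
#' `"Unclassified"` with a warning unless a table is supplied.
#'
#' @param ld50 positive LD50 values, mg/kg.
#' @param route administration route (used to pick the default table).
#' @param table band tibble; default [tox_band_table()] for the route.
#' @param in_ad optional logical vector; appends `"in AD"` / `"out of AD"`.
#' @return character vector of class labels.
#' @examples
#' classify_ld50(c(1978, 4228, 5859), "oral")
#' @export
classify_ld50 <- function(ld50, route = "oral", table = NULL, in_ad = NULL) {
  stopifnot(is.numeric(ld50))
  if (any(!is.finite(ld50) | ld50 <= 0)) {
    abort("ld50 values must be positive")
  }
  if (is.null(table)) table <- tox_band_table(route)
  if (is.null(table)) {
    warn(paste0("no default band table for route '", route,
                "'; supply one via `table`"))
    lab <- rep("Unclassified", length(ld50))
  } else {
    validate_band_table(table)
    lab <- vapply(ld50, function(x) {
      table$label[which(x <= table$upper)[1]]
    }, character(1))
  }
  if (!is.null(in_ad)) {
    lab <- paste(lab, ifelse(in_ad, "in AD", "out of AD"))
  }
  lab
}

#' Score candidate sites of metabolism
#'
#' Ranks atoms by the cytochrome-P450 site-of-metabolism score
#' `score = E - 8 * A - 0.04 * SASA`, where `E` is the activation-energy
#' reactivity descriptor, `A` the relative topological distance of the atom
#' from the molecular centre (accessibility), and `SASA` the
#' solvent-accessible surface area in square Angstroms. Lower scores mean a
#' higher probability of being the site of metabolism; the rank-1 atom is
#' flagged as most reactive.
#'
#' @param atoms tibble with columns `atom` (identifier), `e`, `a`, `sasa`.
#' @return the input ranked by ascending score, with `score`, `rank` and
#'   `most_reactive` columns.
#' @examples
#' score_metabolism_sites(tibble::tibble(atom = c("C1", "C2"),
#'   e = c(50, 50), a = c(0, 1), sasa = c(100, 100)))
#' @export
score_metabolism_sites <- function(atoms) {
  atoms <- as_tibble(atoms)
  needed <- c("atom", "e", "a", "sasa")
  if (!all(needed %in% names(atoms))) {
    abort(paste0("atoms table needs columns: ",
                 paste(needed, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("empty atom list")
  vals <- atoms[, c("e", "a", "sasa")]
  if (!all(vapply(vals, is.numeric, logical(1))) ||
      !all(is.finite(as.matrix(vals)))) {
    abort("e, a and sasa must be finite numerics")
  }
  atoms |>
    mutate(score = .data$e - 8 * .data$a - 0.04 * .data$sasa) |>
    arrange(.data$score) |>
    mutate(rank = row_number(), most_reactive = row_number() == 1L)
}
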