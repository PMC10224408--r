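#' Read a compound library
#'
#' Reads a `.smi` file (one record per line: SMILES, whitespace, identifier)
#' or an SDF (V2000) into a compound table. Every structure is checked with
#' the OpenBabel SMILES/SDF parser at load; record order is preserved and
#' duplicate identifiers are rejected.
#'
#' @param path file path.
#' @param format `"smi"` or `"sdf"`; default guessed from the extension.
#' @return A tibble with columns `id`, `smiles`, `name` (`NA` when the format
#'   carries none).
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("CCO e1", "c1ccccc1 e2"), f)
#' read_library(f)
#' @export
read_library <- function(path, format = c("auto", "smi", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "leadsieve_io_error")
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smi"
  }
  if (format == "sdf") return(read_library_sdf(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    warn(paste0("empty compound library: ", path))
    return(tibble(id = character(), smiles = character(), name = character()))
  }
  lineno <- which(keep)
  recs <- trimws(lines[keep])
  smiles <- sub("[ \t].*$", "", recs)
  rest <- trimws(sub("^[^ \t]+", "", recs))
  id <- sub("[ \t].*$", "", rest)
  name <- trimws(sub("^[^ \t]*", "", rest))
  id[!nzchar(id)] <- paste0("mol", seq_len(sum(!nzchar(id))))
  ok <- ob_valid_smiles(smiles)
  if (!all(ok)) {
    abort(paste0(
      "unparseable SMILES at line ", lineno[which(!ok)[1]], ": ",
      smiles[which(!ok)[1]]
    ), class = "leadsieve_load_error")
  }
  if (anyDuplicated(id)) {
    abort(paste0("duplicate compound id: ", id[duplicated(id)][1]),
          class = "leadsieve_load_error")
  }
  tibble(id = id, smiles = smiles,
         name = ifelse(nzchar(name), name, NA_character_))
}

read_library_sdf <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  smiles <- unname(as.character(suppressWarnings(ChemmineR::sdf2smiles(sdf))))
  id <- ChemmineR::sdfid(sdf)
  if (anyDuplicated(id)) {
    abort(paste0("duplicate compound id: ", id[duplicated(id)][1]),
          class = "leadsieve_load_error")
  }
  ok <- ob_valid_smiles(smiles)
  if (!all(ok)) {
    abort(paste0("unparseable structure in SDF record ", which(!ok)[1]),
          class = "leadsieve_load_error")
  }
  tibble(id = id, smiles = smiles, name = NA_character_)
}

#' Write a compound library to a .smi file
#'
#' @param compounds tibble with `id` and `smiles` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(compounds, path) {
  stopifnot(all(c("id", "smiles") %in% names(compounds)))
  writeLines(paste(compounds$smiles, compounds$id), path)
  invisible(path)
}

annotation_header <- "# leadsieve-annotations v1"

#' Annotation table schema
#'
#' The per-compound annotation CSV carries server-derived predictions the
#' screening cascade consumes: structural toxicity class (Cramer I/II/III),
#' eight named toxicity alert flags, qualitative aqueous solubility,
#' gastrointestinal absorption, blood-brain-barrier/P-gp/CYP interactions,
#' drug-likeness and synthetic-accessibility scores, six bioactivity scores,
#' per-route acute-toxicity LD50s with applicability-domain flags, and the
#' lipophilicity/pKa inputs of the CNS MPO score. The first line of the file
#' must be the versioned header comment `# leadsieve-annotations v1`; extra
#' columns are permitted and preserved.
#'
#' @return A tibble describing the frozen schema: `column`, `type`, `levels`
#'   (comma-separated for enums, `NA` otherwise).
#' @export
annotation_schema <- function() {
  flag_cols <- c(
    "mutagenicity", "genotoxic_carcinogenicity",
    "nongenotoxic_carcinogenicity", "tumorigenesis", "irritation_corrosion",
    "reproductive_effect", "dna_binding_alert", "protein_binding_alert"
  )
  bioact_cols <- paste0("bioactivity_", c(
    "gpcr_ligand", "ion_channel_modulator", "kinase_inhibitor",
    "nuclear_receptor_ligand", "protease_inhibitor", "enzyme_inhibitor"
  ))
  cyp_cols <- paste0("cyp", c("1a2", "2c19", "2c9", "2d6", "3a4"), "_inhibition")
  ld50_cols <- paste0("ld50_", c("ip", "iv", "oral", "sc"))
  ad_cols <- paste0(ld50_cols, "_in_ad")
  bind_rows(
    tibble(column = "id", type = "character", levels = NA_character_),
    tibble(column = "cramer_class", type = "enum", levels = "I,II,III"),
    tibble(column = flag_cols, type = "logical", levels = NA_character_),
    tibble(column = "solubility_class", type = "enum",
           levels = "highly,soluble,moderately,poorly,insoluble"),
    tibble(column = "gi_absorption", type = "enum", levels = "high,low"),
    tibble(column = c("bbb_permeant", "pgp_interaction"), type = "logical",
           levels = NA_character_),
    tibble(column = cyp_cols, type = "logical", levels = NA_character_),
    tibble(column = c("overall_druglikeness", "sa_score",
                      "bioavailability_score"),
           type = "numeric", levels = NA_character_),
    tibble(column = "lead_likeness_pass", type = "logical",
           levels = NA_character_),
    tibble(column = bioact_cols, type = "numeric", levels = NA_character_),
    tibble(column = ld50_cols, type = "numeric", levels = NA_character_),
    tibble(column = ad_cols, type = "logical", levels = NA_character_),
    tibble(column = c("clogp", "clogd", "basic_pka"), type = "numeric",
           levels = NA_character_)
  )
}

parse_flag <- function(x, column) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[v %in% c("0", "false", "f", "no", "n")] <- FALSE
  bad <- which(!is.na(v) & nzchar(v) & is.na(out))
  if (length(bad)) {
    abort(paste0("row ", bad[1], ", column '", column,
                 "': cannot read '", x[bad[1]], "' as a flag"),
          class = "leadsieve_load_error")
  }
  out
}

#' Read a per-compound annotation table
#'
#' Reads and validates the annotation CSV (schema: [annotation_schema()]).
#' Enumerated columns are validated against their levels; missing optional
#' columns are carried as absent (`NA`) rather than silently defaulted.
#' If a compound table is supplied, annotation rows whose `id` has no
#' library match produce a warning but are retained.
#'
#' @param path CSV path; the first line must be the versioned schema header.
#' @param compounds optional compound tibble used to cross-check ids.
#' @return tibble of annotations, one row per compound id.
#' @export
read_annotations <- function(path, compounds = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "leadsieve_io_error")
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!identical(sub("\r$", "", trimws(first)), annotation_header)) {
    abort(paste0("missing annotation schema header '", annotation_header,
                 "' in ", path), class = "leadsieve_load_error")
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!"id" %in% names(df)) {
    abort("annotation table lacks an 'id' column",
          class = "leadsieve_load_error")
  }
  if (anyDuplicated(df$id)) {
    abort(paste0("duplicate annotation id: ", df$id[duplicated(df$id)][1]),
          class = "leadsieve_load_error")
  }
  schema <- annotation_schema()
  out <- tibble(id = df$id)
  for (k in seq_len(nrow(schema))[-1]) {
    colname <- schema$column[k]
    if (!colname %in% names(df)) {
      out[[colname]] <- if (schema$type[k] == "logical") NA else
        if (schema$type[k] == "numeric") NA_real_ else NA_character_
      next
    }
    raw <- df[[colname]]
    out[[colname]] <- switch(
      schema$type[k],
      enum = {
        lv <- strsplit(schema$levels[k], ",")[[1]]
        bad <- which(!is.na(raw) & !raw %in% lv)
        if (length(bad)) {
          abort(paste0("row ", bad[1], ", column '", colname, "': '",
                       raw[bad[1]], "' is not one of ",
                       paste(lv, collapse = "/")),
                class = "leadsieve_load_error")
        }
        raw
      },
      logical = parse_flag(raw, colname),
      numeric = {
        v <- suppressWarnings(as.numeric(raw))
        bad <- which(!is.na(raw) & is.na(v))
        if (length(bad)) {
          abort(paste0("row ", bad[1], ", column '", colname,
                       "': '", raw[bad[1]], "' is not numeric"),
                class = "leadsieve_load_error")
        }
        v
      }
    )
  }
  extra <- setdiff(names(df), schema$column)
  for (colname in extra) out[[colname]] <- df[[colname]]
  validate_annotations(out)
  if (!is.null(compounds)) {
    orphans <- setdiff(out$id, compounds$id)
    if (length(orphans)) {
      warn(paste0("annotation ids with no library match: ",
                  paste(head(orphans, 5), collapse = ", "),
                  if (length(orphans) > 5) ", ..."))
    }
  }
  out
}

validate_annotations <- function(ann) {
  if (any(!is.na(ann$sa_score) & (ann$sa_score < 1 | ann$sa_score > 10))) {
    abort("sa_score outside [1, 10]", class = "leadsieve_load_error")
  }
  for (route in c("ip", "iv", "oral", "sc")) {
    v <- ann[[paste0("ld50_", route)]]
    if (any(!is.na(v) & v <= 0)) {
      abort(paste0("non-positive ld50_", route),
            class = "leadsieve_load_error")
    }
  }
  invisible(ann)
}

#' Write an annotation table with its versioned header
#'
#' @param annotations tibble in the [annotation_schema()] layout.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(annotation_header, con)
  ann <- dplyr::mutate(annotations, across(
    dplyr::where(is.logical), ~ as.integer(.x)
  ))
  utils::write.table(ann, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
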