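#' Retention percentage
#'
#' Percentage of library members surviving the cascade, rounded half-up to
#' one decimal (9 of 123 reports as 7.3).
#'
#' @param n_total library size (> 0).
#' @param n_retained surviving count, `0 <= n_retained <= n_total`.
#' @return numeric percentage with one decimal.
#' @examples
#' retention_percentage(123, 9)  # 7.3
#' @export
retention_percentage <- function(n_total, n_retained) {
  if (!is.numeric(n_total) || n_total <= 0) {
    abort("n_total must be positive")
  }
  if (n_retained < 0 || n_retained > n_total) {
    abort("n_retained must lie in [0, n_total]")
  }
  round_half_up(100 * n_retained / n_total, 1)
}

#' Screening summary table
#'
#' @param records elimination record tibble (`id`, `outcome`, `step`).
#' @return one-row tibble: `n_total`, `n_retained`, `retention_pct`, and one
#'   `step<k>_eliminated` column per step that eliminated at least one
#'   compound.
#' @export
screening_summary <- function(records) {
  n_total <- nrow(records)
  n_ret <- sum(records$outcome == "retained")
  out <- tibble(
    n_total = n_total, n_retained = n_ret,
    retention_pct = if (n_total > 0) retention_percentage(n_total, n_ret)
      else NA_real_
  )
  if (n_total > 0) {
    steps <- records |> filter(.data$outcome == "eliminated") |>
      dplyr::count(.data$step) |> arrange(.data$step)
    for (i in seq_len(nrow(steps))) {
      out[[paste0("step", steps$step[i], "_eliminated")]] <- steps$n[i]
    }
  }
  out
}

#' Lead table for retained compounds
#'
#' Per-survivor digest of rule violations and key annotation scores, in the
#' style of a per-compound results table.
#'
#' @param result a `cascade_result`.
#' @return tibble with one row per retained compound.
#' @export
lead_table <- function(result) {
  stopifnot(inherits(result, "cascade_result"))
  keep <- result$records$id[result$records$outcome == "retained"]
  cols <- intersect(
    c("id", "smiles", "mw", "tpsa", "wlogp", "mlogp",
      "lipinski_violations", "ghose_violations", "veber_violations",
      "egan_violations", "muegge_violations", "cramer_class", "sa_score",
      "overall_druglikeness", "gi_absorption"),
    names(result$data)
  )
  result$data |> filter(.data$id %in% keep) |> select(all_of(cols))
}

#' Emit a screening report
#'
#' Writes the elimination records and summary in a deterministic layout.
#' CSV holds the per-compound records; JSON carries a versioned object with
#' summary, records and lead table; Markdown renders per-compound rows with
#' per-rule columns plus a human-readable audit log (one line per compound:
#' id, outcome, step, clauses).
#'
#' @param result a `cascade_result`.
#' @param path output file path.
#' @param format `"csv"`, `"json"` or `"md"`; default from the extension.
#' @return `path`, invisibly.
#' @export
emit_report <- function(result, path, format = c("auto", "csv", "json", "md")) {
  stopifnot(inherits(result, "cascade_result"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", json = "json", md = "md", markdown = "md",
                     abort(paste0("cannot infer report format from: ", path)))
  }
  rec <- tidy.cascade_result(result)
  ok <- tryCatch({
    switch(format,
      csv = readr::write_csv(rec, path, na = ""),
      json = jsonlite::write_json(
        list(schema = "leadsieve-report/1",
             summary = result$summary,
             records = rec,
             leads = lead_table(result)),
        path, dataframe = "rows", na = "null", auto_unbox = TRUE,
        digits = NA, pretty = TRUE
      ),
      md = writeLines(report_markdown(result), path)
    )
    TRUE
  }, error = function(e) {
    abort(paste0("failed writing report to ", path, ": ",
                 conditionMessage(e)), class = "leadsieve_io_error")
  })
  invisible(path)
}

report_markdown <- function(result) {
  s <- result$summary
  rec <- tidy.cascade_result(result)
  leads <- lead_table(result)
  md_table <- function(df) {
    df <- dplyr::mutate(df, across(dplyr::everything(), as.character))
    df[is.na(df)] <- ""
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      vapply(seq_len(nrow(df)), function(i) {
        paste0("| ", paste(unlist(df[i, ]), collapse = " | "), " |")
      }, character(1)))
  }
  c(
    "# Screening report",
    "",
    paste0("Compounds: ", s$n_total, "; retained: ", s$n_retained,
           " (", s$retention_pct, "%)"),
    "",
    "## Lead table",
    "",
    md_table(leads),
    "",
    "## Audit log",
    "",
    vapply(seq_len(nrow(rec)), function(i) {
      paste0("- ", rec$id[i], ": ", rec$outcome[i],
             if (!is.na(rec$step[i])) paste0(" at step ", rec$step[i]),
             if (!is.na(rec$clauses[i])) paste0(" (", rec$clauses[i], ")"))
    }, character(1))
  )
}

#' Re-read a JSON screening report
#'
#' Round-trip counterpart of [emit_report()]'s JSON writer: reconstructs the
#' summary and records tables exactly.
#'
#' @param path JSON report path.
#' @return list with `summary`, `records` and `leads` tibbles.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "leadsieve_io_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$schema, "leadsieve-report/1")) {
    abort("not a leadsieve JSON report", class = "leadsieve_load_error")
  }
  rec <- as_tibble(raw$records)
  if (!"step" %in% names(rec)) rec$step <- NA_integer_
  rec$step <- as.integer(rec$step)
  if (!"clauses" %in% names(rec)) rec$clauses <- NA_character_
  list(summary = as_tibble(raw$summary), records = rec,
       leads = as_tibble(raw$leads))
}
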