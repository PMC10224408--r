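#' Parse compound library ID codes
#'
#' Library members carry a compact taxonomy code: a class digit (1-5), an
#' uppercase group letter, a lowercase subgroup letter, the compound's number
#' within the subgroup, and optionally a derivative suffix -- either a single
#' trailing lowercase letter or a dotted token such as `".1"` or `".m"`
#' (e.g. `"4Db6"`, `"4Da11"`, `"4Dd4.m"`).
#'
#' @param x character vector of ID codes.
#' @param allow_nonstandard if `TRUE`, codes that do not follow the grammar
#'   are kept as opaque identifiers and flagged in the `nonstandard` column
#'   instead of raising an error, so non-taxonomy libraries stay usable.
#' @return A tibble with one row per input: `id`, `class_digit`,
#'   `group_letter`, `subgroup_letter`, `number`, `suffix` (`NA` when absent)
#'   and `nonstandard`. Taxonomy columns are `NA` for nonstandard ids.
#' @examples
#' parse_id_code(c("4Db6", "4Dd4.m"))
#' format_id_code(parse_id_code("4Da11"))
#' @seealso [format_id_code()]
#' @export
parse_id_code <- function(x, allow_nonstandard = FALSE) {
  stopifnot(is.character(x), all(nzchar(x)))
  rx <- "^([0-9])([A-Za-z])([A-Za-z])([0-9]+)([a-z]|\\.[a-z0-9]+)?$"
  m <- regmatches(x, regexec(rx, x))
  out <- tibble(
    id = x,
    class_digit = NA_integer_, group_letter = NA_character_,
    subgroup_letter = NA_character_, number = NA_integer_,
    suffix = NA_character_, nonstandard = FALSE
  )
  for (i in seq_along(x)) {
    g <- m[[i]]
    bad <- NULL
    if (length(g) == 0) {
      bad <- if (!grepl("^[0-9]", x[i])) {
        "expected a leading class digit"
      } else {
        "does not match <digit><Group><subgroup><number>[suffix]"
      }
    } else {
      if (!g[2] %in% as.character(1:5)) {
        bad <- paste0("class digit '", g[2], "' outside 1-5")
      } else if (!grepl("^[A-Z]$", g[3])) {
        bad <- paste0("group letter '", g[3], "' must be uppercase")
      } else if (!grepl("^[a-z]$", g[4])) {
        bad <- paste0("subgroup letter '", g[4], "' must be lowercase")
      }
    }
    if (!is.null(bad)) {
      if (!allow_nonstandard) {
        abort(paste0("malformed ID code '", x[i], "': ", bad),
              class = "leadsieve_parse_error")
      }
      out$nonstandard[i] <- TRUE
      next
    }
    out$class_digit[i] <- as.integer(g[2])
    out$group_letter[i] <- g[3]
    out$subgroup_letter[i] <- g[4]
    out$number[i] <- as.integer(g[5])
    out$suffix[i] <- if (nzchar(g[6])) g[6] else NA_character_
  }
  out
}

#' Format parsed ID codes back to strings
#'
#' Inverse of [parse_id_code()]: formatting a parsed code reproduces the
#' input string exactly (nonstandard ids pass through unchanged).
#'
#' @param parsed a tibble as returned by [parse_id_code()].
#' @return character vector of ID codes.
#' @export
format_id_code <- function(parsed) {
  ifelse(
    parsed$nonstandard,
    parsed$id,
    paste0(
      parsed$class_digit, parsed$group_letter, parsed$subgroup_letter,
      parsed$number,
      ifelse(is.na(parsed$suffix), "", parsed$suffix)
    )
  )
}
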