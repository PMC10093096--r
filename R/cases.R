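RESULT_LEVELS <- c("+", "-", "nd")

# Map free-form result spellings onto the canonical {+, -, nd}. Anything
# else is left untouched so filter_cases() can flag it as inconclusive
# rather than silently dropping it.
normalize_result <- function(x) {
  key <- tolower(stringr::str_squish(as.character(x)))
  out <- as.character(x)
  out[key %in% c("+", "pos", "positive", "p")] <- "+"
  out[key %in% c("-", "neg", "negative", "n", "−")] <- "-"
  out[key %in% c("nd", "not_done", "notdone", "na", "not done")] <- "nd"
  out
}

#' Coerce a data frame of IHC results into the canonical case format
#'
#' Cases are held in long form: one row per (case, marker) with columns
#' `case_id`, `marker`, `result` and optionally `original_diagnosis` and
#' `site`. Results are normalised to `"+"`, `"-"` or `"nd"` (not done);
#' unrecognised values are kept verbatim (they mark a result as
#' inconclusive downstream). Duplicate markers within one case are
#' rejected.
#'
#' @param x A data frame with at least `case_id`, `marker`, `result`.
#' @return A tibble with the five canonical columns.
#' @export
as_cases <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("case_id", "marker", "result")
  if (!all(need %in% names(x))) {
    rlang::abort(paste0("cases need columns ", paste(need, collapse = ", ")))
  }
  if (!"original_diagnosis" %in% names(x)) {
    x$original_diagnosis <- NA_character_
  }
  if (!"site" %in% names(x)) x$site <- NA_character_
  x$case_id <- as.character(x$case_id)
  x$marker <- stringr::str_squish(x$marker)
  x$result <- normalize_result(x$result)
  dup <- duplicated(paste(x$case_id, canonical_key(x$marker), sep = "\r"))
  if (any(dup)) {
    rlang::abort(paste0(
      "duplicate marker within case(s): ",
      paste(unique(x$case_id[dup]), collapse = ", ")
    ))
  }
  x[, c("case_id", "marker", "result", "original_diagnosis", "site")]
}

#' Read case profiles from CSV or JSON
#'
#' CSV: header `case_id,marker,result[,original_diagnosis,site]`, results
#' in `{+, -, nd}`. JSON: an array of objects
#' `{case_id, site, original_diagnosis, results: {marker: "+"|"-"}}`.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A long tibble of cases (see [as_cases()]).
#' @export
read_cases <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("case file not found: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
    as_cases(x)
  } else if (ext == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rows <- lapply(raw, function(cs) {
      tibble::tibble(
        case_id = as.character(cs$case_id),
        marker = names(cs$results),
        result = unlist(cs$results, use.names = FALSE),
        original_diagnosis = cs$original_diagnosis %||% NA_character_,
        site = cs$site %||% NA_character_
      )
    })
    as_cases(dplyr::bind_rows(rows))
  } else {
    rlang::abort(paste0("unsupported case format: .", ext))
  }
}

#' Write case profiles to CSV
#'
#' @param cases A long tibble of cases.
#' @param path Destination `.csv` path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  readr::write_csv(as_cases(cases), path)
  invisible(path)
}

# Split a long case tibble into a named list of per-case tibbles,
# preserving first-appearance order.
split_cases <- function(cases) {
  split(cases, factor(cases$case_id, levels = unique(cases$case_id)))
}
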