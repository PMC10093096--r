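#' Read a knowledge base from JSON or CSV
#'
#' Two formats are supported, chosen by file extension:
#'
#' * **JSON** (the serialisation default): a nested object
#'   `{grade_table, markers: [{name, role}], diseases: [{name, lineage,
#'   site_class, expression: {marker: grade}}], aliases: {alt: canonical}}`.
#' * **CSV** (long authoring format): header
#'   `disease,lineage,site_class,marker,grade`, one row per
#'   (disease, marker). The marker registry is derived (all diagnostic)
#'   and the default grade table is used.
#'
#' @param path Path to a `.json` or `.csv` file.
#' @return An `ihc_kb`; malformed files raise an error naming the
#'   offending record.
#' @seealso [write_kb()]
#' @export
read_kb <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("knowledge base file not found: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = read_kb_json(path),
    csv = read_kb_csv(path),
    rlang::abort(paste0("unsupported knowledge base format: .", ext,
                        " (expected .json or .csv)"))
  )
}

read_kb_json <- function(path) {
  x <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      rlang::abort(paste0("malformed JSON in ", path, ": ",
                          conditionMessage(e)))
    }
  )

  grades <- if (!is.null(x$grade_table)) {
    dplyr::bind_rows(lapply(x$grade_table, function(g) {
      tibble::tibble(
        label = g$label, lo = as.numeric(g$lo), hi = as.numeric(g$hi),
        frequency = as.numeric(g$frequency)
      )
    }))
  } else {
    grade_table()
  }

  markers <- if (length(x$markers)) {
    dplyr::bind_rows(lapply(x$markers, function(m) {
      tibble::tibble(name = m$name, role = m$role %||% "diagnostic")
    }))
  } else {
    NULL
  }

  dis_rows <- lapply(x$diseases, function(d) {
    tibble::tibble(
      name = d$name,
      lineage = d$lineage,
      site_class = d$site_class %||% NA_character_
    )
  })
  diseases <- if (length(dis_rows)) dplyr::bind_rows(dis_rows) else NULL

  expr_rows <- lapply(x$diseases, function(d) {
    ex <- d$expression
    if (!length(ex)) return(NULL)
    tibble::tibble(
      disease = d$name,
      marker = names(ex),
      grade = unlist(ex, use.names = FALSE)
    )
  })
  expression <- dplyr::bind_rows(expr_rows)

  aliases <- if (length(x$aliases)) {
    tibble::tibble(
      alias = names(x$aliases),
      canonical = unlist(x$aliases, use.names = FALSE)
    )
  } else {
    NULL
  }

  new_kb(
    diseases = diseases %||% tibble::tibble(name = character(),
                                            lineage = character()),
    expression = expression,
    markers = markers,
    aliases = aliases,
    grades = grades
  )
}

read_kb_csv <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("disease", "lineage", "site_class", "marker", "grade")
  if (!all(need %in% names(x))) {
    rlang::abort(paste0(
      "knowledge base CSV must have columns ",
      paste(need, collapse = ","), "; found ",
      paste(names(x), collapse = ",")
    ))
  }
  diseases <- dplyr::distinct(
    x, .data$disease, .data$lineage, .data$site_class
  )
  if (anyDuplicated(canonical_key(diseases$disease))) {
    rlang::abort("inconsistent lineage/site_class rows for one disease")
  }
  new_kb(
    diseases = dplyr::rename(diseases, name = "disease"),
    expression = x[, c("disease", "marker", "grade")]
  )
}

#' Write a knowledge base to JSON or CSV
#'
#' Writing then reading back reproduces the knowledge base field-for-field
#' (for CSV that holds when the KB uses the default grade table, has no
#' aliases, only diagnostic markers, and every disease and registry marker
#' appears in at least one expression row, since the long format carries
#' no separate registry).
#'
#' @param kb An `ihc_kb`.
#' @param path Destination ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  validate_kb(kb)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    write_kb_json(kb, path)
  } else if (ext == "csv") {
    write_kb_csv(kb, path)
  } else {
    rlang::abort(paste0("unsupported knowledge base format: .", ext))
  }
  invisible(path)
}

write_kb_json <- function(kb, path) {
  ekey <- canonical_key(kb$expression$disease)
  diseases <- lapply(seq_len(nrow(kb$diseases)), function(i) {
    d <- kb$diseases[i, ]
    rows <- kb$expression[ekey == canonical_key(d$name), ]
    ex <- stats::setNames(as.list(rows$grade), rows$marker)
    list(
      name = d$name,
      lineage = d$lineage,
      site_class = if (is.na(d$site_class)) NULL else d$site_class,
      expression = ex
    )
  })
  out <- list(
    grade_table = lapply(seq_len(nrow(kb$grades)), function(i) {
      as.list(kb$grades[i, ])
    }),
    markers = lapply(seq_len(nrow(kb$markers)), function(i) {
      as.list(kb$markers[i, ])
    }),
    diseases = diseases,
    aliases = stats::setNames(as.list(kb$aliases$canonical), kb$aliases$alias)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
}

write_kb_csv <- function(kb, path) {
  x <- dplyr::left_join(
    kb$expression,
    dplyr::rename(kb$diseases, disease = "name"),
    by = "disease"
  )
  readr::write_csv(
    x[, c("disease", "lineage", "site_class", "marker", "grade")], path
  )
}
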