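#' Build a disease x marker differential comparison table
#'
#' The side-by-side table used to compare candidate entities: disease
#' names down the rows, IHC antibody names across the columns, and the
#' knowledge-base grade in each cell (`NA` where the marker is not
#' profiled for the disease). Requested row and column order is
#' preserved.
#'
#' @param kb An `ihc_kb`.
#' @param diseases Character vector of disease names or aliases (rows).
#' @param markers Character vector of marker names or aliases (columns);
#'   may be empty for a table of disease names only.
#' @return An `ihc_diff_table`: a tibble with a `disease` column followed
#'   by one column per marker.
#' @export
#' @examples
#' kb <- demo_kb()
#' build_differential_table(
#'   kb,
#'   c("Follicular lymphoma", "Mantle cell lymphoma"),
#'   c("CD10", "CD5", "Cyclin D1", "BCL2")
#' )
build_differential_table <- function(kb, diseases, markers = character()) {
  d_res <- resolve_names(diseases, kb$diseases$name, kb$aliases)
  m_res <- if (length(markers)) {
    resolve_names(markers, kb$markers$name, kb$aliases)
  } else {
    character()
  }
  fails <- c(diseases[is.na(d_res)], markers[is.na(m_res)])
  if (length(fails)) {
    rlang::abort(paste0(
      "unresolvable name(s): ", paste(unique(fails), collapse = "; ")
    ))
  }
  if (anyDuplicated(d_res)) rlang::abort("duplicate diseases requested")
  if (anyDuplicated(m_res)) rlang::abort("duplicate markers requested")

  out <- tibble::tibble(disease = d_res)
  for (m in m_res) {
    out[[m]] <- if (length(d_res)) kb_grade(kb, d_res, m) else character()
  }
  structure(out, class = c("ihc_diff_table", class(tibble::tibble())))
}

#' Edit a differential comparison table
#'
#' Adds or removes one disease row or marker column; every other cell is
#' unchanged (cells for added names are filled from the knowledge base).
#'
#' @param t An `ihc_diff_table`.
#' @param action One of `"add_row"`, `"remove_row"`, `"add_column"`,
#'   `"remove_column"`.
#' @param name Disease or marker name (aliases accepted for additions).
#' @param kb The `ihc_kb` the table was built from.
#' @return A new `ihc_diff_table`.
#' @export
edit_table <- function(t, action, name, kb) {
  action <- match.arg(action,
                      c("add_row", "remove_row", "add_column", "remove_column"))
  diseases <- t$disease
  markers <- setdiff(names(t), "disease")
  if (action == "add_row") {
    cn <- resolve_disease(kb, name)
    if (cn %in% diseases) rlang::abort(paste0("disease already in table: ", cn))
    diseases <- c(diseases, cn)
  } else if (action == "remove_row") {
    cn <- resolve_disease(kb, name, error_on_missing = FALSE)
    hit <- match(cn %||% name, diseases)
    if (is.na(hit)) rlang::abort(paste0("disease not in table: ", name))
    diseases <- diseases[-hit]
  } else if (action == "add_column") {
    cn <- resolve_marker(kb, name)
    if (cn %in% markers) rlang::abort(paste0("marker already in table: ", cn))
    markers <- c(markers, cn)
  } else {
    cn <- resolve_marker(kb, name, error_on_missing = FALSE)
    hit <- match(cn %||% name, markers)
    if (is.na(hit)) rlang::abort(paste0("marker not in table: ", name))
    markers <- markers[-hit]
  }
  build_differential_table(kb, diseases, markers)
}

#' @export
print.ihc_diff_table <- function(x, ...) {
  cat(format_diff_table(x), sep = "\n")
  invisible(x)
}

#' Render a differential table as aligned text
#'
#' @param x An `ihc_diff_table`.
#' @return Character vector of lines (diseases as rows, markers as
#'   columns, grade labels in cells, `"?"` for unknown).
#' @export
format_diff_table <- function(x) {
  markers <- setdiff(names(x), "disease")
  dn <- format(c("Disease", x$disease))
  cols <- lapply(markers, function(m) {
    format(c(m, ifelse(is.na(x[[m]]), "?", x[[m]])), justify = "centre")
  })
  rows <- do.call(paste, c(list(dn), cols, sep = "  "))
  c(rows[1], strrep("-", nchar(rows[1])), rows[-1])
}

#' Plot a differential comparison table
#'
#' Heat-tile rendering of the table, grades shaded by representative
#' frequency.
#'
#' @param object An `ihc_diff_table`.
#' @param grades Grade table used for shading, by default [grade_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ihc_diff_table <- function(object, grades = grade_table(), ...) {
  markers <- setdiff(names(object), "disease")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), dplyr::all_of(markers),
    names_to = "marker", values_to = "grade"
  )
  long$marker <- factor(long$marker, levels = markers)
  long$disease <- factor(long$disease, levels = rev(object$disease))
  long$frequency <- ifelse(
    is.na(long$grade), NA_real_, grade_to_frequency(
      ifelse(is.na(long$grade), grades$label[1], long$grade), grades
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$marker, .data$disease)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$frequency), color = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$grade), "?",
                                                   .data$grade))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "expected\npositivity") +
    ggplot2::theme_minimal()
}
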