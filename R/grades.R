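#' The five-level graded expression scale
#'
#' IHC expression of a marker in a disease entity is recorded on an ordered
#' five-level scale of positivity: `"++"` for 75--100% of cases positive,
#' `"+"` for 50--74%, `"+/-"` for 30--49%, `"-/+"` for 10--29%, and `"-"`
#' for 0--9%. The five printed integer intervals tile 0--100%.
#'
#' Inference needs a point probability per grade; the convention used
#' throughout the package is the interval midpoint on the \[0, 1\] scale
#' (`"++"` -> 0.875, ..., `"-"` -> 0.045). The whole scale lives in this one
#' editable table so an alternative calibration is a single change: every
#' function that consumes grades accepts a `grades` argument.
#'
#' @return A tibble with columns `label`, `lo`, `hi` (closed integer
#'   percentage bounds) and `frequency` (representative probability),
#'   ordered from lowest (`"-"`) to highest (`"++"`) grade.
#' @export
#' @examples
#' grade_table()
grade_table <- function() {
  tibble::tibble(
    label = c("-", "-/+", "+/-", "+", "++"),
    lo = c(0, 10, 30, 50, 75),
    hi = c(9, 29, 49, 74, 100),
    frequency = c(0.045, 0.195, 0.395, 0.62, 0.875)
  )
}

#' Grade labels in ascending order of positivity
#'
#' @param grades A grade table, by default [grade_table()].
#' @return Character vector of the five labels, lowest first.
#' @export
grade_labels <- function(grades = grade_table()) {
  grades$label
}

validate_grade_table <- function(grades) {
  stopifnot(is.data.frame(grades))
  need <- c("label", "lo", "hi", "frequency")
  if (!all(need %in% names(grades))) {
    rlang::abort("grade table must have columns label, lo, hi, frequency")
  }
  if (anyDuplicated(grades$label)) {
    rlang::abort("grade table labels must be unique")
  }
  if (is.unsorted(grades$lo, strictly = TRUE)) {
    rlang::abort("grade table must be ordered by ascending lower bound")
  }
  inside <- grades$frequency > grades$lo / 100 & grades$frequency < grades$hi / 100
  # the bottom interval starts at 0, so "strictly inside" means (0, hi/100)
  inside[1] <- grades$frequency[1] > 0 & grades$frequency[1] < grades$hi[1] / 100
  if (!all(inside)) {
    rlang::abort(paste0(
      "representative frequency outside its own interval for grade(s): ",
      paste(grades$label[!inside], collapse = ", ")
    ))
  }
  invisible(grades)
}

#' Assign a grade label to a positivity percentage
#'
#' Maps a percentage of positive cases onto the five-level scale. The
#' printed integer brackets (0--9, 10--29, 30--49, 50--74, 75--100) are
#' extended to the continuous scale as half-open intervals
#' \[0,10), \[10,30), \[30,50), \[50,75), \[75,100\], which agrees with the
#' integer endpoints everywhere and leaves no fractional value unassigned.
#'
#' @param p Numeric vector of percentages in \[0, 100\].
#' @param grades A grade table, by default [grade_table()].
#' @return Character vector of grade labels.
#' @export
#' @examples
#' grade_from_percentage(c(80, 0, 50, 30, 74.5))
grade_from_percentage <- function(p, grades = grade_table()) {
  if (!is.numeric(p)) {
    rlang::abort("`p` must be numeric (a percentage in [0, 100])")
  }
  validate_grade_table(grades)
  bad <- is.na(p) | p < 0 | p > 100
  if (any(bad)) {
    rlang::abort(paste0(
      "percentage out of [0, 100]: ",
      paste(utils::head(p[bad], 5), collapse = ", ")
    ))
  }
  grades$label[findInterval(p, grades$lo)]
}

#' Representative frequency of a grade
#'
#' Converts grade labels to the point probability used by the inference
#' engine: the midpoint of the grade's percentage interval on the \[0, 1\]
#' scale (`"++"` -> 0.875, `"+"` -> 0.62, `"+/-"` -> 0.395,
#' `"-/+"` -> 0.195, `"-"` -> 0.045 under the default table).
#'
#' @param g Character vector of grade labels.
#' @inheritParams grade_from_percentage
#' @return Numeric vector of probabilities in (0, 1).
#' @export
#' @examples
#' grade_to_frequency(c("++", "-"))
grade_to_frequency <- function(g, grades = grade_table()) {
  validate_grade_table(grades)
  i <- match(g, grades$label)
  if (anyNA(i)) {
    rlang::abort(paste0(
      "unknown grade label(s): ",
      paste(unique(g[is.na(i)]), collapse = ", "),
      " (expected one of ", paste(grades$label, collapse = ", "), ")"
    ))
  }
  grades$frequency[i]
}
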