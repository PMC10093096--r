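LINEAGES <- c("B-cell", "T/NK-cell", "Hodgkin", "histiocytic", "other")
MARKER_ROLES <- c("diagnostic", "prognostic_only")

#' Construct an IHC knowledge base
#'
#' A knowledge base is the disease x marker grid of graded expression
#' frequencies from which likelihoods are drawn, together with a marker
#' registry (carrying role tags so purely prognostic/therapeutic markers
#' such as p53 or EGFR can be told apart from diagnostic ones) and an
#' alias table mapping alternative disease or marker spellings onto
#' canonical names.
#'
#' @param diseases Data frame with columns `name`, `lineage` (one of
#'   B-cell, T/NK-cell, Hodgkin, histiocytic, other) and optionally
#'   `site_class` (free-text location tag, e.g. nodal / extranodal /
#'   cutaneous; `NA` when unspecified).
#' @param expression Data frame with columns `disease`, `marker`, `grade`
#'   (grade labels from the `grades` table). Markers absent from a
#'   disease's rows are unknown for that disease.
#' @param markers Optional data frame with columns `name` and `role`
#'   (`"diagnostic"` or `"prognostic_only"`). Defaults to every marker
#'   appearing in `expression`, tagged diagnostic.
#' @param aliases Optional data frame with columns `alias`, `canonical`
#'   (or a named character vector, names = aliases).
#' @param grades Grade table, by default [grade_table()].
#' @return An object of class `ihc_kb`.
#' @export
#' @examples
#' kb <- new_kb(
#'   diseases = data.frame(name = c("A", "B"), lineage = "B-cell"),
#'   expression = data.frame(
#'     disease = c("A", "B"), marker = "CD20", grade = c("++", "-")
#'   )
#' )
#' kb
new_kb <- function(diseases, expression,
                   markers = NULL, aliases = NULL,
                   grades = grade_table()) {
  validate_grade_table(grades)

  diseases <- tibble::as_tibble(diseases)
  if (!nrow(diseases)) {
    diseases <- tibble::tibble(
      name = character(), lineage = character(), site_class = character()
    )
  }
  if (!all(c("name", "lineage") %in% names(diseases))) {
    rlang::abort("`diseases` needs columns `name` and `lineage`")
  }
  if (!"site_class" %in% names(diseases)) diseases$site_class <- NA_character_
  diseases <- diseases[, c("name", "lineage", "site_class")]
  diseases$name <- stringr::str_squish(diseases$name)

  expression <- tibble::as_tibble(expression)
  if (!nrow(expression)) {
    expression <- tibble::tibble(
      disease = character(), marker = character(), grade = character()
    )
  }
  if (!all(c("disease", "marker", "grade") %in% names(expression))) {
    rlang::abort("`expression` needs columns `disease`, `marker`, `grade`")
  }
  expression <- expression[, c("disease", "marker", "grade")]
  expression$disease <- stringr::str_squish(expression$disease)
  expression$marker <- stringr::str_squish(expression$marker)

  if (is.null(markers)) {
    markers <- tibble::tibble(
      name = unique(expression$marker), role = "diagnostic"
    )
  } else {
    markers <- tibble::as_tibble(markers)
    if (!"name" %in% names(markers)) {
      rlang::abort("`markers` needs a `name` column")
    }
    if (!"role" %in% names(markers)) markers$role <- "diagnostic"
    markers <- markers[, c("name", "role")]
    markers$name <- stringr::str_squish(markers$name)
  }

  if (is.null(aliases)) {
    aliases <- tibble::tibble(alias = character(), canonical = character())
  } else if (is.character(aliases)) {
    aliases <- tibble::tibble(
      alias = names(aliases), canonical = unname(aliases)
    )
  } else {
    aliases <- tibble::as_tibble(aliases)[, c("alias", "canonical")]
  }

  kb <- structure(
    list(
      diseases = diseases,
      markers = markers,
      expression = expression,
      aliases = aliases,
      grades = tibble::as_tibble(grades)
    ),
    class = "ihc_kb"
  )
  validate_kb(kb)
}

#' Validate a knowledge base
#'
#' Checks every structural invariant: canonical disease names unique
#' (after case/whitespace normalisation), all grade labels drawn from the
#' grade table, every profiled marker present in the registry, lineages
#' and marker roles from their closed vocabularies, and alias resolution
#' idempotent.
#'
#' @param kb An `ihc_kb`.
#' @return `kb`, invisibly, if valid; otherwise an error naming the
#'   offending disease/marker/record.
#' @export
validate_kb <- function(kb) {
  if (!inherits(kb, "ihc_kb")) rlang::abort("not an `ihc_kb` object")
  d <- kb$diseases

  dup <- duplicated(canonical_key(d$name))
  if (any(dup)) {
    rlang::abort(paste0(
      "duplicate disease name(s) after normalisation: ",
      paste(unique(d$name[dup]), collapse = "; ")
    ))
  }
  bad_lin <- !d$lineage %in% LINEAGES
  if (any(bad_lin)) {
    rlang::abort(paste0(
      "unknown lineage for ", paste(d$name[bad_lin], collapse = "; "),
      " (expected one of ", paste(LINEAGES, collapse = ", "), ")"
    ))
  }
  bad_role <- !kb$markers$role %in% MARKER_ROLES
  if (any(bad_role)) {
    rlang::abort(paste0(
      "unknown marker role for ",
      paste(kb$markers$name[bad_role], collapse = "; ")
    ))
  }
  if (anyDuplicated(canonical_key(kb$markers$name))) {
    rlang::abort("duplicate marker name(s) in registry")
  }

  e <- kb$expression
  bad_grade <- !e$grade %in% kb$grades$label
  if (any(bad_grade)) {
    i <- which(bad_grade)[1]
    rlang::abort(paste0(
      "unknown grade label \"", e$grade[i], "\" for disease \"",
      e$disease[i], "\", marker \"", e$marker[i], "\""
    ))
  }
  if (!all(canonical_key(e$disease) %in% canonical_key(d$name))) {
    miss <- unique(e$disease[!canonical_key(e$disease) %in% canonical_key(d$name)])
    rlang::abort(paste0(
      "expression rows reference unlisted disease(s): ",
      paste(miss, collapse = "; ")
    ))
  }
  if (!all(canonical_key(e$marker) %in% canonical_key(kb$markers$name))) {
    miss <- unique(e$marker[!canonical_key(e$marker) %in% canonical_key(kb$markers$name)])
    rlang::abort(paste0(
      "expression rows reference marker(s) absent from the registry: ",
      paste(miss, collapse = "; ")
    ))
  }
  if (anyDuplicated(paste(canonical_key(e$disease), canonical_key(e$marker)))) {
    rlang::abort("duplicate (disease, marker) expression rows")
  }

  a <- kb$aliases
  if (nrow(a)) {
    known <- c(canonical_key(d$name), canonical_key(kb$markers$name))
    bad <- !canonical_key(a$canonical) %in% known
    if (any(bad)) {
      rlang::abort(paste0(
        "alias target(s) not a canonical disease or marker: ",
        paste(a$canonical[bad], collapse = "; ")
      ))
    }
    # idempotence: an alias must never shadow a canonical name
    shadow <- canonical_key(a$alias) %in% known
    if (any(shadow)) {
      rlang::abort(paste0(
        "alias(es) shadow canonical names: ",
        paste(a$alias[shadow], collapse = "; ")
      ))
    }
  }
  invisible(kb)
}

# Resolve names against a registry of canonical names plus the alias table.
# Returns the canonical spelling, or NA for unresolvable names. Resolution
# is idempotent: canonical names resolve to themselves first.
resolve_names <- function(x, canonical, aliases) {
  key <- canonical_key(x)
  hit <- canonical[match(key, canonical_key(canonical))]
  still <- is.na(hit)
  if (any(still) && nrow(aliases)) {
    via <- aliases$canonical[match(key[still], canonical_key(aliases$alias))]
    # alias targets are stored in canonical spelling already, but normalise
    via <- canonical[match(canonical_key(via), canonical_key(canonical))]
    hit[still] <- via
  }
  hit
}

#' Resolve disease names to canonical spellings
#'
#' @param kb An `ihc_kb`.
#' @param x Character vector of disease names or aliases.
#' @param error_on_missing Abort (listing the failures) if any name does
#'   not resolve; otherwise return `NA` for it.
#' @return Character vector of canonical names.
#' @export
resolve_disease <- function(kb, x, error_on_missing = TRUE) {
  out <- resolve_names(x, kb$diseases$name, kb$aliases)
  if (error_on_missing && anyNA(out)) {
    rlang::abort(paste0(
      "unresolvable disease name(s): ",
      paste(unique(x[is.na(out)]), collapse = "; ")
    ))
  }
  out
}

#' Resolve marker names to canonical spellings
#'
#' @inheritParams resolve_disease
#' @param x Character vector of marker names or aliases.
#' @return Character vector of canonical names.
#' @export
resolve_marker <- function(kb, x, error_on_missing = TRUE) {
  out <- resolve_names(x, kb$markers$name, kb$aliases)
  if (error_on_missing && anyNA(out)) {
    rlang::abort(paste0(
      "unresolvable marker name(s): ",
      paste(unique(x[is.na(out)]), collapse = "; ")
    ))
  }
  out
}

#' Look up graded expression for (disease, marker) pairs
#'
#' @param kb An `ihc_kb`.
#' @param disease,marker Character vectors (recycled to common length) of
#'   canonical names or aliases.
#' @return Character vector of grade labels, `NA` where the marker is
#'   unknown for the disease.
#' @export
kb_grade <- function(kb, disease, marker) {
  n <- max(length(disease), length(marker))
  disease <- rep_len(resolve_disease(kb, disease), n)
  marker <- rep_len(resolve_marker(kb, marker), n)
  key <- paste(canonical_key(disease), canonical_key(marker), sep = "\r")
  ekey <- paste(canonical_key(kb$expression$disease),
                canonical_key(kb$expression$marker), sep = "\r")
  kb$expression$grade[match(key, ekey)]
}

#' @export
print.ihc_kb <- function(x, ...) {
  cat("<ihc_kb> ", nrow(x$diseases), " diseases x ", nrow(x$markers),
      " markers (", nrow(x$expression), " graded cells, ",
      nrow(x$aliases), " aliases)\n", sep = "")
  if (nrow(x$diseases)) {
    lin <- table(x$diseases$lineage)
    cat("  lineages:",
        paste(names(lin), lin, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Curated demonstration knowledge base
#'
#' Loads the knowledge base of 24 lymphoid-neoplasm entities shipped with
#' the package. Profiles are textbook immunophenotypes over 22 diagnostic
#' markers (plus prognostic-only p53 and EGFR) curated for demonstration
#' and testing; this is a small stand-in, not a production diagnostic
#' database.
#'
#' @return An `ihc_kb`.
#' @export
#' @examples
#' kb <- demo_kb()
#' nrow(kb$diseases)
demo_kb <- function() {
  read_kb(system.file("extdata", "demo_kb.json", package = "ihcbayes"))
}
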