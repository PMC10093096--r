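#' Percentage as printed in validation tables
#'
#' `numerator / denominator * 100`, rounded half-up to one decimal --
#' the convention used for every hit and error rate the package prints.
#'
#' @param numerator,denominator Non-negative counts,
#'   `numerator <= denominator`, `denominator > 0`. Vectorised.
#' @return Numeric percentage(s) with one decimal.
#' @export
#' @examples
#' rate(570, 602)  # 94.7
#' rate(0, 42)     # 0
rate <- function(numerator, denominator) {
  if (!is.numeric(numerator) || !is.numeric(denominator)) {
    rlang::abort("`numerator` and `denominator` must be numeric counts")
  }
  if (any(denominator <= 0)) {
    rlang::abort("`denominator` must be > 0")
  }
  if (any(numerator < 0 | numerator > denominator)) {
    rlang::abort("need 0 <= numerator <= denominator")
  }
  round_half_up(numerator / denominator * 100, 1)
}

EXCLUSION_REASONS <- c("duplicate", "no_diagnosis", "too_few_markers",
                       "prognostic_only")

#' Apply the case-exclusion filters
#'
#' Partitions a cohort into included and excluded cases following the
#' standard protocol: duplicated case ids (first occurrence kept), cases
#' lacking an original diagnosis (when ground truth is required), cases
#' with fewer than `min_markers` usable results, and cases whose usable
#' markers are all tagged `prognostic_only` in the registry (e.g. panels
#' of p53/EGFR only, which say nothing about tumor origin). A usable
#' result is `"+"` or `"-"` on a marker present in the registry.
#'
#' Results outside `{+, -, nd}` are *flagged* as inconclusive (and do not
#' count as usable) rather than silently dropped. Each excluded case
#' carries exactly one primary reason, assigned in the precedence order
#' duplicate > no_diagnosis > too_few_markers > prognostic_only.
#'
#' @param cases Long tibble of cases (see [as_cases()]).
#' @param kb An `ihc_kb` whose marker registry carries role tags.
#' @param min_markers Minimum usable results to keep a case (default 3:
#'   cases with fewer than three antibodies are excluded).
#' @param require_diagnosis Exclude cases with no `original_diagnosis`
#'   (default `TRUE`, the setting for validation runs).
#' @return An `ihc_filter_report`: list with `included` (case rows),
#'   `excluded` (case rows with a `reason` column) and `flagged`
#'   (case ids with inconclusive result values).
#' @export
filter_cases <- function(cases, kb, min_markers = 3, require_diagnosis = TRUE) {
  raw <- tibble::as_tibble(cases)
  if (!all(c("case_id", "marker", "result") %in% names(raw))) {
    rlang::abort("cases need columns case_id, marker, result")
  }
  if (!"original_diagnosis" %in% names(raw)) {
    raw$original_diagnosis <- NA_character_
  }
  if (!"site" %in% names(raw)) raw$site <- NA_character_
  raw <- raw[, c("case_id", "marker", "result", "original_diagnosis", "site")]
  raw$case_id <- as.character(raw$case_id)
  raw$result <- normalize_result(raw$result)

  # a duplicate case is a case id re-submitted as a separate record block
  # (e.g. on hospital transfer); the first block is kept, later ones are
  # excluded wholesale.
  runs <- rle(raw$case_id)
  dup_row <- rep(duplicated(runs$values), runs$lengths)
  dups <- raw[dup_row, ]
  cases <- as_cases(raw[!dup_row, ])
  per <- split_cases(cases)
  ids <- names(per)

  reason <- stats::setNames(rep(NA_character_, length(ids)), ids)
  flagged <- unique(raw$case_id[!raw$result %in% RESULT_LEVELS])

  for (id in ids) {
    x <- per[[id]]
    canon <- resolve_marker(kb, x$marker, error_on_missing = FALSE)
    usable <- x$result %in% c("+", "-") & !is.na(canon)
    roles <- kb$markers$role[match(canonical_key(canon[usable]),
                                   canonical_key(kb$markers$name))]
    if (require_diagnosis && all(is.na(x$original_diagnosis))) {
      reason[id] <- "no_diagnosis"
    } else if (sum(usable) < min_markers) {
      reason[id] <- "too_few_markers"
    } else if (length(roles) && all(roles == "prognostic_only")) {
      reason[id] <- "prognostic_only"
    }
  }

  keep <- ids[is.na(reason)]
  out <- cases[cases$case_id %in% keep, ]
  exc <- cases[!cases$case_id %in% keep, ]
  exc$reason <- unname(reason[exc$case_id])
  if (nrow(dups)) {
    dups$reason <- "duplicate"
    exc <- dplyr::bind_rows(exc, dups)
  }
  structure(
    list(
      included = out,
      excluded = exc,
      flagged = flagged
    ),
    class = "ihc_filter_report"
  )
}

#' @export
print.ihc_filter_report <- function(x, ...) {
  n_in <- length(unique(x$included$case_id))
  n_ex <- length(unique(x$excluded$case_id))
  cat("<ihc_filter_report> included ", n_in, " case(s), excluded ", n_ex,
      "\n", sep = "")
  if (n_ex) {
    tab <- table(dplyr::distinct(x$excluded, .data$case_id, .data$reason)$reason)
    for (r in names(tab)) cat("  ", r, ": ", tab[[r]], "\n", sep = "")
  }
  if (length(x$flagged)) {
    cat("  inconclusive result values flagged in: ",
        paste(x$flagged, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# lineage + profile compatibility of every disease pair: same lineage and
# identical grades on every marker graded for both (site_class free to
# differ). Used by the inclusive-hit rule.
kb_compat_matrix <- function(kb) {
  d <- kb$diseases$name
  n <- length(d)
  g <- matrix(NA_character_, n, ncol = nrow(kb$markers),
              dimnames = list(d, kb$markers$name))
  if (nrow(kb$expression)) {
    i <- match(canonical_key(kb$expression$disease), canonical_key(d))
    j <- match(canonical_key(kb$expression$marker),
               canonical_key(kb$markers$name))
    g[cbind(i, j)] <- kb$expression$grade
  }
  compat <- diag(TRUE, n)
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in seq(a + 1, n)) {
        if (kb$diseases$lineage[a] != kb$diseases$lineage[b]) next
        shared <- !is.na(g[a, ]) & !is.na(g[b, ])
        ok <- !any(shared) || all(g[a, shared] == g[b, shared])
        compat[a, b] <- compat[b, a] <- ok
      }
    }
  }
  dimnames(compat) <- list(d, d)
  compat
}

#' Strict hit of a case against a ranked differential
#'
#' A strict hit means the case's original diagnosis (alias-normalised
#' through the knowledge base when given) appears among the entries of
#' the truncated differential.
#'
#' @param case One case: a data frame with an `original_diagnosis`.
#' @param rd An `ihc_differential`, truncated to k via [top_k()].
#' @param kb Optional `ihc_kb` for alias resolution of the diagnosis.
#' @return One-row tibble: `case_id`, `strict_hit`, `inclusive_hit`
#'   (`NA` here; see [inclusive_hit()]), `rank_of_truth` (`NA` if the
#'   truth is not listed).
#' @export
strict_hit <- function(case, rd, kb = NULL) {
  case <- as_cases(case)
  truth <- unique(case$original_diagnosis[!is.na(case$original_diagnosis)])
  if (length(truth) != 1) {
    rlang::abort("case must carry exactly one original_diagnosis")
  }
  if (!is.null(kb)) {
    truth <- resolve_disease(kb, truth, error_on_missing = FALSE) %||% truth
    if (is.na(truth)) truth <- unique(case$original_diagnosis)[1]
  }
  rank <- match(canonical_key(truth), canonical_key(rd$disease))
  tibble::tibble(
    case_id = case$case_id[1],
    strict_hit = !is.na(rank),
    inclusive_hit = NA,
    rank_of_truth = rank
  )
}

#' Inclusive hit of a case against a ranked differential
#'
#' An inclusive hit is a strict hit, or a near-miss where some listed
#' entry shares the truth's cell of origin (lineage) and an identical
#' knowledge-base expression profile over every marker graded for both
#' entities, differing at most in anatomic location (site_class) -- the
#' nodal vs extranodal marginal-zone-lymphoma situation.
#'
#' @inheritParams strict_hit
#' @param kb An `ihc_kb` (required: supplies lineage and profiles).
#' @return One-row tibble as in [strict_hit()], with `inclusive_hit`
#'   filled; if the truth is absent from the knowledge base the inclusive
#'   outcome is undeterminable and returned as `NA` with attribute
#'   `undeterminable = TRUE` recorded in the `undeterminable` column.
#' @export
inclusive_hit <- function(case, rd, kb) {
  out <- strict_hit(case, rd, kb)
  truth <- unique(as_cases(case)$original_diagnosis)
  truth <- truth[!is.na(truth)][1]
  canon <- resolve_disease(kb, truth, error_on_missing = FALSE)
  out$undeterminable <- FALSE
  if (is.na(canon)) {
    out$inclusive_hit <- NA
    out$undeterminable <- TRUE
    return(out)
  }
  if (out$strict_hit) {
    out$inclusive_hit <- TRUE
    return(out)
  }
  compat <- kb_compat_matrix(kb)
  entries <- resolve_disease(kb, rd$disease, error_on_missing = FALSE)
  entries <- entries[!is.na(entries)]
  out$inclusive_hit <- any(compat[canon, entries])
  out
}

#' Evaluate a cohort against a knowledge base
#'
#' Runs the full validation protocol: per case, compute the posterior,
#' truncate to the top `k`, score strict and/or inclusive hits, then
#' aggregate per original-diagnosis entity and overall. Rates are
#' percentages rounded half-up to one decimal (see [rate()]).
#'
#' Cases should already have passed [filter_cases()]; a case with no
#' usable result aborts. Cases whose original diagnosis is absent from
#' the knowledge base are counted as misses (their inclusive outcome is
#' undeterminable) and a warning totals them.
#'
#' @param cases Long tibble of cases with `original_diagnosis`.
#' @param kb An `ihc_kb`.
#' @param k Differential length (default 10).
#' @param mode `"both"` (default), `"strict"` or `"inclusive"`.
#' @param prior Passed to [posterior()].
#' @return An `ihc_evaluation`: list with `outcomes` (one row per case),
#'   `per_entity` (entity x mode error table) and `overall` (one row per
#'   mode with accurate/error counts and rates).
#' @export
evaluate_cases <- function(cases, kb, k = 10, mode = c("both", "strict",
                                                       "inclusive"),
                           prior = "uniform") {
  mode <- match.arg(mode)
  cases <- as_cases(cases)
  if (!nrow(cases)) rlang::abort("empty case list")
  per <- split_cases(cases)

  fmat <- kb_freq_matrix(kb)
  dnames <- rownames(fmat)
  log_prior <- resolve_prior(prior, kb)
  need_inclusive <- mode %in% c("both", "inclusive")
  compat <- if (need_inclusive) kb_compat_matrix(kb)

  rows <- vector("list", length(per))
  n_truth_missing <- 0L
  for (i in seq_along(per)) {
    x <- per[[i]]
    truth_raw <- unique(x$original_diagnosis[!is.na(x$original_diagnosis)])
    if (length(truth_raw) != 1) {
      rlang::abort(paste0("case ", x$case_id[1],
                          " must carry exactly one original_diagnosis"))
    }
    res <- normalize_result(x$result)
    keep <- res %in% c("+", "-")
    mk <- resolve_marker(kb, x$marker[keep], error_on_missing = FALSE)
    ok <- !is.na(mk)
    if (!any(ok)) {
      rlang::abort(paste0("case ", x$case_id[1],
                          " has no usable results; run filter_cases() first"))
    }
    p <- posterior_core(fmat, mk[ok], res[keep][ok] == "+", log_prior)
    ord <- order(-p, dnames, method = "radix")
    ranked <- dnames[ord]
    topk <- ranked[seq_len(min(k, length(ranked)))]

    truth <- resolve_disease(kb, truth_raw, error_on_missing = FALSE)
    if (is.na(truth)) {
      n_truth_missing <- n_truth_missing + 1L
      rows[[i]] <- tibble::tibble(
        case_id = x$case_id[1], entity = truth_raw,
        rank_of_truth = NA_integer_, strict_hit = FALSE,
        inclusive_hit = NA, undeterminable = TRUE
      )
      next
    }
    rank <- match(truth, ranked)
    strict <- rank <= k
    inclusive <- if (need_inclusive) {
      strict || any(compat[truth, topk])
    } else {
      NA
    }
    rows[[i]] <- tibble::tibble(
      case_id = x$case_id[1], entity = truth,
      rank_of_truth = rank, strict_hit = strict,
      inclusive_hit = inclusive, undeterminable = FALSE
    )
  }
  if (n_truth_missing) {
    rlang::warn(paste0(
      n_truth_missing,
      " case(s) have an original diagnosis absent from the knowledge base;",
      " counted as misses (inclusive outcome undeterminable)"
    ))
  }
  outcomes <- dplyr::bind_rows(rows)

  modes <- switch(mode, both = c("strict", "inclusive"), mode)
  per_entity <- dplyr::bind_rows(lapply(modes, function(md) {
    hit <- if (md == "strict") outcomes$strict_hit else outcomes$inclusive_hit
    hit[is.na(hit)] <- FALSE
    outcomes |>
      dplyr::mutate(hit = hit) |>
      dplyr::group_by(entity = .data$entity) |>
      dplyr::summarise(
        mode = md,
        errors = sum(!.data$hit),
        total = dplyr::n(),
        error_rate = rate(sum(!.data$hit), dplyr::n()),
        .groups = "drop"
      )
  }))
  overall <- dplyr::bind_rows(lapply(modes, function(md) {
    hit <- if (md == "strict") outcomes$strict_hit else outcomes$inclusive_hit
    hit[is.na(hit)] <- FALSE
    tibble::tibble(
      mode = md,
      accurate = sum(hit),
      errors = sum(!hit),
      total = length(hit),
      hit_rate = rate(sum(hit), length(hit)),
      error_rate = rate(sum(!hit), length(hit))
    )
  }))

  structure(
    list(outcomes = outcomes, per_entity = per_entity, overall = overall,
         k = as.integer(k), mode = mode),
    class = "ihc_evaluation"
  )
}

#' @export
print.ihc_evaluation <- function(x, ...) {
  cat("<ihc_evaluation> ", nrow(x$outcomes), " case(s), top-", x$k,
      " differential\n", sep = "")
  ov <- x$overall
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-9s hit rate %s%% (%d/%d), error rate %s%%\n",
                ov$mode[i], format(ov$hit_rate[i], nsmall = 1),
                ov$accurate[i], ov$total[i],
                format(ov$error_rate[i], nsmall = 1)))
  }
  invisible(x)
}

#' Per-entity error table of an evaluation
#'
#' @param x An `ihc_evaluation`.
#' @param ... Unused.
#' @return Tibble with `entity`, `mode`, `errors`, `total`, `error_rate`.
#' @export
#' @exportS3Method generics::tidy
tidy.ihc_evaluation <- function(x, ...) {
  x$per_entity
}

#' Overall summary of an evaluation
#'
#' @param x An `ihc_evaluation`.
#' @param ... Unused.
#' @return Tibble with one row per scoring mode: `accurate`, `errors`,
#'   `total`, `hit_rate`, `error_rate`.
#' @export
#' @exportS3Method generics::glance
glance.ihc_evaluation <- function(x, ...) {
  x$overall
}

#' Plot per-entity error rates
#'
#' @param object An `ihc_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ihc_evaluation <- function(object, ...) {
  df <- object$per_entity
  df$entity <- factor(df$entity, levels = rev(sort(unique(df$entity))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$error_rate, y = .data$entity,
                                   fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "error rate (%)", y = NULL, fill = "hit definition") +
    ggplot2::theme_minimal()
}

#' Write evaluation reports to disk
#'
#' Emits the per-entity error table and the overall summary, each as CSV,
#' plus a combined JSON report.
#'
#' @param ev An `ihc_evaluation`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default `"evaluation"`).
#' @return Character vector of the paths written, invisibly.
#' @export
write_evaluation <- function(ev, dir, stem = "evaluation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(stem, "_per_entity.csv"))
  p2 <- file.path(dir, paste0(stem, "_overall.csv"))
  p3 <- file.path(dir, paste0(stem, ".json"))
  readr::write_csv(ev$per_entity, p1)
  readr::write_csv(ev$overall, p2)
  jsonlite::write_json(
    list(k = ev$k, per_entity = ev$per_entity, overall = ev$overall,
         outcomes = ev$outcomes),
    p3, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
  )
  invisible(c(p1, p2, p3))
}

#' Chi-square comparison of accuracy across datasets
#'
#' Pearson chi-square test (no continuity correction) on a 2 x g
#' contingency table of accurate/error counts per dataset group, df =
#' g - 1. Used to compare hit rates between, e.g., training, validation
#' and external-validation cohorts.
#'
#' @param counts Either a data frame with columns `accurate` and `error`
#'   (one row per group, optional `group` column) or a 2 x g matrix with
#'   rows accurate/error.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' compare_datasets(data.frame(accurate = c(570, 365, 2715),
#'                             error = c(32, 17, 278)))
compare_datasets <- function(counts) {
  if (is.data.frame(counts)) {
    if (!all(c("accurate", "error") %in% names(counts))) {
      rlang::abort("`counts` needs columns `accurate` and `error`")
    }
    m <- rbind(accurate = counts$accurate, error = counts$error)
    if ("group" %in% names(counts)) colnames(m) <- counts$group
  } else {
    m <- as.matrix(counts)
    if (nrow(m) != 2) rlang::abort("`counts` matrix must be 2 x g")
  }
  if (ncol(m) < 2) rlang::abort("need at least two dataset groups")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    rlang::abort("zero row or column sum in the contingency table")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = as.numeric(ht$parameter),
    p_value = unname(ht$p.value)
  )
}
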