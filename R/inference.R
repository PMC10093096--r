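# Disease x marker matrix of representative positivity frequencies.
# NA marks a marker unknown for a disease (neutral 0.5 at likelihood time).
kb_freq_matrix <- function(kb) {
  d <- kb$diseases$name
  m <- kb$markers$name
  f <- matrix(NA_real_, nrow = length(d), ncol = length(m),
              dimnames = list(d, m))
  if (nrow(kb$expression)) {
    i <- match(canonical_key(kb$expression$disease), canonical_key(d))
    j <- match(canonical_key(kb$expression$marker), canonical_key(m))
    f[cbind(i, j)] <- grade_to_frequency(kb$expression$grade, kb$grades)
  }
  f
}

# Core naive-Bayes update, vectorised over all diseases at once and done
# in log space. `fmat` is kb_freq_matrix(kb); `markers` / `positive` the
# observed panel; `log_prior` a vector aligned with rownames(fmat).
# Returns the normalised posterior vector.
posterior_core <- function(fmat, markers, positive, log_prior) {
  f <- fmat[, markers, drop = FALSE]
  f[is.na(f)] <- 0.5
  f <- clamp01(f)
  ll <- log(f)
  if (any(!positive)) {
    neg <- which(!positive)
    ll[, neg] <- log1p(-f[, neg, drop = FALSE])
  }
  lp <- log_prior + rowSums(ll)
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

# Turn a prior spec ("uniform" or a named probability vector) into a
# log-prior aligned with the KB's diseases.
resolve_prior <- function(prior, kb) {
  d <- kb$diseases$name
  if (identical(prior, "uniform")) {
    return(rep(log(1 / length(d)), length(d)))
  }
  if (!is.numeric(prior) || is.null(names(prior))) {
    rlang::abort("`prior` must be \"uniform\" or a named numeric vector")
  }
  nm <- resolve_disease(kb, names(prior))
  p <- rep(0, length(d))
  p[match(canonical_key(nm), canonical_key(d))] <- unname(prior)
  if (abs(sum(p) - 1) > 1e-6) {
    rlang::abort("`prior` must sum to 1 over the knowledge-base diseases")
  }
  if (any(p < 0)) rlang::abort("`prior` probabilities must be non-negative")
  log(p)
}

#' Likelihood of one marker result under one disease
#'
#' The per-marker likelihood behind the Bayes update: if the knowledge
#' base grades the marker for the disease with representative frequency
#' `f`, a positive result has likelihood `f` and a negative result
#' `1 - f`; a marker unknown for the disease is uninformative (0.5 either
#' way). All values are clamped to \[0.01, 0.99\] so no single result can
#' annihilate a candidate.
#'
#' @param kb An `ihc_kb`.
#' @param disease,marker Character vectors (recycled) of names/aliases.
#' @param result Character vector in `{"+", "-"}` (`"nd"` results carry
#'   no information and are rejected here; drop them before calling).
#' @return Numeric vector of likelihoods.
#' @export
#' @examples
#' kb <- demo_kb()
#' marker_likelihood(kb, "Mantle cell lymphoma", "CD20", "+")
marker_likelihood <- function(kb, disease, marker, result) {
  result <- normalize_result(result)
  if (any(!result %in% c("+", "-"))) {
    rlang::abort(
      "`result` must be \"+\" or \"-\"; filter out not-done results first"
    )
  }
  g <- kb_grade(kb, disease, marker)
  f <- ifelse(is.na(g), 0.5, NA_real_)
  f[is.na(f)] <- grade_to_frequency(g[!is.na(g)], kb$grades)
  f <- clamp01(f)
  ifelse(rep_len(result, length(f)) == "+", f, 1 - f)
}

#' Posterior differential diagnosis for one case
#'
#' Applies Bayes' theorem over all knowledge-base diseases given the
#' observed IHC panel, assuming conditional independence of markers given
#' disease (naive Bayes over the graded frequency table). Computation is
#' done in log space; the returned probabilities over all candidates sum
#' to 1.
#'
#' Not-done (`"nd"`) results are ignored. Markers absent from the entire
#' knowledge-base registry are skipped with a warning; markers merely
#' ungraded for some disease contribute a neutral likelihood of 0.5 for
#' that disease.
#'
#' @param case Data frame with columns `marker` and `result` (one case; a
#'   `case_id` column, if present, must be constant).
#' @param kb An `ihc_kb`.
#' @param prior `"uniform"` (default) or a named probability vector over
#'   the knowledge-base diseases (e.g. incidence weights).
#' @return An `ihc_differential`: a tibble with columns `disease` and
#'   `posterior`, sorted by descending probability with ties broken by
#'   canonical name; attributes record the case id, panel used and prior.
#' @export
#' @examples
#' kb <- demo_kb()
#' case <- data.frame(
#'   marker = c("CD20", "CD3", "CD5", "Cyclin D1"),
#'   result = c("+", "-", "+", "+")
#' )
#' top_k(posterior(case, kb), 5)
posterior <- function(case, kb, prior = "uniform") {
  case <- tibble::as_tibble(case)
  if (!all(c("marker", "result") %in% names(case))) {
    rlang::abort("`case` needs columns `marker` and `result`")
  }
  case_id <- if ("case_id" %in% names(case)) unique(case$case_id) else NA_character_
  if (length(case_id) != 1) {
    rlang::abort("`posterior()` takes one case; use evaluate_cases() for cohorts")
  }
  if (!nrow(kb$diseases)) rlang::abort("knowledge base has no diseases")

  res <- normalize_result(case$result)
  keep <- res %in% c("+", "-")
  if (!any(keep)) {
    rlang::abort("case has no usable (+/-) results")
  }
  markers <- stringr::str_squish(case$marker[keep])
  res <- res[keep]

  canon <- resolve_marker(kb, markers, error_on_missing = FALSE)
  unknown <- is.na(canon)
  if (any(unknown)) {
    rlang::warn(paste0(
      "skipping marker(s) absent from the knowledge base: ",
      paste(unique(markers[unknown]), collapse = ", ")
    ))
    canon <- canon[!unknown]
    res <- res[!unknown]
  }
  if (!length(canon)) {
    rlang::abort("no observed marker is present in the knowledge base")
  }
  if (anyDuplicated(canonical_key(canon))) {
    rlang::abort("duplicate markers within the case after normalisation")
  }

  fmat <- kb_freq_matrix(kb)
  p <- posterior_core(fmat, canon, res == "+", resolve_prior(prior, kb))
  ord <- order(-p, rownames(fmat), method = "radix")

  new_differential(
    tibble::tibble(disease = rownames(fmat)[ord],
                   posterior = unname(p[ord])),
    case_id = case_id,
    markers = stats::setNames(res, canon),
    k = NA_integer_
  )
}

new_differential <- function(df, case_id, markers, k) {
  structure(
    df,
    case_id = case_id,
    markers = markers,
    k = k,
    class = c("ihc_differential", class(tibble::tibble()))
  )
}

#' Truncate a ranked differential to its top k entries
#'
#' Keeps the first `k` entries (probability descending, ties broken by
#' canonical name ascending). Probabilities are **not** renormalised:
#' they remain posteriors over the full candidate set, so a truncated
#' differential sums to at most 1.
#'
#' @param rd An `ihc_differential` from [posterior()].
#' @param k Maximum number of entries (default 10, the standard length of
#'   the displayed differential).
#' @return An `ihc_differential` with at most `k` rows.
#' @export
top_k <- function(rd, k = 10) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    rlang::abort("`k` must be a single count >= 1")
  }
  k <- as.integer(k)
  out <- rd[seq_len(min(k, nrow(rd))), ]
  new_differential(
    tibble::as_tibble(out),
    case_id = attr(rd, "case_id"),
    markers = attr(rd, "markers"),
    k = k
  )
}

#' @export
print.ihc_differential <- function(x, ...) {
  id <- attr(x, "case_id")
  k <- attr(x, "k")
  cat("<ihc_differential>",
      if (!is.na(id)) paste0(" case ", id) else "",
      if (!is.na(k)) paste0(" (top ", k, ")") else "", "\n", sep = "")
  n <- nrow(x)
  for (i in seq_len(n)) {
    cat(sprintf("  %2d. %-55s %6s%%\n", i, x$disease[i],
                format_pct(x$posterior[i])))
  }
  invisible(x)
}

#' Tidy a ranked differential
#'
#' @param x An `ihc_differential`.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `disease`, `posterior` and
#'   `percent` (display percentage, half-up to one decimal).
#' @export
#' @exportS3Method generics::tidy
tidy.ihc_differential <- function(x, ...) {
  tibble::tibble(
    rank = seq_len(nrow(x)),
    disease = x$disease,
    posterior = x$posterior,
    percent = round_half_up(100 * x$posterior, 1)
  )
}

#' One-row summary of a ranked differential
#'
#' @param x An `ihc_differential`.
#' @param ... Unused.
#' @return A tibble with the number of candidates shown, markers used,
#'   the leading diagnosis and its posterior, and the Shannon entropy (in
#'   nats) of the listed probabilities.
#' @export
#' @exportS3Method generics::glance
glance.ihc_differential <- function(x, ...) {
  p <- x$posterior
  tibble::tibble(
    n_candidates = nrow(x),
    n_markers = length(attr(x, "markers")),
    top_disease = x$disease[1],
    top_posterior = p[1],
    entropy = -sum(ifelse(p > 0, p * log(p), 0))
  )
}

#' Plot a ranked differential
#'
#' Horizontal bar chart of posterior probabilities, most probable at the
#' top.
#'
#' @param object An `ihc_differential`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ihc_differential <- function(object, ...) {
  df <- tidy.ihc_differential(object)
  df$disease <- factor(df$disease, levels = rev(df$disease))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$posterior, y = .data$disease)) +
    ggplot2::geom_col(fill = "#8c2d2d") +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(
      x = "posterior probability", y = NULL,
      title = "Ranked differential diagnosis",
      subtitle = if (!is.na(attr(object, "case_id"))) {
        paste("case", attr(object, "case_id"))
      }
    ) +
    ggplot2::theme_minimal()
}
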