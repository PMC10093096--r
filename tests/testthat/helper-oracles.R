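# Independent oracles and tiny fixtures shared across the test files.
# The oracles deliberately avoid the package's log-space code path.

# Naive product-formula Bayes posterior: enumerates the likelihood product
# disease by disease, marker by marker, with plain arithmetic.
brute_posterior <- function(case, kb, prior = NULL) {
  d <- kb$diseases$name
  if (is.null(prior)) prior <- stats::setNames(rep(1 / length(d), length(d)), d)
  gt <- kb$grades
  score <- numeric(length(d))
  for (i in seq_along(d)) {
    s <- prior[[d[i]]]
    for (r in seq_len(nrow(case))) {
      g <- kb$expression$grade[
        kb$expression$disease == d[i] & kb$expression$marker == case$marker[r]
      ]
      f <- if (length(g)) gt$frequency[match(g, gt$label)] else 0.5
      f <- min(max(f, 0.01), 0.99)
      s <- s * if (case$result[r] == "+") f else 1 - f
    }
    score[i] <- s
  }
  stats::setNames(score / sum(score), d)
}

# Textbook Pearson chi-square on a 2 x g table: sum over cells of
# (observed - expected)^2 / expected.
chisq_manual <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# A tiny hand-built KB used across files: three B-cell entities, one
# T-cell entity, four markers, one alias, one prognostic-only marker.
tiny_kb <- function() {
  new_kb(
    diseases = data.frame(
      name = c("Alpha lymphoma", "Beta lymphoma", "Gamma lymphoma",
               "Delta T lymphoma"),
      lineage = c("B-cell", "B-cell", "B-cell", "T/NK-cell"),
      site_class = c("nodal", "extranodal", NA, "nodal")
    ),
    expression = data.frame(
      disease = c(rep("Alpha lymphoma", 3), rep("Beta lymphoma", 3),
                  rep("Gamma lymphoma", 2), rep("Delta T lymphoma", 2)),
      marker = c("CD20", "CD5", "CD10",
                 "CD20", "CD5", "CD10",
                 "CD20", "CD10",
                 "CD3", "CD20"),
      grade = c("++", "++", "-",
                "++", "++", "-",
                "++", "++",
                "++", "-")
    ),
    markers = data.frame(
      name = c("CD20", "CD5", "CD10", "CD3", "p53"),
      role = c(rep("diagnostic", 4), "prognostic_only")
    ),
    aliases = c("alpha NHL" = "Alpha lymphoma", "B-CD20" = "CD20")
  )
}

# Random uniform-grade KB + a random case drawn from it; small sizes keep
# the brute-force oracle cheap.
random_instance <- function(seed, max_d = 6, max_m = 6) {
  withr::with_seed(seed, {
    n_d <- sample(2:max_d, 1)
    n_m <- sample(2:max_m, 1)
    kb <- simulate_kb(n_diseases = n_d, n_markers = n_m,
                      overlap = stats::runif(1), seed = seed)
    n_obs <- sample(seq_len(n_m), 1)
    case <- tibble::tibble(
      case_id = paste0("rnd", seed),
      marker = sample(kb$markers$name, n_obs),
      result = sample(c("+", "-"), n_obs, replace = TRUE)
    )
    list(kb = kb, case = case)
  })
}
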