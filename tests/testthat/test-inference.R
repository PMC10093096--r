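two_disease_kb <- function(grade_a = "++", grade_b = "-") {
  new_kb(
    diseases = data.frame(name = c("A disease", "B disease"),
                          lineage = "B-cell"),
    expression = data.frame(
      disease = c("A disease", "B disease"),
      marker = "CD20",
      grade = c(grade_a, grade_b)
    )
  )
}

test_that("marker likelihood follows the graded frequency table", {
  kb <- tiny_kb()
  expect_equal(marker_likelihood(kb, "Alpha lymphoma", "CD20", "+"), 0.875)
  expect_equal(marker_likelihood(kb, "Delta T lymphoma", "CD20", "+"), 0.045)
  expect_equal(marker_likelihood(kb, "Delta T lymphoma", "CD20", "-"), 0.955)
  # marker unknown for the disease: neutral either way
  expect_equal(marker_likelihood(kb, "Alpha lymphoma", "CD3", "+"), 0.5)
  expect_equal(marker_likelihood(kb, "Alpha lymphoma", "CD3", "-"), 0.5)
  expect_error(marker_likelihood(kb, "Alpha lymphoma", "CD20", "nd"),
               "not-done")
})

test_that("posterior reproduces direct Bayes arithmetic", {
  kb <- two_disease_kb("++", "-")
  rd <- posterior(data.frame(marker = "CD20", result = "+"), kb)
  # 0.5 * 0.875 vs 0.5 * 0.045, normalised
  expect_equal(rd$posterior[rd$disease == "A disease"], 0.875 / 0.92,
               tolerance = 1e-12)
  expect_equal(rd$posterior[rd$disease == "B disease"], 0.045 / 0.92,
               tolerance = 1e-12)
})

test_that("identical profiles split the posterior symmetrically", {
  kb <- two_disease_kb("+", "+")
  rd <- posterior(data.frame(marker = "CD20", result = "+"), kb)
  expect_equal(rd$posterior, c(0.5, 0.5))
})

test_that("uninformative evidence returns the prior", {
  kb <- two_disease_kb()
  # CD99 unknown to the whole KB is skipped with a warning; with nothing
  # usable left the case is rejected
  expect_error(
    suppressWarnings(
      posterior(data.frame(marker = "CD99", result = "+"), kb)
    ),
    "no observed marker"
  )
  # a marker in the registry but ungraded for every disease is neutral:
  # the posterior equals the (non-uniform) prior
  kb2 <- new_kb(
    diseases = data.frame(name = c("A disease", "B disease"),
                          lineage = "B-cell"),
    expression = data.frame(disease = "A disease", marker = "CD20",
                            grade = "++"),
    markers = data.frame(name = c("CD20", "CD30"), role = "diagnostic")
  )
  prior <- c("A disease" = 0.3, "B disease" = 0.7)
  rd <- posterior(data.frame(marker = "CD30", result = "+"), kb2,
                  prior = prior)
  expect_equal(stats::setNames(rd$posterior, rd$disease),
               sort(prior, decreasing = TRUE))
})

test_that("not-done results and unknown markers are handled per contract", {
  kb <- two_disease_kb()
  expect_error(
    posterior(data.frame(marker = "CD20", result = "nd"), kb),
    "no usable"
  )
  expect_warning(
    posterior(data.frame(marker = c("CD20", "CD99"), result = c("+", "+")),
              kb),
    "CD99"
  )
})

test_that("log-space engine matches the brute-force oracle", {
  for (seed in 1:200) {
    inst <- random_instance(seed)
    rd <- posterior(inst$case, inst$kb)
    oracle <- brute_posterior(inst$case, inst$kb)
    expect_equal(stats::setNames(rd$posterior, rd$disease),
                 oracle[rd$disease], tolerance = 1e-9)
    expect_equal(sum(rd$posterior), 1, tolerance = 1e-9)
  }
})

test_that("posterior is invariant to the order of the panel", {
  inst <- random_instance(42)
  rd1 <- posterior(inst$case, inst$kb)
  shuffled <- inst$case[rev(seq_len(nrow(inst$case))), ]
  rd2 <- posterior(shuffled, inst$kb)
  expect_equal(rd1$disease, rd2$disease)
  expect_equal(rd1$posterior, rd2$posterior)
})

test_that("adding a marker with identical frequency everywhere keeps the ranking", {
  kb <- new_kb(
    diseases = data.frame(name = c("A disease", "B disease"),
                          lineage = "B-cell"),
    expression = data.frame(
      disease = rep(c("A disease", "B disease"), each = 2),
      marker = rep(c("CD20", "CD30"), 2),
      grade = c("++", "+", "-", "+")
    )
  )
  base <- posterior(data.frame(marker = "CD20", result = "+"), kb)
  extended <- posterior(
    data.frame(marker = c("CD20", "CD30"), result = c("+", "+")), kb
  )
  expect_equal(base$disease, extended$disease)
  expect_equal(base$posterior, extended$posterior, tolerance = 1e-12)
})

test_that("observing a marker positive favours the higher-frequency disease", {
  for (pair in list(c("++", "+"), c("+", "-/+"), c("+/-", "-"))) {
    kb <- two_disease_kb(pair[1], pair[2])
    rd <- posterior(data.frame(marker = "CD20", result = "+"), kb)
    expect_identical(rd$disease[1], "A disease")
    expect_gt(rd$posterior[1], 0.5)
  }
})

test_that("top_k truncates without renormalising and breaks ties by name", {
  kb <- simulate_kb(n_diseases = 12, n_markers = 6, overlap = 0, seed = 3)
  rd <- posterior(data.frame(marker = kb$markers$name[1], result = "+"), kb)
  t10 <- top_k(rd, 10)
  expect_identical(nrow(t10), 10L)
  expect_identical(t10$posterior, rd$posterior[1:10])
  expect_lte(sum(t10$posterior), 1)
  expect_identical(nrow(top_k(rd, 100)), 12L)
  expect_error(top_k(rd, 0), "k")

  # exact ties straddling the cut keep the alphabetically earlier name
  kb2 <- new_kb(
    diseases = data.frame(name = c("Zeta", "Eta", "Theta"),
                          lineage = "B-cell"),
    expression = data.frame(
      disease = c("Zeta", "Eta", "Theta"), marker = "CD20",
      grade = c("++", "++", "-")
    )
  )
  rd2 <- posterior(data.frame(marker = "CD20", result = "+"), kb2)
  expect_identical(top_k(rd2, 1)$disease, "Eta")
  expect_identical(rd2$disease[1:2], c("Eta", "Zeta"))
})
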