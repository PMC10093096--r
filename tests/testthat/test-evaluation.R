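test_that("rate() reproduces printed ratio arithmetic and guards input", {
  expect_equal(rate(570, 602), 94.7)
  expect_equal(rate(0, 42), 0)
  expect_equal(rate(63, 436), 14.4)
  expect_error(rate(1, 0), "> 0")
  expect_error(rate(5, 3), "numerator")
  expect_error(rate(-1, 3), "numerator")
})

test_that("case-exclusion filters follow the protocol", {
  kb <- tiny_kb()
  cases <- tibble::tibble(
    case_id = c(rep("ok3", 3), rep("few2", 2), rep("prog", 3),
                rep("nodx", 3), rep("dupA", 3), rep("zz", 3), rep("dupA", 3)),
    marker = c("CD20", "CD5", "CD10",
               "CD20", "CD5",
               "p53", "p53x", "p53y",
               "CD20", "CD5", "CD10",
               "CD20", "CD5", "CD10",
               "CD20", "CD5", "CD10",
               "CD20", "CD5", "CD10"),
    result = "+",
    original_diagnosis = c(rep("Alpha lymphoma", 8), rep(NA, 3),
                           rep("Alpha lymphoma", 9)),
    site = NA_character_
  )
  # give prog three distinct prognostic-only markers via a richer registry
  kb2 <- new_kb(
    diseases = kb$diseases, expression = kb$expression,
    markers = rbind(kb$markers,
                    data.frame(name = c("p53x", "p53y"),
                               role = "prognostic_only")),
    aliases = c("alpha NHL" = "Alpha lymphoma")
  )
  fr <- filter_cases(cases, kb2)
  reasons <- dplyr::distinct(fr$excluded, case_id, reason)
  # dupA appears twice as separate blocks: the first is kept on its own
  # merits, the re-submission is excluded as a duplicate
  expect_setequal(unique(fr$included$case_id), c("ok3", "zz", "dupA"))
  expect_identical(reasons$reason[reasons$case_id == "few2"],
                   "too_few_markers")
  expect_identical(reasons$reason[reasons$case_id == "prog"],
                   "prognostic_only")
  expect_identical(reasons$reason[reasons$case_id == "nodx"], "no_diagnosis")
  expect_identical(reasons$reason[reasons$case_id == "dupA"], "duplicate")
})

test_that("a three-diagnostic-marker case sits exactly on the inclusion boundary", {
  kb <- tiny_kb()
  ok <- tibble::tibble(case_id = "c1", marker = c("CD20", "CD5", "CD10"),
                       result = c("+", "-", "+"),
                       original_diagnosis = "Alpha lymphoma")
  expect_identical(unique(filter_cases(ok, kb)$included$case_id), "c1")
  # an inconclusive value is flagged, not dropped, and not usable
  odd <- tibble::tibble(case_id = "c2",
                        marker = c("CD20", "CD5", "CD10"),
                        result = c("+", "equivocal", "+"),
                        original_diagnosis = "Alpha lymphoma")
  fr <- filter_cases(odd, kb)
  expect_identical(fr$flagged, "c2")
  expect_identical(unique(fr$excluded$case_id), "c2")
  expect_identical(unique(fr$excluded$reason), "too_few_markers")
})

test_that("strict hits respect rank, truncation and aliases", {
  kb <- demo_kb()
  case <- tibble::tibble(
    case_id = "x", marker = c("CD20", "CD10", "Bcl-2", "Bcl-6"),
    result = c("+", "+", "+", "+"),
    original_diagnosis = "FL" # alias spelling of the truth
  )
  rd <- top_k(posterior(case, kb), 10)
  h <- strict_hit(case, rd, kb)
  expect_true(h$strict_hit)
  expect_identical(h$rank_of_truth, 1L)
  # absent truth
  case2 <- dplyr::mutate(case, original_diagnosis = "Mycosis fungoides")
  h2 <- strict_hit(case2, top_k(posterior(case2, kb), 3), kb)
  expect_false(h2$strict_hit)
  expect_true(is.na(h2$rank_of_truth))
})

test_that("inclusive hits admit location-only near-misses", {
  kb <- demo_kb()
  # a marginal-zone panel: the nodal and extranodal entities tie; truth
  # nodal MZL is inclusive-hit through MALT even at k = 1 if MALT wins
  case <- tibble::tibble(
    case_id = "mz", marker = c("CD20", "CD5", "CD10", "CD23", "Bcl-2"),
    result = c("+", "-", "-", "-", "+"),
    original_diagnosis = "Nodal marginal zone lymphoma"
  )
  rd1 <- top_k(posterior(case, kb), 1)
  expect_identical(rd1$disease, "Extranodal marginal zone lymphoma of MALT")
  h <- inclusive_hit(case, rd1, kb)
  expect_false(h$strict_hit)
  expect_true(h$inclusive_hit)
  # same lineage but differing profile is not inclusive
  case2 <- dplyr::mutate(case, original_diagnosis = "Follicular lymphoma")
  h2 <- inclusive_hit(case2, rd1, kb)
  expect_false(h2$inclusive_hit)
  # truth absent from the KB: undeterminable
  case3 <- dplyr::mutate(case, original_diagnosis = "Not in KB lymphoma")
  h3 <- inclusive_hit(case3, rd1, kb)
  expect_true(is.na(h3$inclusive_hit))
  expect_true(h3$undeterminable)
})

test_that("strict hits imply inclusive hits on random cohorts", {
  kb <- simulate_kb(n_diseases = 8, n_markers = 10, overlap = 0.6, seed = 11)
  cases <- simulate_cases(kb, panel_size = 4, cases_per_disease = 5,
                          atypical_rate = 0.2, seed = 11)
  ev <- evaluate_cases(cases, kb, k = 3, mode = "both")
  expect_true(all(ev$outcomes$inclusive_hit[ev$outcomes$strict_hit]))
})

test_that("evaluation aggregates hits per entity with printed rates", {
  kb <- new_kb(
    diseases = data.frame(name = c("A disease", "B disease"),
                          lineage = "B-cell"),
    expression = data.frame(
      disease = c("A disease", "B disease"), marker = "CD20",
      grade = c("++", "-")
    )
  )
  cases <- tibble::tibble(
    case_id = rep(c("c1", "c2", "c3"), each = 1),
    marker = "CD20",
    result = c("+", "+", "-"), # c3 ranks B first => miss at k = 1
    original_diagnosis = "A disease"
  )
  ev <- evaluate_cases(cases, kb, k = 1, mode = "strict")
  pe <- ev$per_entity
  expect_identical(pe$entity, "A disease")
  expect_identical(pe$errors, 1L)
  expect_identical(pe$total, 3L)
  expect_equal(pe$error_rate, 33.3)
  expect_equal(ev$overall$hit_rate, 66.7)
  expect_error(evaluate_cases(cases[0, ], kb), "empty")
})

test_that("per-entity totals conserve the overall counts", {
  kb <- simulate_kb(n_diseases = 10, n_markers = 12, overlap = 0.5, seed = 5)
  cases <- simulate_cases(kb, panel_size = 5, cases_per_disease = 6,
                          atypical_rate = 0.3, seed = 5)
  ev <- evaluate_cases(cases, kb, k = 3, mode = "both")
  for (md in c("strict", "inclusive")) {
    pe <- dplyr::filter(ev$per_entity, mode == md)
    ov <- dplyr::filter(ev$overall, mode == md)
    expect_identical(sum(pe$total), ov$total)
    expect_identical(sum(pe$errors), ov$errors)
    expect_identical(ov$accurate + ov$errors, ov$total)
  }
})

test_that("hit rate is non-decreasing in k", {
  kb <- simulate_kb(n_diseases = 12, n_markers = 10, overlap = 0.7, seed = 9)
  cases <- simulate_cases(kb, panel_size = 4, cases_per_disease = 5,
                          atypical_rate = 0.25, seed = 9)
  hr <- vapply(c(1, 3, 5, 10), function(k) {
    evaluate_cases(cases, kb, k = k, mode = "strict")$overall$hit_rate
  }, numeric(1))
  expect_true(all(diff(hr) >= 0))
})

test_that("chi-square comparison matches the textbook formula", {
  counts <- data.frame(group = c("training", "validation", "external"),
                       accurate = c(570, 365, 2715),
                       error = c(32, 17, 278))
  res <- compare_datasets(counts)
  m <- rbind(counts$accurate, counts$error)
  expect_equal(res$statistic, chisq_manual(m), tolerance = 1e-9)
  expect_identical(res$df, 2)
  expect_equal(res$p_value,
               stats::pchisq(res$statistic, 2, lower.tail = FALSE))
  # identical proportions give a zero statistic
  z <- compare_datasets(data.frame(accurate = c(90, 45), error = c(10, 5)))
  expect_equal(z$statistic, 0)
  # invariant under group order
  res_rev <- compare_datasets(counts[3:1, ])
  expect_equal(res$statistic, res_rev$statistic)
  expect_error(compare_datasets(data.frame(accurate = c(5, 5),
                                           error = c(0, 0))),
               "zero")
  expect_error(compare_datasets(data.frame(accurate = 5, error = 2)),
               "two dataset groups")
})

test_that("evaluation reports write CSV and JSON mirrors", {
  kb <- tiny_kb()
  cases <- tibble::tibble(
    case_id = rep(c("c1", "c2"), each = 3),
    marker = rep(c("CD20", "CD5", "CD10"), 2),
    result = c("+", "+", "-", "+", "+", "+"),
    original_diagnosis = c(rep("Alpha lymphoma", 3), rep("Gamma lymphoma", 3))
  )
  ev <- evaluate_cases(cases, kb, k = 2)
  dir <- withr::local_tempdir()
  paths <- write_evaluation(ev, dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_setequal(back$entity, c("Alpha lymphoma", "Gamma lymphoma"))
  js <- jsonlite::fromJSON(paths[3])
  expect_identical(js$k, ev$k)
})
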