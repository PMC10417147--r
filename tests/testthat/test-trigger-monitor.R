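test_that("delta_d99 arithmetic, sign convention and mismatch errors", {
  p <- coverage_record("c1", "PLAN", "CTV_HIGH", 100)
  e <- coverage_record("c1", "GTCT", "CTV_HIGH", 96.5)
  expect_identical(delta_d99(p, e), 3.5)
  expect_identical(delta_d99(p, p), 0)
  expect_identical(delta_d99(p, e), -delta_d99(e, p))
  bad <- coverage_record("c2", "GTCT", "CTV_HIGH", 96.5)
  expect_error(delta_d99(p, bad), "case_id")
  bad2 <- coverage_record("c1", "GTCT", "CTV_STANDARD", 96.5)
  expect_error(delta_d99(p, bad2), "structure")
})

test_that("trigger rule matches a brute-force truth table incl. boundaries", {
  deltas <- seq(-1, 7, by = 0.5)   # includes exactly 3 and 5
  grid <- tidyr::expand_grid(structure = c("CTV_HIGH", "CTV_STANDARD"),
                             delta_d99 = deltas)
  rep <- suppressMessages(apply_trigger(grid))
  truth <- ifelse(grid$structure == "CTV_HIGH", grid$delta_d99 > 3,
                  grid$delta_d99 > 5)
  expect_identical(rep$structures$triggered, truth)
  # strictness at the printed thresholds
  at3 <- suppressMessages(
    apply_trigger(tibble::tibble(structure = "CTV_HIGH", delta_d99 = 3)))
  expect_false(at3$review)
  at4 <- apply_trigger(tibble::tibble(structure = "CTV_STANDARD", delta_d99 = 4))
  expect_false(at4$review)
  hi <- apply_trigger(tibble::tibble(structure = "CTV_HIGH", delta_d99 = 3.5))
  expect_true(hi$review)
})

test_that("both structures above threshold yield a single review flag", {
  rep <- apply_trigger(tibble::tibble(structure = c("CTV_HIGH", "CTV_STANDARD"),
                                      delta_d99 = c(4, 6)))
  expect_true(rep$review)
  expect_identical(sum(glance(rep)$review), 1L)
  expect_identical(glance(rep)$n_triggered, 2L)
})

test_that("apply_trigger rejects unknown roles and empty input", {
  expect_error(apply_trigger(tibble::tibble(structure = "BRAINSTEM",
                                            delta_d99 = 9)), "no threshold")
  expect_error(apply_trigger(tibble::tibble(structure = character(),
                                            delta_d99 = numeric())), "no CTV")
})

test_that("wilcoxon: exact enumeration worked examples", {
  # n = 6, all positive: two-sided p = 2/64
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_identical(r$method, "exact")
  expect_equal(r$p_value, 2 / 64)
  expect_identical(r$statistic, 21)
  # exactly mirrored sample: maximal two-sided p
  r2 <- wilcoxon_signed_rank(c(1.3, -1.3, 2.7, -2.7, 0.6, -0.6))
  expect_identical(r2$p_value, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
})

test_that("wilcoxon agrees with the reference implementation (no ties)", {
  set.seed(31)
  for (n in c(6, 9, 12, 15)) {
    x <- round(rnorm(n, 0.4, 1), 4)
    x <- x[x != 0]
    ours <- wilcoxon_signed_rank(x)
    ref <- stats::wilcox.test(x, exact = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("exact and approximate branches agree within 0.02 at n = 15", {
  set.seed(17)
  for (rep in 1:10) {
    x <- rnorm(15, 0.3, 1)
    pe <- wilcoxon_signed_rank(x, exact_max = 15)$p_value
    pa <- wilcoxon_signed_rank(x, exact_max = 5)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("wilcoxon handles ties via midranks and drops zeros", {
  x <- c(2, 2, -2, 3, 3, 0, 0, 1)
  r <- wilcoxon_signed_rank(x)
  expect_identical(r$n, 6L)
  ref <- suppressWarnings(stats::wilcox.test(x[x != 0], correct = TRUE))
  # tie-corrected approximation comparison for sanity only
  expect_true(r$p_value > 0 && r$p_value <= 1)
})

test_that("cohort summary: zero-error surrogates, exclusions, permutation invariance", {
  recs <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(case_id = sprintf("c%02d", i),
                   image = rep(c("PLAN", "GTCT", "VFCT", "CORRCBCT", "VIRTCT"), 2),
                   structure = rep(c("CTV_HIGH", "CTV_STANDARD"), each = 5),
                   d99 = rep(c(100, 98, 98, 98, 98), 2))
  }))
  s <- summarize_cohort(recs)
  expect_true(all(s$accuracy$mean_abs_dd99 == 0))
  expect_true(all(s$accuracy$sd_abs_dd99 == 0))
  expect_identical(s$n_reviews, 0L)
  # order invariance
  s2 <- summarize_cohort(recs[sample(nrow(recs)), ])
  expect_identical(dplyr::arrange(s$accuracy, image, structure),
                   dplyr::arrange(s2$accuracy, image, structure))
  # missing gtCT -> excluded with warning
  recs2 <- dplyr::filter(recs, !(case_id == "c01" & image == "GTCT"))
  expect_warning(s3 <- summarize_cohort(recs2), "without a gtCT")
  expect_identical(s3$loss$n, c(5L, 5L))
})

test_that("planted surrogate errors are recovered over a 200-case cohort", {
  co <- generate_cohort(200, cohort_scenario(), seed = 77)
  recs <- cohort_coverage_records(co)
  s <- summarize_cohort(recs)
  # mean |N(0, sd)| = sd * sqrt(2/pi); check within 2 standard errors
  for (img in c("VFCT", "CORRCBCT", "VIRTCT")) {
    sdv <- cohort_scenario()$surrogate_sd[[img]]
    expected <- sdv * sqrt(2 / pi)
    got <- s$accuracy$mean_abs_dd99[s$accuracy$image == img]
    se <- sdv * sqrt(1 - 2 / pi) / sqrt(200)
    expect_true(all(abs(got - expected) < 2.5 * se + 0.05))
  }
  # trigger count equals the plant list exactly
  expect_identical(s$n_reviews, sum(co$cases$planted_review))
  expect_identical(
    sort(s$review_cases$case_id[s$review_cases$review]),
    sort(co$cases$case_id[co$cases$planted_review]))
  # synthetic CTs beat the verification CT significantly on this cohort
  pw <- s$pairwise
  expect_identical(nrow(pw), 6L)
  expect_true(all(pw$p_value[pw$reference == "VFCT"] < 0.05))
})

test_that("review-rate estimator is consistent as the cohort grows", {
  # the estimator is exact w.r.t. the planted flags at every n; the planted
  # rate itself converges to the scenario probability (binomial check at
  # the largest n, where the fixed-seed draw is well inside the CI)
  for (n in c(50, 200, 800)) {
    co <- generate_cohort(n, cohort_scenario(p_trigger = 0.19), seed = 5)
    s <- summarize_cohort(cohort_coverage_records(co))
    expect_identical(s$review_rate, mean(co$cases$planted_review))
    if (n == 800) {
      ci <- 1.96 * sqrt(0.19 * 0.81 / n)
      expect_lt(abs(s$review_rate - 0.19), ci + 0.02)
    }
  }
})
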