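test_that("composite score and positivity follow the 0-7 scheme", {
  expect_equal(composite_score(3L, 4L), 7L)
  expect_equal(composite_score(0L, 0L), 0L)
  expect_equal(composite_score(2L, 3L), 5L)
  expect_error(composite_score(4L, 0L), class = "basalmir_validation_error")
  expect_error(composite_score(1L, 5L), class = "basalmir_validation_error")

  expect_true(ihc_positive(1L, 1L))
  expect_false(ihc_positive(0L, 0L))
  expect_equal(ihc_positive(c(0, 1, 3), c(0, 2, 4)), c(FALSE, TRUE, TRUE))
})

test_that("chi-square on the printed 2x2 tables reproduces the published p-values", {
  # cyclin D1 initial cohort: positive 8/22 BRCA1 vs 30/46 sporadic
  ccnd <- chisq_2x2(8, 14, 30, 16)
  expect_equal(round(ccnd$p_value, 3), 0.025)
  expect_equal(ccnd$statistic, 5.0256, tolerance = 1e-4)
  # closed form (ad - bc)^2 N / (r1 r2 c1 c2)
  closed <- (8 * 16 - 14 * 30)^2 * 68 / (22 * 46 * 38 * 30)
  expect_equal(ccnd$statistic, closed, tolerance = 1e-10)

  nrp <- chisq_2x2(2, 18, 23, 23)
  expect_equal(round(nrp$p_value, 3), 0.002)

  # no association
  flat <- chisq_2x2(5, 5, 5, 5)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # invariant under simultaneous row and column swaps
  expect_equal(chisq_2x2(16, 30, 14, 8)$statistic, ccnd$statistic,
               tolerance = 1e-10)

  expect_error(chisq_2x2(0, 0, 5, 5), class = "basalmir_validation_error")
})

test_that("Mann-Whitney switches between exact and tie-corrected paths", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 0.1)   # 2 of the 20 arrangements are as extreme

  same <- mann_whitney(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(same$p_value, 1)

  # exhaustive permutation oracle, tie-free small samples
  set.seed(29)
  for (rep in 1:5) {
    a <- sample(100, 6); b <- sample(200:300, 7)
    r <- mann_whitney(a, b)
    expect_equal(r$p_value, oracle_mw_perm(a, b), tolerance = 1e-12)
  }
})

test_that("marker comparison rebuilds the printed NRP1 result from records", {
  mk_records <- function(marker, pos_b, n_b, pos_s, n_s) {
    tibble::tibble(
      case_id = sprintf("%s_c%02d", marker, seq_len(n_b + n_s)),
      cohort = "initial",
      truth_group = rep(c("brca1", "sporadic"), c(n_b, n_s)),
      marker = marker,
      intensity = as.integer(c(rep(c(2L, 0L), c(pos_b, n_b - pos_b)),
                               rep(c(2L, 0L), c(pos_s, n_s - pos_s)))),
      percent_category = as.integer(c(rep(c(3L, 0L), c(pos_b, n_b - pos_b)),
                                      rep(c(3L, 0L), c(pos_s, n_s - pos_s)))),
      evaluable = TRUE
    )
  }
  nrp <- compare_marker(mk_records("NRP1", 2, 20, 23, 46), "NRP1")
  expect_equal(nrp$pos_brca1, 2L)
  expect_equal(nrp$pos_sporadic, 23L)
  expect_equal(round(nrp$p_chi2, 3), 0.002)
  expect_equal(round(nrp$pct_brca1), 10)
  expect_equal(round(nrp$pct_sporadic), 50)

  # non-evaluable records are excluded from the table
  rec <- mk_records("FOXP1", 6, 20, 37, 49)
  rec_extra <- dplyr::bind_rows(rec, tibble::tibble(
    case_id = "naA", cohort = "initial", truth_group = "brca1",
    marker = "FOXP1", intensity = 3L, percent_category = 4L,
    evaluable = FALSE))
  fox <- compare_marker(rec_extra, "FOXP1")
  expect_equal(fox$n_brca1, 20L)
  expect_true(fox$p_chi2 < 0.001)

  none <- rec; none$evaluable <- FALSE
  expect_error(compare_marker(none, "FOXP1"),
               class = "basalmir_validation_error")
})

test_that("null-cohort chi-square p-values are approximately uniform", {
  # equal planted positivity in both groups; check the p distribution is
  # not anti-conservative (KS sanity at alpha = 0.01)
  set.seed(101)
  ps <- vapply(1:60, function(i) {
    sim <- sim_ihc_cohort(
      n_brca1 = 150, n_sporadic = 150,
      positivity = list(brca1 = c(M = 0.5), sporadic = c(M = 0.5)),
      panel_negative_corr = 0, evaluable_prob = 1, seed = 5000 + i
    )
    compare_marker(sim$records, "M")$p_chi2
  }, numeric(1))
  # discrete counts can tie; the KS statistic itself is unaffected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("panel rule classifies by counting negative markers", {
  rec <- tibble::tibble(
    case_id = rep(c("c1", "c2", "c3", "c4"), each = 3),
    cohort = "initial",
    truth_group = rep(c("brca1", "brca1", "sporadic", "sporadic"), each = 3),
    marker = rep(c("FOXP1", "CCND1", "NRP1"), 4),
    intensity = as.integer(c(0, 0, 2,   0, 0, 0,   2, 2, 2,   2, 2, 0)),
    percent_category = as.integer(c(0, 0, 3,  0, 0, 0,  3, 3, 3,  3, 3, 0)),
    evaluable = c(rep(TRUE, 9), TRUE, TRUE, FALSE)
  )
  pred <- panel_classify(rec) |> suppressMessages()
  # c1: 2 negatives -> brca1; c2: 3 negatives -> brca1; c3: 0 -> sporadic;
  # c4 excluded (non-evaluable NRP1)
  expect_equal(pred$case_id, c("c1", "c2", "c3"))
  expect_equal(pred$predicted, c("brca1", "brca1", "sporadic"))
  expect_equal(attr(pred, "n_excluded"), 1L)

  res <- evaluate_panel(pred)
  expect_equal(res$confusion$tp, 2L)
  expect_equal(res$confusion$tn, 1L)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(with(res$confusion, tp + fp + tn + fn), res$n)

  all_pos <- evaluate_panel(tibble::tibble(
    truth_group = c("brca1", "sporadic"), predicted = "brca1"))
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
})

test_that("prevalence-adjusted predictive values follow Bayes' rule", {
  perfect <- prevalence_adjusted_pv(1, 1)
  expect_equal(perfect$adjusted_ppv, 1)
  expect_equal(perfect$adjusted_npv, 1)

  adj <- prevalence_adjusted_pv(0.92, 0.44)
  expect_equal(adj$derived_prevalence, 0.092, tolerance = 1e-12)
  expect_equal(adj$adjusted_ppv, 0.1427, tolerance = 1e-3)
  expect_equal(adj$adjusted_npv, 0.9819, tolerance = 1e-3)

  expect_error(prevalence_adjusted_pv(0.9, 0.5, p_mutation = 0.5,
                                      p_basal = 0.1,
                                      p_basal_given_mutation = 0.9),
               class = "basalmir_assumption_error")

  # PPV rises and NPV falls with prevalence
  grid <- seq(0.05, 0.9, by = 0.05)
  pv <- purrr::map_dfr(grid, function(pr)
    prevalence_adjusted_pv(0.92, 0.44, p_mutation = pr * 0.15 / 0.69))
  expect_true(all(diff(pv$adjusted_ppv) > 0))
  expect_true(all(diff(pv$adjusted_npv) < 0))
})

test_that("ihc_panel reports cohort and adjusted values side by side", {
  sim <- sim_ihc_cohort(seed = 31)
  res <- suppressMessages(ihc_panel(sim$records))
  g <- glance(res)
  expect_true(all(c("sensitivity", "specificity", "cohort_ppv", "cohort_npv",
                    "adjusted_ppv", "adjusted_npv") %in% names(g)))
  expect_equal(g$derived_prevalence, 0.092, tolerance = 1e-12)
  expect_true(all(dplyr::between(tidy(res)$estimate, 0, 1)))
  expect_s3_class(autoplot(res), "ggplot")
})
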