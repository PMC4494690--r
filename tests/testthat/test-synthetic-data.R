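test_that("expression generator is deterministic and structurally valid", {
  a <- sim_expression(n_features = 50, de_features = 5, seed = 8)
  b <- sim_expression(n_features = 50, de_features = 5, seed = 8)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth$de, b$truth$de)
  expect_false(identical(
    a$matrix$values, sim_expression(n_features = 50, de_features = 5,
                                    seed = 9)$matrix$values))

  expect_true(all(a$matrix$values > 0))
  expect_identical(a$matrix$stage, "raw")
  expect_equal(nrow(a$annotations), ncol(a$matrix$values))
  # chips nest within runs
  expect_silent(basalmir:::validate_annotations(a$annotations))
  expect_equal(nrow(a$truth$de), 10L)
})

test_that("degenerate generator settings produce identical samples within a run", {
  sim <- sim_expression(n_features = 30, de_features = 0, log2_effect = 0,
                        chip_effect_sd = 0, noise_sd = 0, run_scale = 1.5,
                        seed = 2)
  v <- sim$matrix$values
  for (r in unique(sim$annotations$run_id)) {
    cols <- sim$annotations$sample_id[sim$annotations$run_id == r]
    spread <- apply(v[, cols, drop = FALSE], 1, function(x) diff(range(x)))
    expect_equal(unname(spread), rep(0, nrow(v)))
  }
  # run 2 scaled up by run_scale relative to run 1
  c1 <- sim$annotations$sample_id[sim$annotations$run_id == "run1"][1]
  c2 <- sim$annotations$sample_id[sim$annotations$run_id == "run2"][1]
  expect_equal(v[, c2] / v[, c1], rep(1.5, 30), ignore_attr = TRUE)
})

test_that("background offset produces negative minima for the shift stage", {
  sim <- sim_expression(n_features = 40, de_features = 0,
                        baseline_log2_mean = 4, background_offset = 50,
                        seed = 12)
  expect_true(any(sim$matrix$values < 0))
  shifted <- sim$matrix |>
    filter_low_intensity(0) |> shift_min_to_one() |> suppressMessages()
  expect_equal(unname(apply(shifted$values, 2, min)),
               rep(1, ncol(shifted$values)))
})

test_that("target tables hit their configured specificities", {
  mirnas <- paste0("m", 1:8)
  perfect <- sim_target_tables(mirnas, source_specificities = c(s = 1),
                               true_targets_per_mirna = 10, seed = 6)
  expect_setequal(paste(perfect$tables$s$mirna_id, perfect$tables$s$gene_id),
                  paste(perfect$truth$mirna_id, perfect$truth$gene_id))

  half <- sim_target_tables(mirnas, source_specificities = c(s = 0.5),
                            true_targets_per_mirna = 10, seed = 6)
  per_mirna <- table(half$tables$s$mirna_id)
  expect_true(all(per_mirna == 20))  # 10 true + 10 false each

  expect_error(sim_target_tables(mirnas, source_specificities = c(s = 0)),
               class = "basalmir_validation_error")

  two <- sim_target_tables(mirnas, source_specificities = c(a = 0.44, b = 0.61),
                           seed = 6)
  u <- union_targets(two$tables)
  expect_true(all(paste(two$truth$mirna_id, two$truth$gene_id) %in%
                    paste(u$mirna_id, u$gene_id)))
})

test_that("cleavage planting is exact in count and direction", {
  truth <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                          mirna_direction = rep(c("up_in_A", "down_in_A"), 100))
  ann <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:12),
    group = rep(c("basal_brca1", "basal_sporadic"), each = 6),
    run_id = "run1", chip_id = "chip1"
  )
  g <- sim_gene_expression(truth, ann, cleavage_fraction = 0.2,
                           noise_sd = 0.5, seed = 3)
  expect_equal(sum(g$truth$cleaved), 40L)   # round(200 * 0.2), without replacement

  none <- sim_gene_expression(truth, ann, cleavage_fraction = 0, noise_sd = 0,
                              seed = 3)
  v <- none$matrix$values
  expect_equal(max(abs(log2(v[, 1]) - log2(v[, 12]))), 0)

  all_c <- sim_gene_expression(truth, ann, cleavage_fraction = 1, noise_sd = 0,
                               mrna_log2_effect = 1.5, seed = 3)
  lv <- log2(all_c$matrix$values)
  delta <- rowMeans(lv[, 1:6]) - rowMeans(lv[, 7:12])
  # every true target shifted by exactly the effect, opposite to its miRNAs
  expect_equal(unname(delta[truth$gene_id]),
               ifelse(truth$mirna_direction == "up_in_A", -1.5, 1.5),
               tolerance = 1e-10)
  expect_equal(unname(delta[201:length(delta)]),
               rep(0, length(delta) - 200), tolerance = 1e-10)
})

test_that("IHC cohort recovers planted positivity within 3 binomial SEs", {
  full_pos <- sim_ihc_cohort(
    n_brca1 = 30, n_sporadic = 30,
    positivity = list(brca1 = c(A = 1, B = 1, C = 1),
                      sporadic = c(A = 1, B = 1, C = 1)),
    evaluable_prob = 1, seed = 9
  )
  pos <- ihc_positive(full_pos$records$intensity,
                      full_pos$records$percent_category)
  expect_true(all(pos))

  planted <- list(brca1 = c(A = 0.3, B = 0.3, C = 0.3),
                  sporadic = c(A = 0.76, B = 0.76, C = 0.76))
  big <- sim_ihc_cohort(n_brca1 = 500, n_sporadic = 500,
                        positivity = planted, evaluable_prob = 1, seed = 14)
  obs <- big$records |>
    dplyr::group_by(truth_group, marker) |>
    dplyr::summarise(p = mean(ihc_positive(intensity, percent_category)),
                     .groups = "drop")
  for (i in seq_len(nrow(obs))) {
    p0 <- planted[[obs$truth_group[i]]][[obs$marker[i]]]
    se <- sqrt(p0 * (1 - p0) / 500)
    expect_lt(abs(obs$p[i] - p0), 3 * se)
  }

  # records validate and are deterministic
  again <- sim_ihc_cohort(n_brca1 = 500, n_sporadic = 500,
                          positivity = planted, evaluable_prob = 1, seed = 14)
  expect_identical(big$records, again$records)
})

test_that("panel-rule sensitivity matches the closed-form k-of-n oracle", {
  # independent markers with per-marker negativity q such that
  # P(>= 2 of 3 negative) = 3 q^2 (1-q) + q^3 = 0.9
  q <- uniroot(function(q) 3 * q^2 * (1 - q) + q^3 - 0.9, c(0.5, 0.99),
               tol = 1e-12)$root
  sens_target <- oracle_kofn(rep(q, 3), 2)
  expect_equal(sens_target, 0.9, tolerance = 1e-9)

  sim <- sim_ihc_cohort(
    n_brca1 = 1000, n_sporadic = 50,
    positivity = list(brca1 = c(FOXP1 = 1 - q, CCND1 = 1 - q, NRP1 = 1 - q),
                      sporadic = c(FOXP1 = 0.9, CCND1 = 0.9, NRP1 = 0.9)),
    panel_negative_corr = 0, evaluable_prob = 1, seed = 21
  )
  res <- suppressMessages(ihc_panel(sim$records))
  se <- sqrt(0.9 * 0.1 / 1000)
  expect_lt(abs(res$sensitivity - 0.9), 3 * se)
})
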