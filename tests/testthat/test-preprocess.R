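test_that("intensity filter keeps the boundary and drops below-threshold probes", {
  m <- make_raw_matrix(rbind(c(149.9, 10), c(150, 20), c(600, 30)))
  f <- suppressMessages(filter_low_intensity(m, 150))
  expect_equal(rownames(f$values), c("f02", "f03"))  # exactly-150 retained
  expect_identical(f$stage, "filtered")

  # threshold 0 is the identity on positive matrices
  f0 <- suppressMessages(filter_low_intensity(m, 0))
  expect_identical(f0$values, m$values)

  # features with a missing value are excluded
  v <- matrix(c(500, NA, 500, 500), 2, 2,
              dimnames = list(c("keep", "drop"), c("s1", "s2")))
  fna <- suppressMessages(filter_low_intensity(expr_matrix(v), 150))
  expect_equal(rownames(fna$values), "keep")

  low <- make_raw_matrix(matrix(c(1, 2), 1, 2))
  expect_error(suppressMessages(filter_low_intensity(low, 150)),
               class = "basalmir_filter_error")
})

test_that("planted sub-threshold features are exactly the ones removed", {
  set.seed(11)
  vals <- matrix(runif(200 * 5, 200, 1000), 200, 5)
  sub <- sample(200, 100)
  vals[sub, ] <- runif(100 * 5, 1, 149)
  m <- make_raw_matrix(vals)
  f <- suppressMessages(filter_low_intensity(m, 150))
  brute <- rownames(m$values)[apply(m$values, 1, max) >= 150]
  expect_setequal(rownames(f$values), brute)
  expect_equal(sort(setdiff(rownames(m$values), rownames(f$values))),
               sort(rownames(m$values)[sub]))
})

test_that("detection filter uses a strict inequality over any sample", {
  m <- make_raw_matrix(matrix(100, 3, 2))
  scores <- rbind(c(0.95, 0.95),   # all at threshold -> removed
                  c(0.96, 0.10),   # one above -> retained
                  c(0.99, 0.99))
  f <- suppressMessages(filter_by_detection(m, scores, 0.95))
  expect_equal(rownames(f$values), c("f02", "f03"))

  set.seed(5)
  big <- make_raw_matrix(matrix(runif(50 * 4, 100, 200), 50, 4))
  sc <- matrix(runif(50 * 4), 50, 4)
  fb <- suppressMessages(filter_by_detection(big, sc, 0.95))
  expect_setequal(rownames(fb$values),
                  rownames(big$values)[apply(sc > 0.95, 1, any)])
})

test_that("per-sample shift puts every minimum at exactly 1", {
  m <- make_raw_matrix(matrix(c(-50, 0, 100), 3, 1))
  mf <- expr_matrix(m$values, "filtered")   # background-subtracted negatives
  s <- shift_min_to_one(mf)
  expect_equal(as.vector(s$values), c(1, 51, 151))

  already <- make_raw_matrix(matrix(c(1, 5, 9), 3, 1))
  s2 <- shift_min_to_one(suppressMessages(filter_low_intensity(already, 0)))
  expect_identical(s2$values, already$values)

  set.seed(3)
  r <- make_raw_matrix(matrix(rnorm(40 * 6, 100, 80), 40, 6))
  s3 <- shift_min_to_one(suppressMessages(filter_low_intensity(r, 0)))
  expect_equal(unname(apply(s3$values, 2, min)), rep(1, 6))
})

test_that("log2 transform maps each sample minimum to 0 and inverts 2^x", {
  m <- make_raw_matrix(matrix(c(1, 8, 2^10), 3, 1))
  lg <- m |> filter_low_intensity(0) |> shift_min_to_one() |>
    log2_transform() |> suppressMessages()
  expect_equal(as.vector(lg$values), c(0, 3, 10))

  set.seed(9)
  x <- matrix(2^runif(30, 0, 12), 10, 3)
  m2 <- make_raw_matrix(pmax(x, 1))
  lg2 <- m2 |> filter_low_intensity(0) |> shift_min_to_one() |>
    log2_transform() |> suppressMessages()
  expect_equal(2^lg2$values, shift_min_to_one(
    suppressMessages(filter_low_intensity(m2, 0)))$values, tolerance = 1e-12)
})

test_that("quantile normalization matches the hand-computed reference", {
  # reference = mean of sorted columns: rank 1 -> (1+3)/2 = 2, rank 2 -> 3
  qn <- basalmir:::.quantile_normalize(cbind(c(1, 2), c(3, 4)))
  expect_equal(unname(qn), cbind(c(2, 3), c(2, 3)))

  # identical samples are a fixed point
  same <- cbind(c(5, 1, 3), c(5, 1, 3))
  expect_equal(basalmir:::.quantile_normalize(same), same)
})

test_that("quantile normalization equalizes distributions, keeps ranks, is idempotent", {
  set.seed(21)
  v <- matrix(rnorm(60 * 5, 8, 2), 60, 5)   # continuous draws: tie-free
  out <- basalmir:::.quantile_normalize(v)
  # all columns share one sorted vector
  sorted <- apply(out, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1)], tolerance = 1e-12)
  # within-sample order preserved
  for (k in 1:5) {
    expect_true(all(diff(out[order(v[, k]), k]) >= -1e-12))
  }
  # idempotent on its own output
  expect_equal(basalmir:::.quantile_normalize(out), out, tolerance = 1e-12)
  expect_equal(out, oracle_quantile_norm(v), tolerance = 1e-12)

  # with ties injected: tied values merge to one value, order still kept,
  # and the loop-based reference agrees exactly
  vt <- v
  vt[sample(300, 20)] <- vt[1]
  outt <- basalmir:::.quantile_normalize(vt)
  for (k in 1:5) {
    expect_true(all(diff(outt[order(vt[, k]), k]) >= -1e-12))
    tied <- which(vt[, k] == vt[1, 1])
    if (length(tied) > 1) expect_length(unique(outt[tied, k]), 1L)
  }
  expect_equal(outt, oracle_quantile_norm(vt), tolerance = 1e-12)
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(25)
  v <- matrix(rnorm(80 * 6, 8, 2), 80, 6)
  expect_equal(basalmir:::.quantile_normalize(v),
               unname(limma::normalizeQuantiles(v)), tolerance = 1e-10)
})

test_that("standardization is per run with the n-1 denominator", {
  vals <- rbind(feat = c(2, 4, 6))
  m <- matrix(vals, 1, 3, dimnames = list("feat", c("s1", "s2", "s3")))
  x <- expr_matrix(m, "quantile_normalized")
  ann <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                        group = "normal", run_id = "run1", chip_id = "chip1")
  z <- standardize_features(x, ann)
  expect_equal(as.vector(z$values), c(-1, 0, 1))  # mean 4, sample sd 2

  const <- expr_matrix(matrix(7, 2, 3, dimnames = list(c("a", "b"), ann$sample_id)),
                       "quantile_normalized")
  zc <- standardize_features(const, ann)
  expect_true(all(zc$values == 0))
  expect_equal(sort(attr(zc, "zero_variance")$feature_id), c("a", "b"))
})

test_that("standardized features have mean 0 and sd 1 within every run", {
  set.seed(31)
  n <- 12
  m <- matrix(rnorm(30 * n, 8, 3), 30, n,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:n)))
  ann <- tibble::tibble(sample_id = colnames(m), group = "normal",
                        run_id = rep(c("run1", "run2"), each = n / 2),
                        chip_id = rep(c("chip1", "chip2"), each = n / 2))
  z <- standardize_features(expr_matrix(m, "quantile_normalized"), ann)
  for (r in c("run1", "run2")) {
    sub <- z$values[, ann$run_id == r]
    expect_equal(unname(rowMeans(sub)), rep(0, 30), tolerance = 1e-12)
    expect_equal(unname(apply(sub, 1, sd)), rep(1, 30), tolerance = 1e-12)
  }
})

test_that("stage order is enforced", {
  m <- make_raw_matrix(matrix(c(200, 300), 1, 2))
  expect_error(shift_min_to_one(m), class = "basalmir_stage_error")
  expect_error(log2_transform(m), class = "basalmir_stage_error")
  f <- suppressMessages(filter_low_intensity(m, 0))
  expect_error(quantile_normalize(f), class = "basalmir_stage_error")
})

test_that("noise-free batch-free pipeline leaves non-differential features at zero", {
  sim <- sim_expression(n_features = 40, de_features = 0,
                        chip_effect_sd = 0, run_scale = 1, noise_sd = 0,
                        seed = 77)
  std <- suppressMessages(preprocess(sim$matrix, sim$annotations,
                                     intensity_threshold = 0))
  # without effects, batches or noise every feature is constant, so
  # per-run standardization zeroes (and flags) all of them
  expect_true(all(abs(std$values) < 1e-10))
  expect_equal(sort(unique(attr(std, "zero_variance")$feature_id)),
               sort(rownames(std$values)))
})
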