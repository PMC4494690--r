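#' Probe filtering by maximum intensity
#'
#' Excludes probes whose maximum intensity across all samples is below
#' `threshold` (strictly less than: a probe whose maximum equals the
#' threshold is retained). Probes carrying any missing value are also
#' excluded here — an absent measurement cannot contribute a maximum and
#' keeping it would leave holes in every later stage. Retained/total
#' counts are reported via a message.
#'
#' @param x Raw-stage [expr_matrix].
#' @param threshold Minimum acceptable per-probe maximum, default 150 raw
#'   intensity units.
#' @return Filtered-stage `expr_matrix`.
#' @export
filter_low_intensity <- function(x, threshold = 150) {
  stage <- advance_stage(x, "raw", "filtered", "filter_low_intensity")
  stopifnot(threshold >= 0)
  complete <- !apply(is.na(x$values), 1L, any)
  mx <- suppressWarnings(apply(x$values, 1L, max, na.rm = TRUE))
  keep <- complete & mx >= threshold
  if (!any(keep)) {
    abort("All features removed by the intensity filter.",
          class = "basalmir_filter_error")
  }
  inform(sprintf("Intensity filter: retained %d of %d features (threshold %g).",
                 sum(keep), nrow(x$values), threshold))
  with_values(x, x$values[keep, , drop = FALSE], stage)
}

#' Probe filtering by detection score
#'
#' For gene-expression matrices accompanied by per-probe detection scores:
#' a probe is retained if *any* sample's detection score is strictly
#' greater than `threshold` (default 0.95). Probes with missing values are
#' excluded as in [filter_low_intensity()].
#'
#' @param x Raw-stage [expr_matrix].
#' @param detection_scores Numeric matrix, same dimensions and dimnames as
#'   `x`, of detection scores in `[0, 1]`.
#' @param threshold Strict lower bound, default 0.95.
#' @return Filtered-stage `expr_matrix`.
#' @export
filter_by_detection <- function(x, detection_scores, threshold = 0.95) {
  stage <- advance_stage(x, "raw", "filtered", "filter_by_detection")
  if (!identical(dim(detection_scores), dim(x$values))) {
    abort("detection_scores must match the matrix dimensions.",
          class = "basalmir_validation_error")
  }
  complete <- !apply(is.na(x$values), 1L, any)
  keep <- complete & apply(detection_scores > threshold, 1L, any)
  if (!any(keep)) {
    abort("All features removed by the detection filter.",
          class = "basalmir_filter_error")
  }
  inform(sprintf("Detection filter: retained %d of %d features (score > %g).",
                 sum(keep), nrow(x$values), threshold))
  with_values(x, x$values[keep, , drop = FALSE], stage)
}

#' Shift each sample so its minimum intensity is 1
#'
#' Adds, per sample, the constant `1 - min(sample)`, so that every
#' sample's minimum becomes exactly 1. This makes the subsequent log2
#' transform total even when background subtraction produced negative
#' intensities. A sample already at minimum 1 is unchanged.
#'
#' @param x Filtered-stage [expr_matrix].
#' @return Shifted-stage `expr_matrix`.
#' @export
shift_min_to_one <- function(x) {
  stage <- advance_stage(x, "filtered", "shifted", "shift_min_to_one")
  mins <- apply(x$values, 2L, min)
  shifted <- sweep(x$values, 2L, 1 - mins, `+`)
  with_values(x, shifted, stage)
}

#' Log2 transform
#'
#' Elementwise log2. Requires all values to be at least 1 (guaranteed by
#' [shift_min_to_one()]), so each sample's minimum maps to 0.
#'
#' @param x Shifted-stage [expr_matrix].
#' @return Log2-stage `expr_matrix`.
#' @export
log2_transform <- function(x) {
  stage <- advance_stage(x, "shifted", "log2", "log2_transform")
  if (any(x$values < 1)) {
    abort("log2_transform requires all values >= 1; run shift_min_to_one first.",
          class = "basalmir_validation_error")
  }
  with_values(x, log2(x$values), stage)
}

#' Quantile normalization
#'
#' Forces every sample to share one empirical distribution: the reference
#' is the mean of the per-sample sorted value vectors, and each value is
#' replaced by the reference value at its within-sample rank. Ties within
#' a sample receive the mean of the reference values spanning their rank
#' range, so tied values stay tied and within-sample rank order is
#' preserved. After normalization all samples have identical sorted
#' vectors, making the operation idempotent.
#'
#' @param x Log2-stage [expr_matrix].
#' @return Quantile-normalized-stage `expr_matrix`.
#' @export
quantile_normalize <- function(x) {
  stage <- advance_stage(x, "log2", "quantile_normalized", "quantile_normalize")
  with_values(x, .quantile_normalize(x$values), stage)
}

# mean-of-sorted-columns reference; ties get the mean reference value over
# their rank span
.quantile_normalize <- function(values) {
  ref <- rowMeans(apply(values, 2L, sort))
  cum <- cumsum(ref)
  out <- apply(values, 2L, function(v) {
    lo <- rank(v, ties.method = "min")
    hi <- rank(v, ties.method = "max")
    (cum[hi] - c(0, cum)[lo]) / (hi - lo + 1)
  })
  dimnames(out) <- dimnames(values)
  out
}

#' Per-feature standardization, separately within each run
#'
#' Standardizes each feature to mean 0 and standard deviation 1 (sample
#' SD, n-1 denominator). Because probe intensities differ systematically
#' between hybridization runs, standardization is performed separately
#' within each run by default (`within = "run"`); `within = "all"` uses
#' the whole cohort. A feature with zero variance within a run is set to 0
#' there and recorded in the `zero_variance` attribute rather than
#' dropped, so feature sets stay aligned across runs.
#'
#' @param x Quantile-normalized-stage [expr_matrix].
#' @param annotations Sample annotation tibble (needed for run membership).
#' @param within `"run"` (default) or `"all"`.
#' @return Standardized-stage `expr_matrix` with attribute
#'   `zero_variance`: tibble of (feature_id, run_id) flagged.
#' @export
standardize_features <- function(x, annotations, within = c("run", "all")) {
  stage <- advance_stage(x, "quantile_normalized", "standardized",
                         "standardize_features")
  within <- match.arg(within)
  ann <- annotations[match(colnames(x$values), annotations$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) {
    abort("Every sample in the matrix needs an annotation row.",
          class = "basalmir_validation_error")
  }
  grp <- if (within == "run") ann$run_id else rep("all", ncol(x$values))
  out <- x$values
  flagged <- list()
  for (g in unique(grp)) {
    cols <- which(grp == g)
    sub <- x$values[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    s <- apply(sub, 1L, sd)
    zv <- s == 0 | is.na(s)
    s[zv] <- 1
    out[, cols] <- (sub - mu) / s
    out[zv, cols] <- 0
    if (any(zv)) {
      flagged[[g]] <- tibble(feature_id = rownames(sub)[zv], run_id = g)
    }
  }
  res <- with_values(x, out, stage)
  attr(res, "zero_variance") <- if (length(flagged)) dplyr::bind_rows(flagged) else
    tibble(feature_id = character(), run_id = character())
  res
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: intensity filter, per-sample shift to minimum 1,
#' log2 transform, quantile normalization, and (when annotations are
#' supplied) per-run feature standardization.
#'
#' @param x Raw-stage [expr_matrix].
#' @param annotations Sample annotations; if `NULL`, the chain stops at
#'   quantile normalization.
#' @param intensity_threshold Passed to [filter_low_intensity()].
#' @param standardize_within Passed to [standardize_features()].
#' @return An `expr_matrix` at the final stage reached.
#' @export
preprocess <- function(x, annotations = NULL, intensity_threshold = 150,
                       standardize_within = "run") {
  out <- x |>
    filter_low_intensity(intensity_threshold) |>
    shift_min_to_one() |>
    log2_transform() |>
    quantile_normalize()
  if (!is.null(annotations)) {
    out <- standardize_features(out, annotations, within = standardize_within)
  }
  out
}
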