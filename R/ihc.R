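#' Composite immunohistochemistry score
#'
#' Staining intensity (0-3) plus the stained-proportion category (0-4),
#' summed to a 0-7 composite.
#'
#' @param intensity Integer vector in 0-3.
#' @param percent_category Integer vector in 0-4.
#' @return Integer vector of composite scores.
#' @export
composite_score <- function(intensity, percent_category) {
  if (any(intensity < 0L | intensity > 3L, na.rm = TRUE)) {
    abort("intensity must lie in 0-3.", class = "basalmir_validation_error")
  }
  if (any(percent_category < 0L | percent_category > 4L, na.rm = TRUE)) {
    abort("percent_category must lie in 0-4.", class = "basalmir_validation_error")
  }
  as.integer(intensity + percent_category)
}

#' Staining positivity
#'
#' A core is positive when any staining is present: intensity >= 1 with a
#' stained proportion >= 1 (equivalently, composite score >= 2 under the
#' ingestion invariant that the two components are zero together).
#'
#' @param intensity,percent_category Score components as in
#'   [composite_score()].
#' @return Logical vector.
#' @export
ihc_positive <- function(intensity, percent_category) {
  intensity >= 1L & percent_category >= 1L
}

#' Pearson chi-square test on a 2x2 table
#'
#' df = 1, no continuity correction (matching how the published cohort
#' comparisons were computed). All four margins must be positive.
#'
#' @param a,b,c,d Cell counts: rows are groups, columns
#'   positive/negative, i.e. `rbind(c(a, b), c(c, d))`.
#' @return List with `statistic` and `p_value`.
#' @export
chisq_2x2 <- function(a, b, c, d) {
  m <- rbind(c(a, b), c(c, d))
  if (any(m < 0) || any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("chisq_2x2 requires non-negative counts with positive margins.",
          class = "basalmir_validation_error")
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Mann-Whitney U test on composite scores
#'
#' Two-sided. The exact U distribution is used when both groups have at
#' most 8 observations and there are no ties; otherwise the normal
#' approximation with tie correction (and no continuity correction) is
#' used, matching common statistical-package defaults for scored data.
#'
#' @param scores_a,scores_b Numeric vectors (composite 0-7 scores).
#' @return List with `u` and `p_value`.
#' @export
mann_whitney <- function(scores_a, scores_b) {
  ties <- anyDuplicated(c(scores_a, scores_b)) > 0L
  exact <- length(scores_a) <= 8L && length(scores_b) <= 8L && !ties
  res <- suppressWarnings(
    wilcox.test(scores_a, scores_b, exact = exact, correct = FALSE)
  )
  list(u = unname(res$statistic), p_value = res$p.value)
}

#' Compare one marker between truth groups
#'
#' Builds, from the evaluable records of one marker (optionally one
#' cohort), the 2x2 positivity table (group x positive/negative), runs the
#' Pearson chi-square on presence/absence and the Mann-Whitney U on the
#' 0-7 composite scores, and reports per-group positive counts and
#' percentages.
#'
#' @param records IHC record tibble (see [read_ihc_table()]).
#' @param marker Marker id to compare.
#' @param cohort Optional cohort filter (`"initial"`/`"validation"`).
#' @return One-row tibble: marker, per-group n / n positive / percent
#'   positive, chi-square statistic and p, U and p.
#' @export
compare_marker <- function(records, marker, cohort = NULL) {
  r <- records[records$marker == marker & records$evaluable, , drop = FALSE]
  if (!is.null(cohort)) r <- r[r$cohort == cohort, , drop = FALSE]
  if (nrow(r) == 0L) {
    abort(sprintf("No evaluable records for marker '%s'.", marker),
          class = "basalmir_validation_error")
  }
  if (length(unique(r$truth_group)) < 2L) {
    abort(sprintf("Marker '%s' needs evaluable cases in both groups.", marker),
          class = "basalmir_validation_error")
  }
  pos <- ihc_positive(r$intensity, r$percent_category)
  br <- r$truth_group == "brca1"
  chi <- chisq_2x2(sum(br & pos), sum(br & !pos),
                   sum(!br & pos), sum(!br & !pos))
  score <- composite_score(r$intensity, r$percent_category)
  mw <- mann_whitney(score[br], score[!br])
  tibble(
    marker = marker,
    n_brca1 = sum(br), pos_brca1 = sum(br & pos),
    pct_brca1 = 100 * sum(br & pos) / sum(br),
    n_sporadic = sum(!br), pos_sporadic = sum(!br & pos),
    pct_sporadic = 100 * sum(!br & pos) / sum(!br),
    chi2_statistic = chi$statistic, p_chi2 = chi$p_value,
    mannwhitney_u = mw$u, p_mw = mw$p_value
  )
}

#' @rdname compare_marker
#' @export
compare_markers <- function(records, cohort = NULL) {
  dplyr::bind_rows(lapply(sort(unique(records$marker)),
                          function(m) compare_marker(records, m, cohort)))
}

#' k-of-n negative-marker classifier
#'
#' Predicts germline BRCA1 mutation when at least `k` of the rule markers
#' stain negative (default: 2 or more of FOXP1, cyclin D1, NRP1). Cases
#' with any rule marker non-evaluable cannot be scored and are excluded
#' (reported via message and the `n_excluded` attribute), not imputed.
#'
#' @param records IHC record tibble.
#' @param markers Rule markers, default `c("FOXP1", "CCND1", "NRP1")`.
#' @param k Negatives required, default 2.
#' @param cohort Optional cohort filter.
#' @return Tibble: `case_id`, `truth_group`, `n_negative`, `predicted`
#'   (`"brca1"`/`"sporadic"`), with attribute `n_excluded`.
#' @export
panel_classify <- function(records, markers = c("FOXP1", "CCND1", "NRP1"),
                           k = 2L, cohort = NULL) {
  stopifnot(k >= 1L, k <= length(markers))
  r <- records[records$marker %in% markers, , drop = FALSE]
  if (!is.null(cohort)) r <- r[r$cohort == cohort, , drop = FALSE]
  missing_markers <- setdiff(markers, unique(r$marker))
  if (length(missing_markers)) {
    abort(sprintf("Rule marker(s) absent from records: %s.",
                  paste(missing_markers, collapse = ", ")),
          class = "basalmir_validation_error")
  }
  per_case <- r |>
    dplyr::group_by(.data$case_id, .data$truth_group) |>
    dplyr::summarise(
      complete = sum(.data$evaluable) == length(markers),
      n_negative = sum(!ihc_positive(.data$intensity, .data$percent_category) &
                         .data$evaluable),
      .groups = "drop"
    )
  n_excluded <- sum(!per_case$complete)
  if (n_excluded > 0L) {
    inform(sprintf("Excluded %d case(s) with non-evaluable rule markers.",
                   n_excluded))
  }
  out <- per_case[per_case$complete, c("case_id", "truth_group", "n_negative")]
  out$predicted <- ifelse(out$n_negative >= k, "brca1", "sporadic")
  structure(out, n_excluded = n_excluded, markers = markers, k = k)
}

#' Evaluate panel predictions against truth
#'
#' Confusion counts with BRCA1 as the positive class, sensitivity,
#' specificity, and the predictive values at the cohort's own prevalence.
#'
#' @param predictions Tibble from [panel_classify()] (columns
#'   `truth_group`, `predicted`).
#' @return Object of class `basalmir_panel` (a list): `confusion`
#'   (tp/fp/tn/fn), `sensitivity`, `specificity`, `cohort_ppv`,
#'   `cohort_npv`, `n`. Supports [tidy()], [glance()], [autoplot()].
#' @export
evaluate_panel <- function(predictions) {
  tp <- sum(predictions$predicted == "brca1" & predictions$truth_group == "brca1")
  fp <- sum(predictions$predicted == "brca1" & predictions$truth_group == "sporadic")
  tn <- sum(predictions$predicted == "sporadic" & predictions$truth_group == "sporadic")
  fn <- sum(predictions$predicted == "sporadic" & predictions$truth_group == "brca1")
  structure(list(
    confusion = tibble(tp = tp, fp = fp, tn = tn, fn = fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    cohort_ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    cohort_npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    n = nrow(predictions),
    markers = attr(predictions, "markers"),
    k = attr(predictions, "k")
  ), class = "basalmir_panel")
}

#' Prevalence-adjusted predictive values
#'
#' Re-expresses a test's predictive values at the disease prevalence of a
#' target population instead of the study cohort. The prevalence of BRCA1
#' mutation among *basal-like* cancers is derived from three assumptions
#' by Bayes' rule:
#' `prev = p_mutation * p_basal_given_mutation / p_basal`
#' (defaults 0.02 * 0.69 / 0.15 = 0.092), then
#' `PPV = sens*prev / (sens*prev + (1-spec)(1-prev))` and
#' `NPV = spec*(1-prev) / (spec*(1-prev) + (1-sens)*prev)`.
#'
#' @param sensitivity,specificity Test operating characteristics in `[0,1]`.
#' @param p_mutation Prevalence of BRCA1 mutation among breast cancers,
#'   default 0.02.
#' @param p_basal Fraction of breast cancers with a basal phenotype,
#'   default 0.15.
#' @param p_basal_given_mutation Fraction of BRCA1 cancers that are basal,
#'   default 0.69.
#' @return One-row tibble: `derived_prevalence`, `adjusted_ppv`,
#'   `adjusted_npv`.
#' @export
prevalence_adjusted_pv <- function(sensitivity, specificity,
                                   p_mutation = 0.02, p_basal = 0.15,
                                   p_basal_given_mutation = 0.69) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  prev <- p_mutation * p_basal_given_mutation / p_basal
  if (!is.finite(prev) || prev <= 0 || prev >= 1) {
    abort(sprintf("Derived prevalence %.4g lies outside (0, 1); check assumptions.",
                  prev),
          class = "basalmir_assumption_error")
  }
  ppv <- sensitivity * prev / (sensitivity * prev + (1 - specificity) * (1 - prev))
  npv <- specificity * (1 - prev) /
    (specificity * (1 - prev) + (1 - sensitivity) * prev)
  tibble(derived_prevalence = prev, adjusted_ppv = ppv, adjusted_npv = npv)
}

#' Full IHC panel analysis
#'
#' Classifies every fully evaluable case with the k-of-n negative-marker
#' rule, evaluates the confusion against the truth labels, and attaches
#' the prevalence-adjusted predictive values. Cohort-based and
#' prevalence-adjusted predictive values are always reported side by
#' side.
#'
#' @inheritParams panel_classify
#' @inheritParams prevalence_adjusted_pv
#' @return A `basalmir_panel` object (see [evaluate_panel()]) with the
#'   adjusted predictive values and assumptions added.
#' @examples
#' sim <- sim_ihc_cohort(seed = 7)
#' res <- ihc_panel(sim$records)
#' glance(res)
#' @export
ihc_panel <- function(records, markers = c("FOXP1", "CCND1", "NRP1"),
                      k = 2L, cohort = NULL, p_mutation = 0.02,
                      p_basal = 0.15, p_basal_given_mutation = 0.69) {
  pred <- panel_classify(records, markers = markers, k = k, cohort = cohort)
  res <- evaluate_panel(pred)
  adj <- prevalence_adjusted_pv(res$sensitivity, res$specificity,
                                p_mutation, p_basal, p_basal_given_mutation)
  res$derived_prevalence <- adj$derived_prevalence
  res$adjusted_ppv <- adj$adjusted_ppv
  res$adjusted_npv <- adj$adjusted_npv
  res$assumptions <- tibble(p_mutation = p_mutation, p_basal = p_basal,
                            p_basal_given_mutation = p_basal_given_mutation)
  res$n_excluded <- attr(pred, "n_excluded")
  res
}

#' @export
print.basalmir_panel <- function(x, ...) {
  cat(sprintf("<basalmir_panel> %d-of-%d negative-marker rule (%s), n = %d\n",
              x$k %||% NA, length(x$markers %||% character()),
              paste(x$markers %||% "?", collapse = ", "), x$n))
  cat(sprintf("  sensitivity %.3f  specificity %.3f\n",
              x$sensitivity, x$specificity))
  cat(sprintf("  cohort PPV %.3f  cohort NPV %.3f\n", x$cohort_ppv, x$cohort_npv))
  if (!is.null(x$adjusted_ppv)) {
    cat(sprintf("  adjusted PPV %.3f  adjusted NPV %.3f (prevalence %.3f)\n",
                x$adjusted_ppv, x$adjusted_npv, x$derived_prevalence))
  }
  invisible(x)
}

#' @export
tidy.basalmir_panel <- function(x, ...) {
  rates <- tibble(
    metric = c("sensitivity", "specificity", "cohort_ppv", "cohort_npv",
               if (!is.null(x$adjusted_ppv)) c("adjusted_ppv", "adjusted_npv")),
    estimate = c(x$sensitivity, x$specificity, x$cohort_ppv, x$cohort_npv,
                 if (!is.null(x$adjusted_ppv)) c(x$adjusted_ppv, x$adjusted_npv))
  )
  rates
}

#' @export
glance.basalmir_panel <- function(x, ...) {
  dplyr::bind_cols(x$confusion, tibble(
    n = x$n, sensitivity = x$sensitivity, specificity = x$specificity,
    cohort_ppv = x$cohort_ppv, cohort_npv = x$cohort_npv,
    adjusted_ppv = x$adjusted_ppv %||% NA_real_,
    adjusted_npv = x$adjusted_npv %||% NA_real_,
    derived_prevalence = x$derived_prevalence %||% NA_real_
  ))
}

#' @export
autoplot.basalmir_panel <- function(object, ...) {
  d <- tidy(object)
  d$metric <- factor(d$metric, levels = d$metric)
  ggplot(d, aes(x = .data$metric, y = .data$estimate)) +
    geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    labs(x = NULL, y = "estimate",
         title = sprintf("%d-of-%d negative-marker panel",
                         object$k %||% NA, length(object$markers %||% character()))) +
    theme_minimal()
}
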