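#' Per-feature ANOVA with the chip as a batch covariate
#'
#' Fits, for every feature, the two-way fixed-effects linear model
#' `log2 expression ~ group + chip` (no interaction) on the samples whose
#' group is in `groups`, and tests the group factor with a partial F test
#' (full model vs. chip-only model). Chip levels that are aliased in the
#' design (e.g. a chip entirely absent from the selected samples) are
#' dropped automatically; if the *group* factor itself is confounded with
#' chip, the fit refuses with an error naming the confounded levels, since
#' no within-chip information about the group effect exists.
#'
#' Features with zero residual variance *and* zero group effect have an
#' undefined F ratio; they are flagged and assigned p = 1 rather than
#' propagating NaN.
#'
#' @param x Quantile-normalized [expr_matrix] (log2 scale).
#' @param annotations Sample annotation tibble.
#' @param groups Group levels to compare: either a character vector of
#'   group labels (each its own level) or a named list whose elements are
#'   sets of group labels pooled into one level (e.g.
#'   `list(basal = c("basal_sporadic", "basal_brca1"), luminal = "luminal")`).
#'   Each level needs >= 2 samples.
#' @param covariate `"chip"` to adjust for the BeadChip (default), or
#'   `"none"` for the unadjusted one-way model.
#' @return Tibble: `feature_id`, `f_statistic`, `p_raw`, `flagged`.
#' @export
fit_group_model <- function(x, annotations, groups,
                            covariate = c("chip", "none")) {
  advance_stage(x, c("quantile_normalized", "standardized"),
                x$stage, "fit_group_model")
  covariate <- match.arg(covariate)
  lv <- as_level_map(groups)
  ann <- annotations[match(colnames(x$values), annotations$sample_id), , drop = FALSE]
  gl <- level_of(ann$group, lv)
  keep <- !is.na(gl)
  ann <- ann[keep, , drop = FALSE]
  y <- x$values[, keep, drop = FALSE]

  g <- factor(gl[keep], levels = names(lv)[names(lv) %in% gl[keep]])
  if (nlevels(g) < 2L) {
    abort("Need at least two group levels with samples.",
          class = "basalmir_validation_error")
  }
  if (any(table(g) < 2L)) {
    abort(sprintf("Each group needs >= 2 samples (got: %s).",
                  paste(sprintf("%s=%d", names(table(g)), table(g)), collapse = ", ")),
          class = "basalmir_validation_error")
  }

  x1 <- stats::model.matrix(~g)
  if (covariate == "chip") {
    ch <- factor(ann$chip_id)
    if (nlevels(ch) > 1L) {
      xc <- stats::model.matrix(~ch)[, -1L, drop = FALSE]
      xf <- cbind(x1, xc)
      q <- qr(xf)
      if (q$rank < ncol(xf)) {
        dropped <- q$pivot[-seq_len(q$rank)]
        if (any(dropped <= ncol(x1))) {
          confounded <- colnames(xf)[dropped[dropped <= ncol(x1)]]
          abort(sprintf("Group levels confounded with chip: %s.",
                        paste(confounded, collapse = ", ")),
                class = "basalmir_model_error")
        }
        xf <- xf[, -dropped, drop = FALSE]
      }
      x1 <- xf
      x0 <- cbind(1, xc)
      q0 <- qr(x0)
      if (q0$rank < ncol(x0)) {
        x0 <- x0[, q0$pivot[seq_len(q0$rank)], drop = FALSE]
      }
    } else {
      x0 <- matrix(1, nrow(ann), 1L)
    }
  } else {
    x0 <- matrix(1, nrow(ann), 1L)
  }

  df1 <- qr(x1)$rank - qr(x0)$rank
  if (df1 < nlevels(g) - 1L) {
    abort(sprintf("Group factor (levels %s) confounded with chip: the chip-adjusted design leaves %d group degree(s) of freedom.",
                  paste(levels(g), collapse = ", "), df1),
          class = "basalmir_model_error")
  }
  rss <- function(X) {
    fit <- stats::lm.fit(X, t(y))
    res <- as.matrix(fit$residuals)
    colSums(res^2)
  }
  rss1 <- rss(x1)
  rss0 <- rss(x0)
  df2 <- ncol(y) - qr(x1)$rank
  if (df2 < 1L) {
    abort("No residual degrees of freedom in the group+chip model.",
          class = "basalmir_model_error")
  }
  tol <- 1e-10 * max(1, mean(abs(y)))^2
  flagged <- rss1 < tol & (rss0 - rss1) < tol
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  f[flagged] <- NA_real_
  p[flagged] <- 1
  tibble(feature_id = rownames(y), f_statistic = unname(f),
         p_raw = unname(p), flagged = unname(flagged))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values, clipped at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Signed fold change between two groups
#'
#' Anti-logs the difference of group means computed on the
#' quantile-normalized log2 scale: `r = 2^(mean_A - mean_B)`. The signed
#' convention mirrors magnitude-with-direction reporting:
#' `fold_change = r` when `r >= 1`, else `-1/r`, so swapping the contrast
#' negates the value and `|fold_change| >= 1` always.
#'
#' @param x Quantile-normalized [expr_matrix].
#' @param annotations Sample annotations.
#' @param contrast Pair `c(A, B)` of group labels, or a named 2-element
#'   list pooling several labels per side (see [fit_group_model()]).
#' @return Tibble: `feature_id`, `fold_change`, `direction`
#'   (`"up_in_A"` / `"down_in_A"`).
#' @export
fold_change <- function(x, annotations, contrast) {
  lv <- as_level_map(contrast)
  stopifnot(length(lv) == 2L)
  ann <- annotations[match(colnames(x$values), annotations$sample_id), , drop = FALSE]
  a <- ann$group %in% lv[[1L]]
  b <- ann$group %in% lv[[2L]]
  if (!any(a) || !any(b)) {
    abort("Both contrast groups need samples in the matrix.",
          class = "basalmir_validation_error")
  }
  delta <- rowMeans(x$values[, a, drop = FALSE]) -
    rowMeans(x$values[, b, drop = FALSE])
  r <- 2^delta
  fc <- ifelse(r >= 1, r, -1 / r)
  tibble(feature_id = rownames(x$values), fold_change = unname(fc),
         direction = unname(ifelse(delta >= 0, "up_in_A", "down_in_A")))
}

#' Differential expression for one contrast
#'
#' Combines the batch-adjusted ANOVA ([fit_group_model()]),
#' Benjamini-Hochberg adjustment ([adjust_bh()]), and signed fold changes
#' ([fold_change()]) into one result table per contrast.
#'
#' @inheritParams fit_group_model
#' @param contrast Character pair `c(A, B)`.
#' @return A tibble of class `basalmir_de`: `feature_id`, `fold_change`,
#'   `direction`, `f_statistic`, `p_raw`, `p_adjusted`, `flagged`; the
#'   contrast is stored as an attribute. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' sim <- sim_expression(n_features = 60, de_features = 8, seed = 42)
#' qn <- preprocess(sim$matrix)
#' de <- diff_expr(qn, sim$annotations, c("basal_brca1", "basal_sporadic"))
#' glance(de)
#' @export
diff_expr <- function(x, annotations, contrast,
                      covariate = c("chip", "none")) {
  lv <- as_level_map(contrast)
  fit <- fit_group_model(x, annotations, groups = lv,
                         covariate = match.arg(covariate))
  fc <- fold_change(x, annotations, lv)
  out <- dplyr::left_join(fc, fit, by = "feature_id")
  out$p_adjusted <- adjust_bh(out$p_raw)
  out <- out[, c("feature_id", "fold_change", "direction", "f_statistic",
                 "p_raw", "p_adjusted", "flagged")]
  out <- dplyr::arrange(out, .data$p_adjusted, dplyr::desc(abs(.data$fold_change)),
                        .data$feature_id)
  structure(out, contrast = names(lv),
            class = c("basalmir_de", class(out)))
}

# normalize a group specification: a character vector becomes one level
# per label; a named list pools its element's labels into one level
as_level_map <- function(groups) {
  if (is.list(groups)) {
    if (is.null(names(groups)) || any(names(groups) == "")) {
      names(groups) <- vapply(groups, paste, "", collapse = "+")
    }
    groups
  } else {
    as.list(setNames(groups, groups))
  }
}

level_of <- function(group, lv) {
  out <- rep(NA_character_, length(group))
  for (nm in names(lv)) out[group %in% lv[[nm]]] <- nm
  out
}

#' @export
tidy.basalmir_de <- function(x, ...) {
  as_tibble(unclass_de(x))
}

#' @export
glance.basalmir_de <- function(x, fc_threshold = 2.5, q_threshold = 0.05, ...) {
  tibble(
    contrast = paste(attr(x, "contrast"), collapse = "_vs_"),
    n_features = nrow(x),
    n_significant = sum(x$p_adjusted < q_threshold, na.rm = TRUE),
    n_reportable = sum(x$p_adjusted < q_threshold &
                         abs(x$fold_change) > fc_threshold, na.rm = TRUE)
  )
}

#' @export
autoplot.basalmir_de <- function(object, q_threshold = 0.05,
                                 fc_threshold = 2.5, ...) {
  d <- tidy(object)
  d$log2fc <- sign(d$fold_change) * log2(abs(d$fold_change))
  d$status <- ifelse(d$p_adjusted < q_threshold &
                       abs(d$fold_change) > fc_threshold, "reportable",
                     ifelse(d$p_adjusted < q_threshold, "significant", "ns"))
  ggplot(d, aes(x = .data$log2fc, y = -log10(.data$p_adjusted),
                colour = .data$status)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = -log10(q_threshold), linetype = 2) +
    geom_vline(xintercept = c(-log2(fc_threshold), log2(fc_threshold)),
               linetype = 3) +
    scale_colour_manual(values = c(ns = "grey60", significant = "steelblue",
                                   reportable = "firebrick")) +
    labs(x = "signed log2 fold change", y = "-log10 adjusted p",
         title = paste(attr(object, "contrast"), collapse = " vs ")) +
    theme_minimal()
}

unclass_de <- function(x) {
  class(x) <- setdiff(class(x), "basalmir_de")
  attr(x, "contrast") <- NULL
  x
}

#' Select a clustering signature as the union of top-ranked features
#'
#' Takes the top `n` features of each contrast ranked by absolute fold
#' change (ties broken by feature id ascending, so the set is invariant to
#' input permutation) and returns their deduplicated union, sorted by the
#' maximum absolute fold change across contrasts (descending, feature id
#' ascending). Defaults follow the headline signature: top 75 for basal
#' vs. luminal plus top 100 for BRCA1 vs. sporadic basal.
#'
#' @param ... One or more `basalmir_de` (or compatible) tibbles.
#' @param top_n Integer vector recycled across the inputs; defaults
#'   `c(75, 100)` when two tables are given, else 75.
#' @return Tibble: `feature_id`, `abs_fold_change` (max across contrasts).
#' @export
select_signature <- function(..., top_n = NULL) {
  des <- list(...)
  if (length(des) == 1L && is.list(des[[1L]]) && !is.data.frame(des[[1L]])) {
    des <- des[[1L]]
  }
  if (is.null(top_n)) top_n <- if (length(des) == 2L) c(75L, 100L) else 75L
  top_n <- rep_len(top_n, length(des))
  picked <- purrr::map2(des, top_n, function(de, n) {
    d <- dplyr::arrange(as_tibble(de), dplyr::desc(abs(.data$fold_change)),
                        .data$feature_id)
    head(d[, c("feature_id", "fold_change")], n)
  })
  dplyr::bind_rows(picked) |>
    dplyr::mutate(abs_fold_change = abs(.data$fold_change)) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(abs_fold_change = max(.data$abs_fold_change),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$abs_fold_change), .data$feature_id)
}
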