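#' Union of target-prediction tables
#'
#' Combines per-source (miRNA, gene) prediction edges into one
#' deduplicated pair set; a pair is kept when at least one source predicts
#' it, and per-pair provenance is retained as the sorted set of sources.
#' Idempotent: feeding the same table twice changes nothing.
#'
#' @param ... Target-pair tibbles (columns `mirna_id`, `gene_id`,
#'   `source`), or a single list of them.
#' @return Tibble: `mirna_id`, `gene_id`, `sources` (collapsed `;`-string),
#'   `n_sources`.
#' @export
union_targets <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) && !is.data.frame(tabs[[1L]])) {
    tabs <- tabs[[1L]]
  }
  dplyr::bind_rows(tabs) |>
    dplyr::distinct(.data$mirna_id, .data$gene_id, .data$source) |>
    dplyr::group_by(.data$mirna_id, .data$gene_id) |>
    dplyr::summarise(sources = paste(sort(unique(.data$source)), collapse = ";"),
                     n_sources = dplyr::n_distinct(.data$source),
                     .groups = "drop") |>
    dplyr::arrange(.data$mirna_id, .data$gene_id)
}

#' Consensus target genes supported by >= 3 differential miRNAs
#'
#' A predicted target gene is retained only when at least `min_support`
#' *distinct* differentially expressed miRNAs target it, counted
#' separately within each miRNA direction: targets of up-regulated miRNAs
#' form the predicted protein *down* list and vice versa (a miRNA
#' suppresses its targets). A gene reaching the support threshold in both
#' directions appears in both lists with `in_both_lists = TRUE` rather
#' than being resolved arbitrarily.
#'
#' @param pairs Pair set from [union_targets()] (or any tibble with
#'   `mirna_id`, `gene_id`).
#' @param de_mirnas Tibble with `mirna_id` and `direction`
#'   (`"up_in_A"`/`"down_in_A"`), e.g. the significant rows of a
#'   [diff_expr()] result renamed.
#' @param min_support Minimum distinct supporting miRNAs, default 3.
#' @return Tibble of class `basalmir_consensus`: `gene_id`,
#'   `predicted_protein_direction`, `support`, `supporting_mirnas`
#'   (`;`-collapsed), `in_both_lists`.
#' @export
consensus_genes <- function(pairs, de_mirnas, min_support = 3L) {
  if (nrow(de_mirnas) == 0L) {
    abort("de_mirnas must be nonempty.", class = "basalmir_validation_error")
  }
  stopifnot(min_support >= 1L)
  joined <- dplyr::inner_join(
    dplyr::distinct(pairs[, c("mirna_id", "gene_id")]),
    dplyr::distinct(de_mirnas[, c("mirna_id", "direction")]),
    by = "mirna_id"
  )
  per_dir <- joined |>
    dplyr::group_by(.data$gene_id, .data$direction) |>
    dplyr::summarise(support = dplyr::n_distinct(.data$mirna_id),
                     supporting_mirnas = paste(sort(unique(.data$mirna_id)),
                                               collapse = ";"),
                     .groups = "drop") |>
    dplyr::filter(.data$support >= min_support)
  per_dir$predicted_protein_direction <-
    ifelse(per_dir$direction == "up_in_A", "down_in_A", "up_in_A")
  both <- per_dir |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n > 1L)
  per_dir$in_both_lists <- per_dir$gene_id %in% both$gene_id
  out <- per_dir[, c("gene_id", "predicted_protein_direction", "support",
                     "supporting_mirnas", "in_both_lists")] |>
    dplyr::arrange(.data$gene_id, .data$predicted_protein_direction)
  structure(out, min_support = min_support,
            class = c("basalmir_consensus", class(out)))
}

#' Flag consensus genes regulated by RISC-mediated cleavage
#'
#' Cross-matches consensus targets against a gene-level mRNA differential
#' expression table. Because cleavage degrades the message, the mRNA must
#' itself be differentially expressed (`p_adjusted < q_threshold`) and —
#' by default — shifted *opposite* to its supporting miRNAs (i.e. in the
#' gene's predicted protein direction); targets silenced only
#' translationally show no mRNA change and stay unflagged.
#'
#' @param consensus Result of [consensus_genes()].
#' @param mrna_de Gene-level DE tibble with `feature_id` (gene id),
#'   `direction`, `p_adjusted` (e.g. a [diff_expr()] result on the mRNA
#'   matrix).
#' @param q_threshold BH-adjusted significance cutoff, default 0.05.
#' @param require_opposite_mrna_direction Require the mRNA shift to match
#'   the predicted protein direction (default `TRUE`).
#' @return `consensus` with an added logical `cleavage_flag` column.
#' @export
cleavage_subset <- function(consensus, mrna_de, q_threshold = 0.05,
                            require_opposite_mrna_direction = TRUE) {
  de <- tibble(gene_id = mrna_de$feature_id,
               mrna_direction = mrna_de$direction,
               mrna_q = mrna_de$p_adjusted)
  out <- dplyr::left_join(as_tibble(consensus), de, by = "gene_id")
  sig <- !is.na(out$mrna_q) & out$mrna_q < q_threshold
  if (require_opposite_mrna_direction) {
    sig <- sig & out$mrna_direction == out$predicted_protein_direction
  }
  out$cleavage_flag <- sig
  out$mrna_direction <- NULL
  out$mrna_q <- NULL
  structure(out, min_support = attr(consensus, "min_support"),
            class = c("basalmir_consensus", class(out)))
}

#' Overlap statistics between the predicted-up and predicted-down lists
#'
#' `n_total` counts list memberships (a gene in both lists counts twice,
#' matching how union searches report totals), so
#' `overlap_fraction = n_overlap / n_total`.
#'
#' @param consensus Result of [consensus_genes()].
#' @return One-row tibble: `n_total`, `n_up`, `n_down`, `n_overlap`,
#'   `overlap_fraction`.
#' @export
overlap_stats <- function(consensus) {
  up <- unique(consensus$gene_id[consensus$predicted_protein_direction == "up_in_A"])
  down <- unique(consensus$gene_id[consensus$predicted_protein_direction == "down_in_A"])
  n_overlap <- length(intersect(up, down))
  n_total <- length(up) + length(down)
  tibble(n_total = n_total, n_up = length(up), n_down = length(down),
         n_overlap = n_overlap,
         overlap_fraction = if (n_total > 0L) n_overlap / n_total else 0)
}
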