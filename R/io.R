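#' Read and write expression matrices as TSV
#'
#' The interchange format is plain TSV: a header row of sample ids, the
#' first column holding feature ids, values at full double precision.
#' Writers prepend a `#`-comment line recording the processing stage and
#' package version; readers skip such lines. Round-trips are bit-identical
#' for values representable in decimal at double precision.
#'
#' @param path File path.
#' @param stage Stage to tag the matrix with (see [expr_matrix]).
#' @return [read_expression_matrix()] returns an `expr_matrix`;
#'   [write_expression_matrix()] returns `path` invisibly.
#' @export
read_expression_matrix <- function(path, stage = "raw") {
  df <- read_tsv_checked(path, what = "expression matrix")
  if (ncol(df) < 2L) {
    abort(sprintf("Parse error in '%s': need a feature-id column plus >=1 sample column.", path),
          class = "basalmir_parse_error")
  }
  fid <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- names(df)[-1L][!vapply(df[-1L], is.numeric, logical(1))]
    abort(sprintf("Parse error in '%s': non-numeric sample column(s): %s.",
                  path, paste(bad, collapse = ", ")),
          class = "basalmir_parse_error")
  }
  rownames(vals) <- fid
  expr_matrix(vals, stage = stage)
}

#' @param x An [expr_matrix].
#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, stage = x$stage)
}

#' Read per-sample annotations
#'
#' Expects a TSV with columns `sample_id`, `group`, `run_id`, `chip_id`.
#' The group vocabulary is fixed to the study design (`normal`, `luminal`,
#' `basal_sporadic`, `basal_brca1`, `cell_line`, `control`); unknown labels
#' are rejected. A chip belongs to exactly one run, so a `chip_id` seen
#' under two `run_id`s is a validation error.
#'
#' @param path File path.
#' @return A tibble with one row per sample.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, what = "annotation table")
  need_columns(df, c("sample_id", "group", "run_id", "chip_id"), path)
  ann <- tibble(
    sample_id = as.character(df$sample_id),
    group = as.character(df$group),
    run_id = as.character(df$run_id),
    chip_id = as.character(df$chip_id)
  )
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  if (anyDuplicated(ann$sample_id)) {
    abort("Duplicate sample_id in annotations.", class = "basalmir_validation_error")
  }
  bad <- setdiff(unique(ann$group), .GROUPS)
  if (length(bad)) {
    abort(sprintf("Unknown group label(s): %s. Allowed: %s.",
                  paste(bad, collapse = ", "), paste(.GROUPS, collapse = ", ")),
          class = "basalmir_schema_error")
  }
  runs_per_chip <- tapply(ann$run_id, ann$chip_id, function(r) length(unique(r)))
  if (any(runs_per_chip > 1L)) {
    abort(sprintf("chip_id %s spans more than one run_id.",
                  paste(names(runs_per_chip)[runs_per_chip > 1L], collapse = ", ")),
          class = "basalmir_validation_error")
  }
  ann
}

#' @param ann Annotation tibble.
#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  write_tsv_with_header(as.data.frame(ann), path, stage = "annotations")
}

#' Read a miRNA-target prediction table
#'
#' One table per prediction source. Rows are (miRNA, gene) edges; the
#' source name is attached so the same pair from two algorithms remains
#' two distinct triples. Exact duplicate triples are dropped with a
#' message reporting the count; an empty table yields a warning and an
#' empty result rather than an error, since a source may legitimately
#' predict nothing for a small miRNA set.
#'
#' @param path File path to a TSV with columns `mirna_id`, `gene_id`.
#' @param source_name Name of the prediction source.
#' @return Tibble with columns `mirna_id`, `gene_id`, `source`.
#' @export
read_target_table <- function(path, source_name) {
  df <- read_tsv_checked(path, what = "target table", allow_empty = TRUE)
  if (nrow(df) == 0L) {
    warn(sprintf("Target table '%s' is empty.", path))
    return(tibble(mirna_id = character(), gene_id = character(),
                  source = character()))
  }
  need_columns(df, c("mirna_id", "gene_id"), path)
  tp <- tibble(mirna_id = as.character(df$mirna_id),
               gene_id = as.character(df$gene_id),
               source = as.character(source_name))
  n0 <- nrow(tp)
  tp <- dplyr::distinct(tp)
  if (nrow(tp) < n0) {
    inform(sprintf("Dropped %d duplicate target pair(s) from '%s'.",
                   n0 - nrow(tp), path))
  }
  tp
}

#' @param pairs Target-pair tibble.
#' @rdname read_target_table
#' @export
write_target_table <- function(pairs, path) {
  write_tsv_with_header(as.data.frame(pairs), path, stage = "target_pairs")
}

#' Read an immunohistochemistry scoring table
#'
#' Each row is one case x marker observation from a tissue-microarray
#' core: staining intensity scored 0-3 (negative/weak/moderate/strong) and
#' the stained-proportion category 0-4 (0%, 1-10%, 11-50%, 51-80%,
#' 81-100%). A core with no staining must score (0, 0) on both components,
#' so `intensity == 0` if and only if `percent_category == 0`; violations
#' are rejected at ingestion, naming the case. Non-evaluable cores (lost
#' or uninterpretable on the array) are retained with `evaluable = FALSE`
#' and excluded from comparisons downstream.
#'
#' @param path TSV with columns `case_id`, `cohort`, `truth_group`,
#'   `marker`, `intensity`, `percent_category`, `evaluable`.
#' @return Tibble of validated records.
#' @export
read_ihc_table <- function(path) {
  df <- read_tsv_checked(path, what = "IHC table")
  need_columns(df, c("case_id", "cohort", "truth_group", "marker",
                     "intensity", "percent_category", "evaluable"), path)
  rec <- tibble(
    case_id = as.character(df$case_id),
    cohort = as.character(df$cohort),
    truth_group = as.character(df$truth_group),
    marker = as.character(df$marker),
    intensity = as.integer(df$intensity),
    percent_category = as.integer(df$percent_category),
    evaluable = as.logical(df$evaluable)
  )
  validate_ihc(rec)
}

validate_ihc <- function(rec) {
  bad_cohort <- setdiff(unique(rec$cohort), c("initial", "validation"))
  if (length(bad_cohort)) {
    abort(sprintf("Unknown cohort label(s): %s.", paste(bad_cohort, collapse = ", ")),
          class = "basalmir_schema_error")
  }
  bad_group <- setdiff(unique(rec$truth_group), c("brca1", "sporadic"))
  if (length(bad_group)) {
    abort(sprintf("Unknown truth_group label(s): %s.", paste(bad_group, collapse = ", ")),
          class = "basalmir_schema_error")
  }
  ev <- rec$evaluable
  chk <- function(cond, msg) {
    bad <- which(cond & ev)
    if (length(bad)) {
      abort(sprintf("%s for case(s): %s.", msg,
                    paste(unique(rec$case_id[bad]), collapse = ", ")),
            class = "basalmir_validation_error")
    }
  }
  chk(is.na(rec$intensity) | rec$intensity < 0L | rec$intensity > 3L,
      "intensity outside 0-3")
  chk(is.na(rec$percent_category) | rec$percent_category < 0L | rec$percent_category > 4L,
      "percent_category outside 0-4")
  chk((rec$intensity == 0L) != (rec$percent_category == 0L),
      "intensity 0 and percent_category 0 must co-occur")
  rec
}

#' @param rec IHC record tibble.
#' @rdname read_ihc_table
#' @export
write_ihc_table <- function(rec, path) {
  write_tsv_with_header(as.data.frame(rec), path, stage = "ihc_records")
}

# --- shared helpers ---------------------------------------------------------

read_tsv_checked <- function(path, what, allow_empty = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path), class = "basalmir_parse_error")
  }
  df <- tryCatch(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) {
      abort(sprintf("Parse error reading %s '%s': %s", what, path,
                    conditionMessage(e)),
            class = "basalmir_parse_error")
    }
  )
  prob <- readr::problems(df)
  if (nrow(prob)) {
    abort(sprintf("Parse error in %s '%s' at line %d: %s", what, path,
                  prob$row[1L], prob$expected[1L]),
          class = "basalmir_parse_error")
  }
  if (!allow_empty && (nrow(df) == 0L || ncol(df) == 0L)) {
    abort(sprintf("Parse error: %s '%s' is empty.", what, path),
          class = "basalmir_parse_error")
  }
  df
}

need_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("Schema error in '%s': missing column(s) %s.", path,
                  paste(missing, collapse = ", ")),
          class = "basalmir_schema_error")
  }
  invisible(df)
}

write_tsv_with_header <- function(df, path, stage) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# basalmir %s stage=%s",
                     as.character(utils::packageVersion("basalmir")), stage),
             con)
  # full double precision so round-trips are bit-identical
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, format = "g", digits = 17))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
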