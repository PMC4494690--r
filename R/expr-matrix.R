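#' Expression matrix with a processing-stage tag
#'
#' A light container for a features-by-samples intensity grid. The `stage`
#' tag records how far along the preprocessing chain the values are
#' (`raw` -> `filtered` -> `shifted` -> `log2` -> `quantile_normalized` ->
#' `standardized`); preprocessing functions refuse input at the wrong stage,
#' so a matrix cannot silently be log-transformed twice or standardized
#' before normalization. Values are arbitrary intensity units up to the
#' `shifted` stage and log2 intensities afterwards.
#'
#' Missing values are permitted only at the `raw` stage (an absent
#' measurement); any feature still carrying one is excluded by the
#' filtering step, so all later stages are complete grids.
#'
#' @param values Numeric matrix, features in rows and samples in columns,
#'   with unique row and column names.
#' @param stage Processing stage, one of `"raw"`, `"filtered"`, `"shifted"`,
#'   `"log2"`, `"quantile_normalized"`, `"standardized"`.
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- matrix(c(100, 300, 50, 400), 2, 2,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' expr_matrix(m, "raw")
#' @export
expr_matrix <- function(values, stage = "raw") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "basalmir_validation_error")
  }
  stage <- match.arg(stage, .STAGES)
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    abort("`values` must have feature (row) and sample (column) names.",
          class = "basalmir_validation_error")
  }
  if (anyDuplicated(fid)) {
    abort(paste0("Duplicate feature ids: ",
                 paste(unique(fid[duplicated(fid)]), collapse = ", ")),
          class = "basalmir_validation_error")
  }
  if (anyDuplicated(sid)) {
    abort(paste0("Duplicate sample ids: ",
                 paste(unique(sid[duplicated(sid)]), collapse = ", ")),
          class = "basalmir_validation_error")
  }
  if (stage != "raw" && anyNA(values)) {
    abort(paste0("Missing values are only permitted at the raw stage (got ",
                 stage, ")."),
          class = "basalmir_validation_error")
  }
  structure(list(values = values, stage = stage), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' Feature and sample identifiers of an expression matrix
#' @param x An [expr_matrix].
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, stage: %s\n",
              nrow(x$values), ncol(x$values), x$stage))
  n <- min(4L, nrow(x$values))
  m <- min(4L, ncol(x$values))
  print(x$values[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x$values) > n || ncol(x$values) > m) cat("...\n")
  invisible(x)
}

#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble(
    feature_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

# Enforce the documented stage order: `from` may be a set of admissible
# input stages; the result is tagged `to`.
advance_stage <- function(x, from, to, op) {
  if (!inherits(x, "expr_matrix")) {
    abort(sprintf("`%s()` expects an expr_matrix.", op),
          class = "basalmir_validation_error")
  }
  if (!x$stage %in% from) {
    abort(sprintf("`%s()` expects stage %s, got '%s'.",
                  op, paste(sQuote(from), collapse = " or "), x$stage),
          class = "basalmir_stage_error")
  }
  to
}

with_values <- function(x, values, stage) {
  expr_matrix(values, stage)
}
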