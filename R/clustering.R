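#' Pearson correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` with `r` the Pearson correlation of the two
#' samples' feature vectors, so distances lie in `[0, 2]` with 0 on the
#' diagonal. A sample whose feature vector has zero variance has no
#' defined correlation and raises an error naming the sample.
#'
#' @param x An [expr_matrix] (normally standardized).
#' @param over `"samples"` (default) or `"features"` (transposes first).
#' @return A symmetric numeric matrix of distances.
#' @export
pearson_dist <- function(x, over = c("samples", "features")) {
  over <- match.arg(over)
  v <- if (over == "samples") x$values else t(x$values)
  sds <- apply(v, 2L, sd)
  if (any(sds == 0 | is.na(sds))) {
    abort(sprintf("Zero-variance vector(s): %s.",
                  paste(colnames(v)[sds == 0 | is.na(sds)], collapse = ", ")),
          class = "basalmir_validation_error")
  }
  d <- 1 - cor(v)
  diag(d) <- 0
  d
}

#' UPGMA (average-linkage) agglomerative clustering
#'
#' Repeatedly merges the pair of clusters with the smallest mean
#' inter-cluster distance; after a merge, the distance from the new
#' cluster to any other is the size-weighted mean of its parents'
#' distances. Ties on the minimum are broken deterministically by the
#' lexicographically smallest pair of smallest-member leaf ids, so the
#' tree is invariant to input leaf order.
#'
#' @param d Symmetric distance matrix with dimnames, or a [stats::dist].
#' @return An object of classes `basalmir_dendro` and `hclust` (so
#'   [stats::cutree()], plotting, and [ape::as.phylo()] all apply), with
#'   `merge`, `height`, `order`, and `labels` components.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2L) abort("Need at least two leaves.", class = "basalmir_validation_error")
  if (max(abs(d - t(d))) > 1e-12) {
    abort("Distance matrix must be symmetric.", class = "basalmir_validation_error")
  }

  # active clusters: id (<0 leaf, >0 merge row), members, smallest leaf label
  active <- data.frame(id = -seq_len(n), size = 1L,
                       minlab = labels, stringsAsFactors = FALSE)
  cur <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- nrow(active)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        key <- sort(c(active$minlab[i], active$minlab[j]))
        if (is.null(best) || cur[i, j] < best$d - 1e-15 ||
            (abs(cur[i, j] - best$d) <= 1e-15 &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(i = i, j = j, d = cur[i, j], key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- pair_order(active$id[i], active$id[j])
    height[step] <- best$d
    ni <- active$size[i]; nj <- active$size[j]
    newd <- (ni * cur[i, ] + nj * cur[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newd[keep]),
                 c(newd[keep], 0))
    active <- rbind(
      active[keep, , drop = FALSE],
      data.frame(id = step, size = ni + nj,
                 minlab = min(active$minlab[c(i, j)]),
                 stringsAsFactors = FALSE)
    )
  }

  structure(list(merge = merge, height = height,
                 order = dendro_order(merge, n), labels = labels,
                 method = "average", dist.method = "pearson",
                 call = match.call()),
            class = c("basalmir_dendro", "hclust"))
}

# hclust merge-row convention: singletons before merged clusters,
# singletons by ascending observation index
pair_order <- function(a, b) {
  if (a < 0 && b < 0) c(max(a, b), min(a, b)) else sort(c(a, b))
}

# leaf order for plotting: left-to-right traversal of the merge matrix
dendro_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(n - 1L)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges and labels the resulting clusters
#' 1..k in order of their smallest member's position, so labels are
#' deterministic.
#'
#' @param dendro A `basalmir_dendro` (or any `hclust`).
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Tibble: `sample_id`, `cluster` (integer).
#' @export
cut_clusters <- function(dendro, k) {
  stopifnot(k >= 1L, k <= length(dendro$labels))
  cl <- cutree(dendro, k = k)
  tibble(sample_id = dendro$labels, cluster = unname(cl))
}

#' Cross-tabulate clusters against annotated groups
#'
#' @param labels Tibble from [cut_clusters()].
#' @param annotations Sample annotation tibble.
#' @return Tibble with one row per cluster: per-group counts (wide), total
#'   `n`, `majority_group`, and `purity` (majority fraction).
#' @export
cluster_composition <- function(labels, annotations) {
  d <- dplyr::inner_join(labels, annotations[, c("sample_id", "group")],
                         by = "sample_id")
  counts <- d |>
    dplyr::count(.data$cluster, .data$group) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0L)
  grp_cols <- setdiff(names(counts), "cluster")
  counts$n <- rowSums(counts[grp_cols])
  counts$majority_group <- grp_cols[max.col(counts[grp_cols], ties.method = "first")]
  counts$purity <- do.call(pmax, counts[grp_cols]) / counts$n
  counts
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are the difference between a node's merge height and
#' its child's height (0 for leaves), so two leaves merged at height `h`
#' export as `(A:h,B:h);`. The string round-trips through
#' [ape::read.tree()].
#'
#' @param dendro A `basalmir_dendro`/`hclust` object.
#' @return A single Newick string, terminated with `;`.
#' @export
export_newick <- function(dendro) {
  merge <- dendro$merge; height <- dendro$height; labels <- dendro$labels
  build <- function(node, parent_h) {
    if (node < 0L) {
      sprintf("%s:%.10g", labels[-node], parent_h)
    } else {
      sprintf("(%s,%s):%.10g",
              build(merge[node, 1L], height[node]),
              build(merge[node, 2L], height[node]),
              parent_h - height[node])
    }
  }
  root <- nrow(merge)
  sprintf("(%s,%s);",
          build(merge[root, 1L], height[root]),
          build(merge[root, 2L], height[root]))
}

#' Cluster samples over a signature
#'
#' Convenience wrapper for the headline analysis: subset a standardized
#' matrix to a signature, compute Pearson correlation distances between
#' samples, run UPGMA, and (optionally) cut into `k` clusters and
#' tabulate their composition.
#'
#' @param x Standardized [expr_matrix].
#' @param signature Optional feature ids to subset to (e.g. from
#'   [select_signature()]).
#' @param annotations Optional annotations for composition.
#' @param k Optional number of clusters to cut.
#' @return A list of class `basalmir_clustering`: `dendrogram`, plus
#'   `clusters` and `composition` when `k` and `annotations` are given.
#' @export
cluster_samples <- function(x, signature = NULL, annotations = NULL, k = NULL) {
  if (!is.null(signature)) {
    ids <- if (is.data.frame(signature)) signature$feature_id else signature
    missing <- setdiff(ids, rownames(x$values))
    if (length(missing)) {
      abort(sprintf("Signature feature(s) not in matrix: %s.",
                    paste(head(missing, 5L), collapse = ", ")),
            class = "basalmir_validation_error")
    }
    x <- with_values(x, x$values[ids, , drop = FALSE], x$stage)
  }
  dend <- upgma(pearson_dist(x))
  out <- list(dendrogram = dend)
  if (!is.null(k)) {
    out$clusters <- cut_clusters(dend, k)
    if (!is.null(annotations)) {
      out$composition <- cluster_composition(out$clusters, annotations)
    }
  }
  structure(out, class = "basalmir_clustering")
}

#' @export
print.basalmir_clustering <- function(x, ...) {
  cat(sprintf("<basalmir_clustering> %d samples\n", length(x$dendrogram$labels)))
  if (!is.null(x$composition)) print(x$composition)
  invisible(x)
}

#' @export
autoplot.basalmir_dendro <- function(object, ...) {
  merge <- object$merge; height <- object$height
  n <- length(object$labels)
  pos <- numeric(n)
  pos[object$order] <- seq_len(n)
  nx <- numeric(nrow(merge)); ny <- height
  node_x <- function(id) if (id < 0L) pos[-id] else nx[id]
  node_y <- function(id) if (id < 0L) 0 else ny[id]
  segs <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    x1 <- node_x(merge[i, 1L]); x2 <- node_x(merge[i, 2L])
    y1 <- node_y(merge[i, 1L]); y2 <- node_y(merge[i, 2L])
    nx[i] <- (x1 + x2) / 2
    segs[[i]] <- tibble(
      x = c(x1, x2, x1), xend = c(x1, x2, x2),
      y = c(y1, y2, height[i]), yend = c(height[i], height[i], height[i])
    )
  }
  leaf <- tibble(x = pos, label = object$labels)
  ggplot(dplyr::bind_rows(segs)) +
    geom_segment(aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leaf$x, labels = leaf$label) +
    labs(x = NULL, y = "merge height (1 - Pearson r)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @export
autoplot.basalmir_clustering <- function(object, ...) {
  autoplot(object$dendrogram, ...)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, approximately 0 for independent ones.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
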