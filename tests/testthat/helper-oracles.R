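# Independent oracles: deliberately naive implementations, kept separate
# from the package code paths they check.

# O(n^2) Benjamini-Hochberg step-up: for each p_i, the minimum over all
# p_j >= p_i of n * p_j / rank(p_j).
oracle_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(n), function(i) {
    cand <- vapply(seq_len(n), function(j) {
      if (p[j] >= p[i]) n * p[j] / r[j] else Inf
    }, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# Per-feature group F test by explicit lm() model comparison.
oracle_anova_f <- function(y, group, chip = NULL) {
  d <- data.frame(y = y, g = factor(group))
  if (!is.null(chip) && length(unique(chip)) > 1L) {
    d$chip <- factor(chip)
    full <- lm(y ~ g + chip, data = d)
    red <- lm(y ~ chip, data = d)
  } else {
    full <- lm(y ~ g, data = d)
    red <- lm(y ~ 1, data = d)
  }
  a <- anova(red, full)
  list(f = a$F[2L], p = a$`Pr(>F)`[2L])
}

# UPGMA by definition: inter-cluster distance recomputed each step as the
# plain mean of all original pairwise member distances (no recurrence).
# Same lexicographic tie-break as the package.
oracle_upgma <- function(d) {
  labels <- rownames(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)     # member leaf indices
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
        better <- is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 &&
           (key[1L] < best$key[1L] ||
            (key[1L] == best$key[1L] && key[2L] < best$key[2L])))
        if (better) best <- list(i = i, j = j, d = dij, key = key)
      }
    }
    a <- ids[best$i]; b <- ids[best$j]
    merge[step, ] <- if (a < 0 && b < 0) c(max(a, b), min(a, b)) else sort(c(a, b))
    height[step] <- best$d
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    ids[best$i] <- step
    clusters[[best$j]] <- NULL
    ids <- ids[-best$j]
  }
  list(merge = merge, height = height)
}

# Quantile normalization by an explicit per-column loop over sorted
# positions, averaging the reference over tied spans.
oracle_quantile_norm <- function(values) {
  ref <- rowMeans(apply(values, 2L, sort))
  out <- values
  for (k in seq_len(ncol(values))) {
    v <- values[, k]
    for (i in seq_along(v)) {
      span <- which(sort(v) == v[i])
      out[i, k] <- mean(ref[span])
    }
  }
  out
}

# Exhaustive two-sided permutation p for the Mann-Whitney U.
oracle_mw_perm <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  ustat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  mu <- n1 * length(b) / 2
  u_obs <- ustat(a, b)
  us <- apply(idx, 2L, function(k) ustat(pooled[k], pooled[-k]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Per-gene tally of distinct supporting miRNAs, split by direction.
oracle_consensus <- function(pairs, de_mirnas, min_support) {
  res <- list()
  for (g in unique(pairs$gene_id)) {
    for (dir in unique(de_mirnas$direction)) {
      mirs <- unique(de_mirnas$mirna_id[de_mirnas$direction == dir])
      supp <- unique(pairs$mirna_id[pairs$gene_id == g &
                                      pairs$mirna_id %in% mirs])
      if (length(supp) >= min_support) {
        res[[length(res) + 1L]] <- data.frame(
          gene_id = g,
          predicted_protein_direction = ifelse(dir == "up_in_A",
                                               "down_in_A", "up_in_A"),
          support = length(supp), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(gene_id = character(),
                      predicted_protein_direction = character(),
                      support = integer()))
  }
  out <- do.call(rbind, res)
  out[order(out$gene_id, out$predicted_protein_direction), , drop = FALSE]
}

# Closed-form sensitivity of a k-of-n negative rule with independent
# markers: sum over subsets of >= k negatives.
oracle_kofn <- function(q_neg, k) {
  n <- length(q_neg)
  total <- 0
  for (size in k:n) {
    subs <- utils::combn(n, size, simplify = FALSE)
    for (s in subs) {
      total <- total + prod(q_neg[s]) * prod(1 - q_neg[-s])
    }
  }
  total
}

# small random symmetric distance matrix with distinct entries
random_dist <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 2)
  d <- d + t(d)
  dimnames(d) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  d
}

make_raw_matrix <- function(values, features = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- features %||% sprintf("f%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  expr_matrix(m, "raw")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
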