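#' Simulate a miRNA intensity matrix with planted structure
#'
#' Generates a raw-scale probe-by-sample intensity matrix that emulates a
#' two-run BeadChip study design: a log2-normal probe baseline, planted
#' group effects for two contrasts (basal vs. luminal, and BRCA1 vs.
#' sporadic within basal), additive per-chip log2 offsets, a multiplicative
#' run-level intensity distortion, and i.i.d. log2 residual noise. Raw
#' intensities are `2^(baseline + effect + chip + noise) * run_scale^(run-1)`
#' minus an optional additive `background_offset` (default 0), which
#' emulates background-subtracted exports whose minima can go negative.
#'
#' Samples are randomised across chips; the first chip forms run 1 with
#' `run1_size` samples, the remaining chips split run 2 evenly, mirroring
#' the 1 + 5 chip layout of a two-run study. Each random component draws
#' from its own deterministic sub-stream of `seed`, so enlarging the design
#' does not perturb earlier draws.
#'
#' @param n_features Number of probes.
#' @param n_per_group Named integer vector of per-group sample counts;
#'   names must come from the fixed group vocabulary. The default mirrors
#'   the study design (13 normal, 17 luminal, 16 sporadic basal, 11 BRCA1
#'   basal).
#' @param de_features Number of planted differential features per contrast.
#' @param log2_effect Planted group shift in log2 units.
#' @param chip_effect_sd SD of the additive per-chip log2 offset.
#' @param run_scale Multiplicative raw-scale distortion applied to run 2.
#' @param noise_sd Residual SD in log2 units.
#' @param baseline_log2_mean,baseline_log2_sd Probe baseline distribution.
#' @param background_offset Additive raw-scale offset subtracted from all
#'   intensities (default 0; set positive to produce negative minima).
#' @param n_chips Total number of chips across both runs.
#' @param run1_size Number of samples hybridised on the run-1 chip.
#' @param seed Integer seed; identical configurations are byte-identical.
#' @return A list with elements `matrix` (a raw-stage [expr_matrix]),
#'   `annotations` (sample tibble), and `truth` (a list holding the planted
#'   differential features with directions, the chip offsets, and the
#'   configuration).
#' @export
sim_expression <- function(n_features = 500L,
                           n_per_group = c(normal = 13L, luminal = 17L,
                                           basal_sporadic = 16L,
                                           basal_brca1 = 11L),
                           de_features = 50L,
                           log2_effect = 2,
                           chip_effect_sd = 0.3,
                           run_scale = 1.25,
                           noise_sd = 0.5,
                           baseline_log2_mean = 8,
                           baseline_log2_sd = 1.5,
                           background_offset = 0,
                           n_chips = 6L,
                           run1_size = 11L,
                           seed = 1L) {
  stopifnot(n_features >= 1L, all(n_per_group >= 1L),
            de_features >= 0L, de_features <= n_features,
            chip_effect_sd >= 0, noise_sd >= 0, baseline_log2_sd >= 0,
            run_scale > 0, n_chips >= 1L)
  bad <- setdiff(names(n_per_group), .GROUPS)
  if (length(bad)) {
    abort(sprintf("Unknown group(s) in n_per_group: %s.", paste(bad, collapse = ", ")),
          class = "basalmir_validation_error")
  }
  n_samples <- sum(n_per_group)
  fid <- sprintf("miR-%04d", seq_len(n_features))
  sid <- sprintf("S%03d", seq_len(n_samples))
  group <- rep(names(n_per_group), n_per_group)

  # design: randomise samples across chips (sub-stream 1)
  set.seed(seed + 1L)
  ord <- sample.int(n_samples)
  run1_size <- min(run1_size, n_samples - (n_chips - 1L))
  chip_sizes <- if (n_chips == 1L) n_samples else {
    rest <- n_samples - run1_size
    k <- n_chips - 1L
    c(run1_size, rep(rest %/% k, k) + c(rep(1L, rest %% k), rep(0L, k - rest %% k)))
  }
  chip <- character(n_samples)
  chip[ord] <- rep(sprintf("chip%d", seq_len(n_chips)), chip_sizes)
  run <- ifelse(chip == "chip1" & n_chips > 1L, "run1", "run2")
  if (n_chips == 1L) run[] <- "run1"
  ann <- tibble(sample_id = sid, group = group, run_id = run, chip_id = chip)

  # probe baselines (sub-stream 2)
  set.seed(seed + 2L)
  baseline <- rnorm(n_features, baseline_log2_mean, baseline_log2_sd)

  # chip offsets (sub-stream 3)
  set.seed(seed + 3L)
  chip_offset <- setNames(rnorm(n_chips, 0, chip_effect_sd),
                          sprintf("chip%d", seq_len(n_chips)))

  # planted differential features and directions (sub-stream 4)
  set.seed(seed + 4L)
  idx <- sample.int(n_features, min(2L * de_features, n_features))
  idx_bl <- idx[seq_len(min(de_features, length(idx)))]
  idx_bs <- setdiff(idx, idx_bl)
  dir_bl <- sample(c(1, -1), length(idx_bl), replace = TRUE)
  dir_bs <- sample(c(1, -1), length(idx_bs), replace = TRUE)

  effect <- matrix(0, n_features, n_samples)
  is_basal <- group %in% c("basal_sporadic", "basal_brca1")
  is_brca1 <- group == "basal_brca1"
  if (length(idx_bl)) effect[idx_bl, is_basal] <- dir_bl * log2_effect
  if (length(idx_bs)) effect[idx_bs, is_brca1] <- dir_bs * log2_effect

  # residual noise, one sub-stream per sample so added samples leave
  # earlier columns untouched
  noise <- matrix(0, n_features, n_samples)
  for (s in seq_len(n_samples)) {
    set.seed(seed + 1000L + s)
    noise[, s] <- rnorm(n_features, 0, noise_sd)
  }

  log2v <- baseline + effect +
    matrix(chip_offset[chip], n_features, n_samples, byrow = TRUE) + noise
  raw <- 2^log2v * ifelse(run == "run2", run_scale, 1)[col(log2v)]
  raw <- raw - background_offset
  dimnames(raw) <- list(fid, sid)

  truth_de <- dplyr::bind_rows(
    tibble(feature_id = fid[idx_bl], contrast = "basal_vs_luminal",
           direction = ifelse(dir_bl > 0, "up_in_A", "down_in_A")),
    tibble(feature_id = fid[idx_bs], contrast = "brca1_vs_sporadic",
           direction = ifelse(dir_bs > 0, "up_in_A", "down_in_A"))
  )
  list(
    matrix = expr_matrix(raw, "raw"),
    annotations = ann,
    truth = list(de = truth_de, chip_offsets = chip_offset,
                 config = list(n_features = n_features,
                               n_per_group = n_per_group,
                               de_features = de_features,
                               log2_effect = log2_effect,
                               chip_effect_sd = chip_effect_sd,
                               run_scale = run_scale, noise_sd = noise_sd,
                               background_offset = background_offset,
                               seed = seed))
  )
}

#' Simulate per-source miRNA-target prediction tables
#'
#' Each prediction source emits every true (miRNA, gene) pair and dilutes
#' it with randomly drawn false pairs so that the fraction of emitted pairs
#' that are true equals the source's configured specificity (within
#' rounding). The defaults use the published pSILAC-estimated specificities
#' of the two algorithms the union search combines (0.44 and 0.61).
#'
#' @param mirna_ids Character vector of miRNA identifiers.
#' @param truth_map Named list, one entry per miRNA, of its true target
#'   genes. If `NULL`, a truth map is drawn: `true_targets_per_mirna` genes
#'   per miRNA sampled from a universe of `n_genes`.
#' @param source_specificities Named numeric vector in (0, 1]; one table is
#'   generated per entry.
#' @param n_genes Size of the gene universe used for truth and false pairs.
#' @param true_targets_per_mirna True targets drawn per miRNA when
#'   `truth_map` is `NULL`.
#' @param seed Integer seed.
#' @return A list with `tables` (named list of target-pair tibbles, one per
#'   source) and `truth` (tibble of true pairs).
#' @export
sim_target_tables <- function(mirna_ids,
                              truth_map = NULL,
                              source_specificities = c(mirbase = 0.44,
                                                       targetscan = 0.61),
                              n_genes = 2000L,
                              true_targets_per_mirna = 10L,
                              seed = 1L) {
  if (any(source_specificities <= 0) || any(source_specificities > 1)) {
    abort("source_specificities must lie in (0, 1].",
          class = "basalmir_validation_error")
  }
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  if (is.null(truth_map)) {
    set.seed(seed + 1L)
    truth_map <- lapply(setNames(mirna_ids, mirna_ids), function(m)
      sample(genes, true_targets_per_mirna))
  }
  missing <- setdiff(mirna_ids, names(truth_map))
  if (length(missing)) {
    abort(sprintf("truth_map does not cover miRNA(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "basalmir_validation_error")
  }
  truth <- dplyr::bind_rows(lapply(mirna_ids, function(m)
    tibble(mirna_id = m, gene_id = truth_map[[m]])))

  tables <- lapply(seq_along(source_specificities), function(i) {
    s <- source_specificities[i]
    src <- names(source_specificities)[i] %||% paste0("source", i)
    set.seed(seed + 100L * i)
    per_mirna <- lapply(mirna_ids, function(m) {
      true_g <- truth_map[[m]]
      n_false <- round(length(true_g) * (1 - s) / s)
      pool <- setdiff(genes, true_g)
      false_g <- if (n_false > 0L) sample(pool, min(n_false, length(pool))) else character()
      tibble(mirna_id = m, gene_id = c(true_g, false_g), source = src)
    })
    dplyr::bind_rows(per_mirna)
  })
  names(tables) <- names(source_specificities) %||%
    paste0("source", seq_along(source_specificities))
  list(tables = tables, truth = truth)
}

#' Simulate a gene-level mRNA matrix with a planted cleavage subset
#'
#' Only a minority of miRNA targets show their regulation at the mRNA
#' level (RISC-mediated cleavage); the rest are silenced translationally
#' with no mRNA change. This generator plants that structure: a seeded
#' `cleavage_fraction` subset of the true target genes (sampled without
#' replacement, size `round(n * cleavage_fraction)`) receives an mRNA log2
#' shift *opposite* in sign to its targeting miRNAs' shift in the A group;
#' all other genes carry no shift.
#'
#' @param target_truth Tibble with columns `gene_id` and `mirna_direction`
#'   (`"up_in_A"`/`"down_in_A"`: the shift of the targeting miRNAs).
#' @param annotations Sample annotations; the shift is applied to
#'   `contrast[1]` samples relative to `contrast[2]`.
#' @param contrast Character pair (group A, group B).
#' @param cleavage_fraction Fraction of true targets cleaved, default 0.20.
#' @param mrna_log2_effect Magnitude of the planted mRNA shift (log2).
#' @param noise_sd Residual log2 SD.
#' @param n_extra_genes Additional unshifted background genes.
#' @param baseline_log2_mean,baseline_log2_sd Gene baseline distribution.
#' @param seed Integer seed.
#' @return List with `matrix` (raw-stage gene [expr_matrix]) and `truth`
#'   (tibble: `gene_id`, `cleaved`, `mrna_direction`).
#' @export
sim_gene_expression <- function(target_truth, annotations,
                                contrast = c("basal_brca1", "basal_sporadic"),
                                cleavage_fraction = 0.20,
                                mrna_log2_effect = 1.5,
                                noise_sd = 0.5,
                                n_extra_genes = 200L,
                                baseline_log2_mean = 8,
                                baseline_log2_sd = 1,
                                seed = 1L) {
  stopifnot(cleavage_fraction >= 0, cleavage_fraction <= 1)
  tt <- dplyr::distinct(target_truth, .data$gene_id, .keep_all = TRUE)
  n_t <- nrow(tt)
  n_cleaved <- round(n_t * cleavage_fraction)
  set.seed(seed + 1L)
  cleaved_idx <- if (n_cleaved > 0L) sample.int(n_t, n_cleaved) else integer()
  cleaved <- rep(FALSE, n_t); cleaved[cleaved_idx] <- TRUE
  mrna_dir <- ifelse(tt$mirna_direction == "up_in_A", "down_in_A", "up_in_A")

  genes <- c(tt$gene_id, sprintf("BG%05d", seq_len(n_extra_genes)))
  keep <- annotations$group %in% contrast
  ann <- annotations[keep, , drop = FALSE]
  n_g <- length(genes); n_s <- nrow(ann)

  set.seed(seed + 2L)
  baseline <- rnorm(n_g, baseline_log2_mean, baseline_log2_sd)
  shift <- numeric(n_g)
  shift[seq_len(n_t)][cleaved] <-
    ifelse(mrna_dir[cleaved] == "up_in_A", 1, -1) * mrna_log2_effect

  noise <- matrix(0, n_g, n_s)
  for (s in seq_len(n_s)) {
    set.seed(seed + 2000L + s)
    noise[, s] <- rnorm(n_g, 0, noise_sd)
  }
  in_a <- as.numeric(ann$group == contrast[1L])
  log2v <- baseline + outer(shift, in_a) + noise
  raw <- 2^log2v
  dimnames(raw) <- list(genes, ann$sample_id)
  list(
    matrix = expr_matrix(raw, "raw"),
    annotations = ann,
    truth = tibble(gene_id = tt$gene_id, cleaved = cleaved,
                   mrna_direction = ifelse(cleaved, mrna_dir, NA_character_))
  )
}

#' Simulate an immunohistochemistry cohort with planted marker positivity
#'
#' Draws per-case marker staining for a two-group cohort. Positivity is
#' Bernoulli with group-conditional probabilities; within-case correlation
#' of marker negativity is induced by a shared standard-normal case factor
#' with loading `sqrt(panel_negative_corr)` (probit latent model — the
#' marginal positivity probabilities are preserved exactly). Positive cores
#' draw intensity from `intensity_probs` (categories 1-3) and proportion
#' from `percent_probs` (categories 1-4); negative cores score (0, 0).
#' Cores are independently non-evaluable with probability
#' `1 - evaluable_prob`, emulating lost or uninterpretable TMA cores.
#'
#' Default cohort sizes and positivity probabilities follow the published
#' validation cohort (82 BRCA1 vs. 65 sporadic; FOXP1 52%/94%, cyclin D1
#' 57%/89%, NRP1 41%/72%, CD99 28%/47% positive).
#'
#' @param n_brca1,n_sporadic Cases per truth group.
#' @param positivity Named list with numeric vectors `brca1` and
#'   `sporadic`, one probability per marker (names = marker ids).
#' @param intensity_probs Probabilities for intensity categories 1-3 given
#'   positive (must sum to 1).
#' @param percent_probs Probabilities for percent categories 1-4 given
#'   positive (must sum to 1).
#' @param panel_negative_corr Latent within-case correlation of marker
#'   negativity, in `[0, 1)`.
#' @param evaluable_prob Probability a core is evaluable.
#' @param cohort Cohort label for the records.
#' @param seed Integer seed.
#' @return List with `records` (IHC tibble) and `truth` (planted
#'   positivity probabilities, long tibble).
#' @export
sim_ihc_cohort <- function(n_brca1 = 82L, n_sporadic = 65L,
                           positivity = list(
                             brca1 = c(FOXP1 = 0.52, CCND1 = 0.57,
                                       NRP1 = 0.41, CD99 = 0.28),
                             sporadic = c(FOXP1 = 0.94, CCND1 = 0.89,
                                          NRP1 = 0.72, CD99 = 0.47)),
                           intensity_probs = c(0.3, 0.4, 0.3),
                           percent_probs = c(0.15, 0.25, 0.30, 0.30),
                           panel_negative_corr = 0.3,
                           evaluable_prob = 0.85,
                           cohort = "validation",
                           seed = 1L) {
  stopifnot(length(intensity_probs) == 3L, length(percent_probs) == 4L,
            panel_negative_corr >= 0, panel_negative_corr < 1,
            evaluable_prob >= 0, evaluable_prob <= 1)
  if (abs(sum(intensity_probs) - 1) > 1e-8 || abs(sum(percent_probs) - 1) > 1e-8) {
    abort("intensity_probs and percent_probs must each sum to 1.",
          class = "basalmir_validation_error")
  }
  markers <- names(positivity$brca1)
  if (is.null(markers) || !setequal(markers, names(positivity$sporadic))) {
    abort("positivity$brca1 and positivity$sporadic must share marker names.",
          class = "basalmir_validation_error")
  }
  if (any(unlist(positivity) < 0) || any(unlist(positivity) > 1)) {
    abort("Positivity probabilities must lie in [0, 1].",
          class = "basalmir_validation_error")
  }
  n <- n_brca1 + n_sporadic
  case_id <- sprintf("case%03d", seq_len(n))
  grp <- rep(c("brca1", "sporadic"), c(n_brca1, n_sporadic))
  rho <- panel_negative_corr

  set.seed(seed + 1L)
  u <- rnorm(n)                     # shared case factor
  rec <- vector("list", length(markers))
  for (j in seq_along(markers)) {
    set.seed(seed + 10L * j)
    e <- rnorm(n)
    z <- sqrt(rho) * u + sqrt(1 - rho) * e
    p_pos <- ifelse(grp == "brca1",
                    positivity$brca1[[markers[j]]],
                    positivity$sporadic[[markers[j]]])
    pos <- pnorm(z) <= p_pos        # P(positive) = p_pos marginally
    intensity <- ifelse(pos, sample(1:3, n, TRUE, intensity_probs), 0L)
    pct <- ifelse(pos, sample(1:4, n, TRUE, percent_probs), 0L)
    evaluable <- runif(n) <= evaluable_prob
    rec[[j]] <- tibble(case_id = case_id, cohort = cohort, truth_group = grp,
                       marker = markers[j],
                       intensity = as.integer(intensity),
                       percent_category = as.integer(pct),
                       evaluable = evaluable)
  }
  records <- validate_ihc(dplyr::bind_rows(rec))
  truth <- dplyr::bind_rows(
    tibble(truth_group = "brca1", marker = markers,
           p_positive = unname(positivity$brca1[markers])),
    tibble(truth_group = "sporadic", marker = markers,
           p_positive = unname(positivity$sporadic[markers]))
  )
  list(records = records, truth = truth)
}
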