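---
title: "Methods: miRNA profiling and IHC panel analysis of BRCA1 and sporadic basal-like breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA profiling and IHC panel analysis of BRCA1 and sporadic basal-like breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basalmir)
```

# The scientific problem

Basal-like breast cancers arising in germline *BRCA1* mutation carriers are
morphologically similar to sporadic basal-like cancers, yet the two groups
differ in their microRNA (miRNA) expression and, downstream, in the protein
expression of predicted miRNA targets. `basalmir` implements the full
comparative analysis chain for this question as reusable, tested functions:

1. array preprocessing (probe filtering, per-sample shifting, log2,
   quantile normalization, per-run standardization);
2. per-miRNA differential expression by ANOVA with the hybridization
   BeadChip as a batch covariate and Benjamini–Hochberg (BH) adjustment;
3. unsupervised hierarchical clustering of samples over a fold-change
   signature (Pearson correlation distance, average linkage);
4. consensus filtering of miRNA→gene target predictions with an mRNA
   cross-reference for the cleavage-visible subset;
5. an immunohistochemistry (IHC) marker panel scored 0–7 per marker, a
   k-of-n negative-marker classifier for BRCA1 status, and
   prevalence-adjusted predictive values.

Because the original array cohorts and historical prediction databases are
not redistributable, the package ships seeded generators
(`sim_expression()`, `sim_target_tables()`, `sim_gene_expression()`,
`sim_ihc_cohort()`) that emulate the statistical structure of every input
with planted, recoverable truth. Every pipeline stage is validated against
that planted truth and against independent numerical oracles.

# Preprocessing model

Raw probe intensities are background-subtracted vendor exports, so minima
can be negative. The chain is *filter → shift → log2 → quantile normalize
→ standardize*, enforced by a stage tag on the matrix container:

* **Intensity filter.** A probe is excluded when its maximum across all
  samples is *strictly below* 150 intensity units; a probe exactly at the
  threshold is retained. Probes with any missing value are excluded here
  too, so downstream arithmetic is total. For mRNA matrices an analogous
  detection filter keeps probes with a detection score strictly above
  0.95 in at least one sample.
* **Shift.** Each sample is shifted additively so its minimum is exactly
  1, making the log2 transform defined everywhere and mapping each
  sample's minimum to 0.
* **Quantile normalization.** The reference distribution is the mean of
  the per-sample sorted vectors. Ties within a sample receive the mean of
  the reference values across their rank span; dialects differ here, so
  the choice is documented and pinned by tests (the loop-based reference
  oracle and, on tie-free data, `limma::normalizeQuantiles`). On tie-free
  data the operation is idempotent and leaves all samples with identical
  sorted vectors.
* **Standardization.** Each miRNA is scaled to mean 0, standard deviation
  1 (sample SD, $n-1$ denominator — the convention is a package choice)
  *separately within each hybridization run*, because probe intensities
  differ systematically between runs. Zero-variance features are set to 0
  and flagged rather than dropped, keeping feature sets aligned.

# Differential expression

For each feature the two-way fixed-effects model
$y = \mu + \beta_{\text{group}} + \gamma_{\text{chip}} + \varepsilon$
(no interaction) is fitted by least squares, and the group factor is
tested with a partial F test against the chip-only model. Chip levels
aliased in the reduced design are dropped; if the *group* factor itself
carries no degrees of freedom after chip adjustment, the fit aborts and
names the confounding — a deliberately loud failure, since a
group-confounded chip layout cannot be rescued statistically. Features
with zero residual *and* zero effect variance are flagged and assigned
p = 1 rather than propagating NaN.

Fold changes are computed from quantile-normalized log2 group means,
anti-logged, and reported with the signed magnitude convention
($r$ if $r \ge 1$, else $-1/r$), so swapping the contrast negates the
value and $|FC| \ge 1$ always. The published tables pair negative fold
changes with "Up" labels under an unstated reference convention; this
package defines its own convention (direction = sign of
$\overline{\log_2 A} - \overline{\log_2 B}$) and does not attempt to
reproduce those signs.

BH adjustment uses the standard step-up procedure (`stats::p.adjust`),
cross-checked in tests against a quadratic "minimum over the tail"
oracle. Signatures are the union of the top-N features per contrast by
absolute fold change (defaults 75 for basal vs. luminal, 100 for BRCA1
vs. sporadic), with ties broken by feature id so selection is invariant
to row order.

# Clustering

Samples are clustered on standardized signature expression with distance
$d(i,j) = 1 - r(i,j)$ (Pearson), range $[0, 2]$, and UPGMA (average
linkage). UPGMA is implemented directly because the tie-break must be
deterministic: when two merges are equally close, the pair whose
smallest-member labels sort lexicographically first wins, making the tree
invariant to input leaf order. The result is an `hclust`-compatible
object, so `cutree()` and standard plotting apply; `export_newick()`
writes branch lengths as height differences (two leaves merged at height
*h* export as `(A:h,B:h);`). Tests verify the implementation against a
definition-level oracle that recomputes inter-cluster means from the
original distances, and against `stats::hclust` on tie-free inputs.

Cluster cuts remove the $k-1$ highest merges; labels are assigned by each
cluster's smallest member position. Composition tables report per-cluster
group counts, majority group and purity.

# Target consensus and the cleavage subset

Predictions from multiple algorithms are combined by a union search with
per-pair provenance. A gene is a *consensus target* when at least
`min_support = 3` distinct differentially expressed miRNAs target it,
counted separately per miRNA direction: targets of up-regulated miRNAs
form the predicted protein-*down* list and vice versa. Genes reaching
support in both directions appear in both lists (`in_both_lists`),
mirroring how union searches report totals — `overlap_stats()` therefore
counts list memberships, so a 562-up/656-down split with 71 shared genes
gives an overlap fraction of 71/1218 ≈ 5.8 %.

Only about 20 % of miRNA targets show their regulation at the mRNA level
(RISC-mediated cleavage); the rest are silenced translationally. The
cleavage flag therefore requires the gene's mRNA to be differentially
expressed (BH q < 0.05) *and*, by default, shifted opposite to its
supporting miRNAs. The opposite-direction requirement is switchable
because a plain cross-match is also defensible; the default encodes the
biology (cleavage lowers the mRNA of targets of up-regulated miRNAs).

# IHC scoring, marker comparisons and the panel classifier

Each core is scored as intensity (0–3) plus stained-proportion category
(0–4), summed to 0–7. *Positivity* is any staining: intensity ≥ 1 with
proportion ≥ 1 (the two components are zero together by the ingestion
invariant). Group comparisons use the Pearson chi-square on
presence/absence (df = 1, *no* continuity correction — validated by
reproducing the published p = 0.025 / 0.002 / 0.002 exactly from the
printed 2×2 tables) and the Mann–Whitney U on the 0–7 scores (exact when
both groups have ≤ 8 tie-free observations, else the tie-corrected normal
approximation without continuity correction, as scored-data comparisons
in common statistical packages compute it).

The classifier predicts BRCA1 when ≥ k of the rule markers are negative
(default 2 of FOXP1, cyclin D1, NRP1). Cases with any rule marker
non-evaluable are excluded and counted, never imputed. `evaluate_panel()`
reports the confusion, sensitivity, specificity and the cohort's own
predictive values; `prevalence_adjusted_pv()` re-expresses PPV/NPV at the
population prevalence derived by Bayes' rule from three assumptions
(BRCA1 prevalence in breast cancer 2 %, basal fraction 15 %, basal
fraction among BRCA1 cancers 69 %), giving

$$\text{prev} = \frac{0.02 \times 0.69}{0.15} = 0.092 .$$

**A documented discrepancy:** at sensitivity 92 % and specificity 44 %,
the standard formula yields PPV ≈ 14.3 % and NPV ≈ 98.2 % at prevalence
0.092. The published figures of 38 % and 94 % are not reproducible from
these inputs (they imply a prevalence near 0.27 whose derivation is not
stated). The package implements the standard formula, reports cohort and
adjusted values side by side, and deliberately does not match the printed
numbers.

# Synthetic-data generators: what they emulate

`sim_expression()` draws raw intensities as
$2^{\text{baseline} + \text{group effect} + \text{chip offset} + \text{noise}} \times \text{run scale}$,
with samples randomized across chips in a 1-chip run 1 / 5-chip run 2
layout. Defaults mirror the study design: 13 normal, 17 luminal, 16
sporadic-basal and 11 BRCA1-basal samples; 50 planted features per
contrast at |log2 effect| 2; chip offsets with SD 0.3; run-2 intensity
scale 1.25; residual log2 SD 0.5. Each random component uses its own
deterministic sub-stream of the seed (one per sample for noise), so
enlarging a design never perturbs earlier draws. An optional additive
background offset produces negative minima to exercise the shift stage.

`sim_target_tables()` defaults to two sources with specificities 0.44 and
0.61 — the published pSILAC estimates for the two union-search
algorithms — each emitting all true pairs plus false pairs at the
complementary rate. `sim_gene_expression()` plants an exact
`round(n × 0.2)` cleavage subset with mRNA shifts opposite to the
targeting miRNAs. `sim_ihc_cohort()` defaults to the validation-cohort
design (82 BRCA1 / 65 sporadic; marker positivity from the published
percentages) with a probit latent factor inducing within-case correlation
of marker negativity (default 0.3 — the published data give no joint
distribution, so a single shared-factor loading is the package's choice)
and an evaluable-core probability of 0.85, emulating lost TMA cores.

What the generators do *not* emulate: probe-level spatial artifacts,
intensity-dependent variance, miRNA co-regulation structure, the real
cohorts' probe counts or effect-size spectrum, and inter-observer scoring
noise. Passing recovery tests therefore demonstrates correctness of the
*computations* under the stated statistical model, not performance on
real cohorts.

# Numerical choices and degenerate inputs

* Exactly-at-threshold probes are retained (filter is strict-less-than);
  detection filtering is strict-greater-than.
* Quantile-normalization ties: mean of the reference over the rank span.
* Standardization: sample SD; zero-variance features zeroed and flagged.
* F tests: zero-residual/zero-effect features flagged with p = 1;
  group–chip confounding is a hard error naming the levels.
* UPGMA ties: lexicographic smallest-leaf-pair rule; merge heights are
  non-decreasing by construction.
* Chi-square requires positive margins; Mann–Whitney identical samples
  give p = 1 via the approximation path.
* Derived prevalence outside (0, 1) is an assumption error.

# Verification protocol and problem sizes

Every operation with a stated contract is tested against an independent
oracle: a loop-based quantile-normalization reference; per-feature
`lm()`/`anova()` refits (agreement to 1e−8); a quadratic BH step-up; a
definition-level UPGMA recomputing means from raw distances for n ≤ 6;
exhaustive Mann–Whitney permutation enumeration for small groups; and a
per-gene counting tally for the consensus rule.

Recovery checks run at sizes chosen to make Monte-Carlo noise small while
keeping the default suite fast: differential-expression power on the
standard 500-feature design (power 1.0 across a 20-seed calibration;
threshold frozen at ≥ 0.9), a null false-positive check on 1000 features
(observed 0; bound 0.05 + 3 binomial SE), clustering on a 15 + 15 fixture
at effect 2.0 / noise 0.5 where the acceptance measurement is the median
adjusted Rand index over five sub-seeds (50-seed calibration: median 1.0,
96 % of seeds ≥ 0.9; the median-of-5 protocol makes the check robust to a
single unlucky draw), panel recovery on 1000 cases per group against the
closed-form k-of-n binomial value, and cleavage recovery on 200 genes ×
24 samples (20-seed calibration: sensitivity 1.0 throughout, FDR ≤ 0.091;
envelope frozen at sensitivity ≥ 0.9, FDR ≤ 0.15).

# Known limitations

* The published cohort-level results (1037 retained probes, the specific
  miRNA lists and fold changes, the 1218/562/656/71 consensus counts, and
  the cohort sensitivity 92 % / specificity 44 %) require the original
  deposited cohorts, historical prediction databases, or unpublished
  joint staining patterns; they are not recomputable here and the package
  does not pretend to reproduce them.
* The group vocabulary is fixed to the study's design; extending it is a
  configuration concern, not a code path.
* No moderated-variance (empirical Bayes) testing is provided — the
  modeled analysis used plain ANOVA — and no bootstrap cluster stability.
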