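# basalmir

`basalmir` is an R package for the comparative miRNA-profiling analysis of
**BRCA1-mutated versus sporadic basal-like breast cancer**, built for
analysts who want the published analysis chain as tested, composable
functions rather than a one-off script. It covers:

- **Array preprocessing** — probe filtering (maximum intensity < 150
  excluded), per-sample shifting to minimum 1, log2 transform, quantile
  normalization, and per-run standardization of each miRNA to mean 0 / SD 1.
- **Differential expression** — per-feature two-way fixed-effects ANOVA
  (`expression ~ group + chip`) testing the group factor with the BeadChip
  as a batch covariate, Benjamini–Hochberg FDR adjustment, and signed fold
  changes `FC = r` if `r ≥ 1` else `−1/r` with `r = 2^(mean log2 A − mean log2 B)`.
- **Signature clustering** — union of the top-75 (basal vs. luminal) and
  top-100 (BRCA1 vs. sporadic) features by |FC|, Pearson correlation
  distance `d = 1 − r`, UPGMA with a deterministic tie-break, Newick export.
- **Target consensus** — union search over multiple prediction sources,
  genes kept when ≥ 3 distinct differential miRNAs target them (counted per
  direction), and a RISC-cleavage flag for consensus genes whose mRNA is
  itself differentially expressed in the opposite direction.
- **IHC marker panel** — composite staining scores (intensity 0–3 +
  proportion 0–4, max 7), Pearson chi-square (df = 1, no continuity
  correction) and Mann–Whitney U marker comparisons, a *k-of-n
  negative-marker* BRCA1 classifier (default: ≥ 2 of FOXP1, cyclin D1,
  NRP1 negative), and prevalence-adjusted predictive values via Bayes'
  rule with prevalence `0.02 × 0.69 / 0.15 = 0.092`.
- **Seeded synthetic-data generators** for all four input types, with
  planted truth, so the entire pipeline is testable offline.

## Worked example

```r
library(basalmir)

sim <- sim_expression(seed = 101)           # 57-sample, 500-probe design
qn  <- preprocess(sim$matrix)               # filter -> shift -> log2 -> quantile
std <- preprocess(sim$matrix, sim$annotations)  # ... -> per-run standardized

de <- diff_expr(qn, sim$annotations,
                list(brca1 = "basal_brca1", sporadic = "basal_sporadic"))
glance(de)
#> # A tibble: 1 × 4
#>   contrast          n_features n_significant n_reportable
#>   <chr>                  <int>         <int>        <int>
#> 1 brca1_vs_sporadic        480            52           51
head(tidy(de), 3)
#> # A tibble: 3 × 7
#>   feature_id fold_change direction f_statistic    p_raw p_adjusted flagged
#>   <chr>            <dbl> <chr>           <dbl>    <dbl>      <dbl> <lgl>
#> 1 miR-0004         -6.07 down_in_A        257. 7.06e-13   3.39e-10 FALSE
#> 2 miR-0323         -4.53 down_in_A        221. 2.88e-12   6.91e-10 FALSE
#> 3 miR-0347          4.44 up_in_A          172. 2.82e-11   3.15e- 9 FALSE
```

Of the 480 probes surviving the intensity filter, 52 are significant at
BH q < 0.05 and 51 also exceed |FC| > 2.5; the top hits carry the planted
|log2 FC| = 2 effects. Clustering the standardized matrix over the
signature separates the BRCA1 group cleanly:

```r
sig <- select_signature(de, top_n = 100)
cl <- cluster_samples(std, signature = intersect(sig$feature_id, rownames(std$values)),
                      annotations = sim$annotations, k = 2)
cl$composition
#> # A tibble: 2 × 8
#>   cluster basal_sporadic luminal normal basal_brca1     n majority_group purity
#>     <int>          <int>   <int>  <int>       <int> <dbl> <chr>           <dbl>
#> 1       1             16      17     13           0    46 luminal         0.370
#> 2       2              0       0    0          11    11 basal_brca1     1
autoplot(cl)   # ggplot2 dendrogram
```

All 11 BRCA1-basal samples form a pure cluster (purity 1.0) on this
BRCA1-vs-sporadic signature. The IHC side works from printed 2×2 counts
or record-level tables:

```r
chisq_2x2(8, 14, 30, 16)        # cyclin D1, initial cohort (8/22 vs 30/46)
#> chi2 = 5.03, p = 0.025
prevalence_adjusted_pv(0.92, 0.44)
#> # A tibble: 1 × 3
#>   derived_prevalence adjusted_ppv adjusted_npv
#>                <dbl>        <dbl>        <dbl>
#> 1              0.092        0.143        0.982
```

At sensitivity 0.92 and specificity 0.44 the standard Bayes formula gives
PPV 14.3 % and NPV 98.2 % at the derived prevalence of 9.2 % — the
package reports cohort-based and prevalence-adjusted values side by side
(see the methods vignette for why these differ from some published
figures). `run_pipeline()` executes all stages end-to-end and writes a
hash manifest, so identical configurations are verifiably byte-identical.

## Documentation

The methods vignette (`vignettes/basalmir-methods.Rmd`) describes the
statistical models, every tunable parameter with its default and
rationale, what the synthetic generators do and do not emulate, numerical
edge-case handling, and known limitations.
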