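# wbnet — wavelet-based functional brain networks and method comparison

Functional brain networks are usually built by decomposing regional fMRI
time series into frequency bands with a discrete wavelet transform,
correlating same-band coefficients between regions, thresholding the
correlation matrix to a fixed edge density, and summarizing the resulting
graph. Each of those steps hides methodological choices — the transform
(orthogonal **DWT** vs. the non-decimated, shift-invariant **MODWT**), the
orthonormal filter family (Daubechies Extremal Phase **D**, Least
Asymmetric **LA**, Coiflet **C**), and the filter length (2–24) — and
those choices measurably change graph metrics, group-difference
sensitivity, and diagnostic classification. `wbnet` is for neuroimaging
methodologists who want to construct such networks and *quantify* the
consequences of these choices rather than inherit them silently.

## What the package computes

For a cohort of subjects (each a timepoints × regions matrix):

1. **Decomposition.** MODWT/DWT pyramid algorithms (periodic boundaries,
   depth 4 by default) for all 21 admissible filters; scale *j* covers the
   band (fs/2^(j+1), fs/2^j], i.e. 0.0625–0.125 Hz at TR = 2 s for the
   commonly analysed scale 2. Energy conservation, perfect reconstruction
   and shift equivariance hold to floating-point precision.
2. **Connectivity.** Wavelet correlation
   `r_ij = cor(W_j^(i), W_j^(j))` per scale (partial correlation and
   MRA-detail variants as sensitivity switches).
3. **Graph metrics.** Threshold to 30% density (signed ranking,
   deterministic ties), then: mean/variance of correlations, clustering
   coefficient, characteristic path length, global and local efficiency,
   Louvain modularity `Q = (1/2l) Σ_ij (A_ij − k_i k_j/2l) δ(c_i,c_j)`
   (mean over 20 seeded restarts) and the number of communities of a
   consensus partition.
4. **Statistics.** The length-variation statistic `Σ_k |v_(k+1) − v_k|`
   compared between methods by paired t; sign tests with Bonferroni
   correction; repeated-measures ANOVA with wavelet length as the
   within-subject factor (df = (k−1, (k−1)(n−1))); −log10 p sensitivity
   surfaces.
5. **Classification.** 10-trial AdaBoost.M1 over gain-ratio (C4.5-style)
   decision trees, stratified 6-fold cross-validation, pooled confusion
   counts, patient group as positive class.
6. **Synthetic cohorts.** Two-group cohorts of long-memory (fractional
   Gaussian noise, exact circulant embedding) community-structured
   signals at the reference dimensions (29 + 29 subjects, 90 regions,
   177 timepoints, TR = 2 s) with a tunable group connectivity effect —
   so every stage is testable without clinical data.

## Worked example

```r
library(wbnet)

ch <- generate_cohort(cohort_spec(seed = 7))
#> synthetic cohort: 29 + 29 subjects, 90 regions x 177 timepoints (TR = 2s)
#> H = 0.8, 6 modules, within/between corr 0.4/0.1, broadband group effect -0.15

scale_to_band(2, 2)                    # the band scale 2 analyses
#> scale 2 band: 0.0625-0.125 Hz

# sweep the D family at scale 2 under both methods, weighted metrics only
cfg <- pipeline_config(methods = c("modwt", "dwt"),
                       filters = paste0("D", seq(2, 20, 2)),
                       scales = 2, binary_metrics = FALSE, seed = 1)
tab <- run_pipeline(ch, cfg)
head(tab[, c("subject", "group", "method", "length", "mean_corr")], 3)
#>   subject   group method length mean_corr
#> 1    S001 control  modwt      2 0.1462574
#> 2    S001 control  modwt      4 0.1535983
#> 3    S001 control  modwt      6 0.1572187

# do metric profiles vary more over filter lengths under DWT than MODWT?
method_variation_test(tab, "mean_corr", "D", 2, group = "control")
#> paired t: statistic = -9.343, df = 28, p = 4.221e-10
```

The negative paired t (df = 28 over the 29 controls) says MODWT profiles
vary significantly *less* across filter lengths than DWT profiles — the
decimated transform estimates scale-2 correlations from a quarter of the
coefficients and is correspondingly noisier. Classification of the two
groups from the eight scale-2 graph metrics of a single filter:

```r
cfg2 <- pipeline_config(methods = "modwt", filters = "LA8", scales = 2, seed = 2)
tab2 <- run_pipeline(ch, cfg2)
classification_sweep(tab2, scale = 2, seed = 3)
#>   family length scale accuracy sensitivity specificity TP FN FP TN
#> 1     LA      8     2        1           1           1 29  0  0 29
```

Perfect separation here reflects the generator's deliberately large
injected effect (−0.15 within-module correlation in patients), not a claim
about clinical data. With permuted labels the same sweep falls to chance
(~0.5). See `vignettes/wavelet-network-methods.Rmd` for the model, every
tunable parameter, and the design decisions.

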