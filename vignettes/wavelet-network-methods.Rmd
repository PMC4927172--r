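---
title: "Wavelet choices in functional brain network construction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet choices in functional brain network construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Resting-state fMRI time series have slowly decaying positive
autocorrelations (long memory, Hurst exponent above 0.5). Plain time-domain
correlation is a poor estimator of association between two long-memory
series, so functional connectivity is customarily estimated per frequency
band from wavelet coefficients: decompose every regional series, correlate
same-scale coefficients between regions, threshold the resulting matrix to a
fixed edge density, and summarize the binary graph. Every step involves
methodological choices — the transform (orthogonal DWT versus non-decimated
MODWT), the filter family (Daubechies Extremal Phase "D", Least Asymmetric
"LA", Coiflet "C"), and the filter length (2–24) — and those choices change
the numbers downstream. `wbnet` implements the full construction and the
comparison machinery needed to quantify that sensitivity: estimate
variability across filter lengths, group-difference statistics, and
diagnostic classification.

## Transforms

Both pyramids use periodic (circular) boundary handling, which makes the
energy identities exact and keeps every identity testable to floating-point
precision. The MODWT uses rescaled filters (`g/sqrt(2)`, `h/sqrt(2)`) and no
downsampling: each of the `J` scales carries `N` coefficients, the transform
commutes with circular shifts, and `sum_j ||W_j||^2 + ||V_J||^2 = ||x||^2`
exactly. Coefficients influenced by the circular wrap are flagged in
`boundary_mask_per_scale`; they are *included* in connectivity estimation by
default (no exclusion rule is standard practice in this literature) and
exclusion is available as a switch (`exclude_boundary`). The one place where
boundary exclusion is the default is `estimate_hurst()`, because the
unbiased (interior-only) wavelet variance is the standard estimator there
and it makes the estimator exactly immune to polynomial trends up to the
filter's vanishing moments — a circularly wrapped trend otherwise leaks a
large jump discontinuity into the boundary coefficients.

The DWT accepts arbitrary lengths by an odd-length carry rule: when an
intermediate scaling series has odd length `M`, its last value is set aside
as one extra scaling coefficient and the remaining `M - 1` values are
decomposed. The carried values are re-attached to the final scaling vector,
so the coefficient count always equals the input length and the round trip
is exact (at `N = 177`, depth 4: 88 + 44 + 22 + 11 + 12 coefficients). When
`N` is a multiple of `2^J` the transform is orthonormal and satisfies the
subsampling identity `W^dwt_j[t] = 2^{j/2} W^modwt_j[2^j (t+1) - 1]`, which
the tests verify at 1e-10.

No phase-alignment correction is applied before correlation: a common
circular shift of both sequences leaves their correlation unchanged, so
alignment would only matter for plotting.

Scale `j` maps to the nominal band `(fs/2^{j+1}, fs/2^j]` with
`fs = 1/TR`; at TR = 2 s, scale 1 is 0.125–0.25 Hz and scale 2 (the band
most resting-state analyses target) is 0.0625–0.125 Hz.

## Filters

Scaling filters are shipped as double-precision tables in the Percival &
Walden time-domain convention; the wavelet filter follows from the
quadrature-mirror relation `h[l] = (-1)^l g[L-1-l]`. Every constructor call
re-validates unit energy, `sum(g) = sqrt(2)`, `sum(h) = 0` and
orthogonality to even shifts at 1e-10. Admissible lengths are D 2–20, LA
8–20 (the least-asymmetric construction needs length at least 8) and C
{6, 12, 18, 24} (Coiflets exist at multiples of 6).

`vanishing_moments()` computes the moment count numerically rather than
assuming a formula. For D and LA filters it equals `length/2`. For Coiflets
the standard tables give `2K` wavelet vanishing moments at length `6K`
(C6 has 2, not 3): the folklore statement that a length-`2p` filter has `p`
vanishing moments holds for the Daubechies families only, and the package
reports the numerically verified count.

## Connectivity

The connectivity estimator is the plain Pearson correlation of same-scale
coefficient sequences — the standard choice with MODWT outputs in
neuroimaging; no bias-corrected wavelet-correlation estimator is used. A
partial-correlation variant (standardized negative inverse covariance, with
an optional ridge for the rank-deficient case) and correlation of MRA
details instead of raw coefficients are provided as sensitivity analyses.
Wavelet coherence is out of scope: it needs spectral smoothing machinery
that is a different project. Regions with zero-variance coefficients are
flagged and set to `NA`, never silently zeroed.

## Graph metrics

Matrices are thresholded to a fixed density (default 30%, the conventional
small-world regime for functional brain networks) by keeping the
`round(density * n(n-1)/2)` most positive edges (half-away-from-zero
rounding; `mode = "weakest"` keeps the least positive). Signed values are
ranked as-is, not by magnitude. Ties are broken by lexicographic (row,
column) order so thresholding is deterministic.

Two printed-formula ambiguities are resolved toward the conventions of the
standard brain-connectivity toolboxes, and documented here: the
characteristic path length averages geodesics over ordered pairs of
*distinct* vertices within components (denominator `sum_m n_m (n_m - 1)`;
a `sum n_m^2` denominator would deflate the average with zero diagonal
terms), and modularity is the normalized Newman–Girvan `Q in [-1, 1]`
including the `1/(2l)` prefactor. Local efficiency computes geodesics
*within* the neighbour-induced subgraph. Nodes of degree below 2 contribute
zero to clustering and local efficiency.

Because the modularity landscape is nearly degenerate, Louvain is restarted
(default 20 times) with seeded random vertex orders; the reported `Q` is
the restart mean by default (`reducer = "max"` gives the best-solution
convention instead, and both the count and reducer are configurable since
both appear in the literature). The number of communities comes from a
consensus partition: module-allegiance matrix, entries at or below a
permutation-null expectation zeroed, re-clustered until the restart set is
identical (iteration cap 20, non-convergence returns the last iterate with
a flag). The permutation null — community labels of each input partition
randomly reassigned to nodes — is one concrete interpretation of the
consensus procedure, which the source literature leaves under-specified.

## Statistics battery

* Length-variation statistic: `sum_k |v_{k+1} - v_k|` over ascending filter
  lengths; it is location-invariant and scales linearly, and is compared
  between MODWT and DWT by a paired t test across subjects.
* Two-sample comparisons use the classical pooled-variance t
  (df `n_a + n_b - 2 = 56` at 29 + 29); the sign test is the exact
  two-sided binomial on nonzero paired differences; family-wise correction
  is Bonferroni — the most conservative standard reading of "conservative
  family-wise error correction".
* The repeated-measures ANOVA treats wavelet *length* as the within-subject
  factor and subject as the repeated unit, giving df
  `(k-1, (k-1)(n-1))` — (9, 252), (6, 168) and (3, 84) for the D, LA and C
  sweeps over 29 subjects. The alternative reading (metric type as the
  repeated measure) is inconsistent with those df and is not implemented.
  No sphericity correction is applied by default; Greenhouse–Geisser is a
  flag. The closed-form implementation is cross-checked against
  `stats::aov` with an `Error(subject/condition)` stratum in the tests.
* The sensitivity surface reports `-log10 p` of the group two-sample t per
  (family, length, metric) cell.

On calibration: the exact sign test is discrete, so its true size is below
0.05 for most sample sizes (at n = 29 pairs it is 0.024). The type-I
simulations use 58 pairs — the cohort's own subject count — where the exact
size is 0.048, so an empirical rate can meaningfully be compared with the
nominal level.

## Classification

The protocol is 10-trial AdaBoost.M1 over decision trees with stratified
6-fold cross-validation and cumulative (pooled) confusion counts, with the
patient group as the positive class. The base learner is a C4.5-style tree
written for this package: gain-ratio selection over continuous thresholds
with the C4.5 release-8 MDL correction (`log2(#cuts)/n`) applied to the
ranking — without it, gain ratio degenerates into slicing off single cases —
and pessimistic-error pruning at confidence 0.25. C5.0 itself is
proprietary; what is reproduced is the observable protocol (boosted
axis-aligned trees, 10 trials, 6 folds, cumulative confusion), not its
exact trees. Folds are stratified by group: with 29 + 29 subjects, plain
random folds can produce a single-class training fold, and stratification
keeps fold sizes in {9, 10}. One classifier is trained per (family, length)
cell, mirroring the per-cell presentation of accuracy, sensitivity and
specificity.

## The synthetic cohort generator

No clinical data ship with the package; the generator stands in for the
study's resting-state cohort and its defaults encode the study dimensions:
29 subjects per group, 90 regions, 177 timepoints (180 volumes minus 3
dummy scans) at TR = 2 s. Signals are mixtures of independent fractional
Gaussian noise components (exact Davies–Harte circulant embedding), one
global factor, one factor per module, and idiosyncratic noise, so the
implied region correlation matrix is an exact block structure with
`within_corr` inside modules and `between_corr` elsewhere. Chosen once and
documented here:

* `hurst = 0.8` — in the middle of the long-memory range reported for
  cortical BOLD series (0.5 < H < 1).
* `n_modules = 6` modules of 15 regions — on the order of the canonical
  resting-state systems.
* `within_corr = 0.4`, `between_corr = 0.1` — typical magnitudes of
  scale-2 wavelet correlations in parcellated resting-state data.
* `group_effect = -0.15` applied to the within-module correlation of the
  patient group — hypoconnectivity, built as a *large* effect at the
  connectivity level so that the classification machinery is exercised in
  its high-signal regime; the group difference enters connectivity, not
  signal mean, because every downstream statistic operates on connectivity.
* `effect_scale = j` confines the group difference to one wavelet band by
  adding a module-shared component that is the scale-`j` MRA detail of an
  extra fGn factor; this construction is exact in intent but approximate at
  neighbouring scales (filter leakage), and the ground-truth record carries
  the construction rather than a closed-form band correlation.

What the generator does *not* emulate: hemodynamic response convolution,
subject-level random variation of the connectome beyond finite-sample noise,
motion and physiological artifacts, spatial autocorrelation of parcels, and
non-Gaussian marginals. Passing tests on these cohorts therefore
demonstrate the correctness and calibration of the machinery and the
direction of method effects (e.g. DWT estimates vary more over filter
lengths than MODWT estimates, because scale-j DWT correlations rest on
`N/2^j` coefficients rather than `N`), not clinical effect sizes: the
study's printed t values, F values and accuracy percentages depend on its
non-deposited patient data and are not reproducible from synthetic cohorts.

## Problem sizes used in the tests

The test suite verifies transform identities on series of length 32–177,
graph-metric oracle agreement on 200 random graphs of up to 12 nodes
(exhaustive-partition modularity up to 8 nodes), method-comparison
replication on 20 synthetic cohorts at the full study dimensions
(29 + 29 × 90 × 177), one full-metric classification cohort, and 1000-rep
type-I calibration of each test in the battery. The acceptance script
reruns the same computations at 10 cohorts and 500 calibration replicates.
These sizes were chosen so the whole suite runs in a few minutes on one CPU
while leaving every statistical check adequately powered.

## Known limitations

* Periodic boundary handling is the only option; reflection boundaries
  would change boundary-coefficient behaviour for strongly trending series.
* The partial-correlation estimator uses a plain ridge, not shrinkage
  estimators from the covariance literature.
* The consensus-partition null is one interpretation (label permutation);
  other nulls in the literature differ in detail.
* `run_pipeline()` recomputes rather than caches intermediates; runs are
  deterministic given the config seed, so caching would only save time, and
  at these problem sizes it is not worth the added state.
* The C4.5-style learner implements gain-ratio splits and pessimistic
  pruning but none of C5.0's rule sets, winnowing, or cost matrices.
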