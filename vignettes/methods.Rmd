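---
title: "From labeled single cells to prognosis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From labeled single cells to prognosis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tmerisk` chains five analyses: reference-profile construction from
labeled single cells, reference-based deconvolution of bulk samples,
single-sample gene-set activation scoring, an activation–proportion
association screen, and a Cox risk model with survival stratification.
This vignette explains each model, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does
not emulate.

## Reference profile (RGEP)

Cells are kept when both windows hold inclusively: 200 ≤ expressed
genes ≤ 3,000 and 500 ≤ UMIs ≤ 10,000. The discard rule is phrased as
"fewer than 200 / more than 3,000", so the boundary values are keeps;
`qc_thresholds()` exposes all four numbers. Counts are log-normalized
per cell as $\ln(1 + 10^4\,c_{gj}/\sum_g c_{gj})$; bulk samples as
$\ln(1 + 10^6\,c_{gs}/\sum_g c_{gs})$ (CPM). A pseudocount of 1 sits
inside every log.

Markers are one-vs-rest per type: a gene is a candidate when its
natural-log fold change of linear-scale mean expression is ≥ 0.5 and at
least 10% of cells express it in one of the two groups; candidates are
tested with a two-sided Wilcoxon rank-sum test and Benjamini–Hochberg
correction at 0.05 across the candidates of that type. Natural log is
used throughout for consistency with the normalization (some toolkits
report base-2 fold changes; the threshold is interpreted on the natural
scale here). Degenerate all-tied comparisons carry no evidence and get
p = 1.

The RGEP entry is the mean expression of a signature gene within a cell
type. Averaging is done on **linear CPM** by default: the downstream
mixing model is linear in expression, so averaging on the log scale
would bias the basis. A `lognorm` option is kept for exploratory use.
Types are ordered alphabetically so the profile is invariant to cell
order.

## Deconvolution

Per bulk sample $y$ the solver minimizes
$\sum_g w_g (y_g - \sum_t B_{gt} p_t)^2$ subject to $p \ge 0$, using a
hand-written Lawson–Hanson active-set NNLS inner solve and IRLS weight
updates: residuals are scaled by $1.4826\cdot\mathrm{MAD}$ and passed
through the Tukey bisquare weight $(1-u^2)^2$ for $|u| < 1$ (tuning
constant 4.685; a Huber option with k = 1.345 and an unweighted `none`
mode exist). Convergence is declared when the coefficient vector moves
less than `tol` (relative, default 1e-7) or after `max_iter` = 30
rounds; the final coefficients are renormalized to the unit simplex.
The procedure is deterministic.

Practical guards: estimation needs at least 2 genes shared with the
signature (below 50% overlap a warning is raised); a rank-deficient
basis (duplicated/collinear cell types) is an error naming the
offending columns, because no solver can attribute mass between
identical columns. Because each sample is renormalized, scaling a bulk
column by any positive constant leaves its estimate unchanged — the
method estimates relative, not absolute, composition.

One consequence worth knowing: count-space deconvolution recovers
*read* proportions. They coincide with *cell* proportions when expected
library size is equal across types, which the generator satisfies by
drawing library sizes independently of type; with strongly
type-dependent capture the two would diverge, and no renormalization
can fix that without external information.

## Activation scores

Stage one replaces each gene's expression with a smoothed relative-rank
statistic across samples, $z_{ij} = \frac1n \sum_k
\Phi\!\big((x_{ij}-x_{ik})/h_i\big)$ with bandwidth $h_i =
\mathrm{sd}_i/4$ (an empirical-CDF option exists for count-like data).
This makes scores invariant to any per-gene affine rescaling. Stage two
ranks genes per sample by decreasing $z$ and weights rank $\rho$ by the
symmetric statistic $|N/2 + 1/2 - \rho|^\tau$ ($\tau = 1$), so both
tails of the ranking carry weight. Stage three runs the weighted
KS-like random walk — up by the normalized weight at in-set genes, down
by $1/(N-k)$ otherwise — and reports the **signed difference**
convention: (max positive deviation) + (min negative deviation). The
alternative single-max-deviation convention is available via
`convention = "max"`; the difference convention was chosen as the
default because it produces scores centered near zero under null data,
which suits the downstream correlation screen. Scores always lie in
$[-1, 1]$.

Implementation detail: the walk's extrema are computed from the in-set
gene positions alone ($O(k\log k)$ per set/sample rather than $O(N)$);
the test suite checks this against a brute-force enumeration of the
full walk at 1e-12.

Zero-variance genes are excluded (warning); sets outside the size
window [5, 2000] after intersection with the matrix's genes are dropped
and recorded. Rank ties are broken by gene order, deterministically.

## Association screen

For each retained set $g$ and cell type $C$, $r_{gC}$ is the Pearson
correlation of activation with proportion across samples. Aggregation
uses the Fisher transform, $\bar z_g = \tfrac12 \sum_C
\ln\frac{1+r_{gC}}{1-r_{gC}}$ — the sum of $\operatorname{artanh} r$
over types, so opposite-sign correlations cancel. Correlations at
magnitude ≥ 1 − 1e-7 are clipped (and counted) to keep the transform
finite. Standardization is robust: $S_g = (\bar z_g - \mathrm{median}\,
z)/(1.4826\cdot\mathrm{MAD}\,z)$, with the MAD taken raw and the
normal-consistency constant applied explicitly, so the $S$ vector has
median exactly 0. Selection keeps sets with two-sided normal p-values
strictly below 0.01. Two-sided was chosen because strongly negative
aggregate correlation is as meaningful as positive; a one-sided switch
exists. The population entering the median/MAD is all screened sets.
No multiplicity correction is applied at this stage by design — the
screen is a filter, not an inference, and the raw 1% rule is part of
its definition. MAD-standardization makes the null calibration
approximate rather than exact: with 2000 independent null sets the
selected fraction concentrates near 1% (measured 1.25% at a fixed
seed), and the sd of $S$ for normal $\bar z$ sits near 1.03.

Sets with undefined correlations (constant vectors) are excluded from
aggregation and reported rather than silently dropped.

## Risk model

LASSO-Cox (`glmnet`, features standardized internally, coefficients on
the original scale) with 10-fold cross-validation picks $\lambda_{\min}$
(the deviance minimizer, not the 1-SE rule) and keeps features with
nonzero coefficients there; fold assignment derives from the seed, so
model selection is reproducible. The multivariate Cox refit
(`survival::coxph`, Efron ties — the ecosystem default) uses **all**
LASSO-selected features without further pruning. Monotone likelihoods
(perfect separation) and collinear designs are errors, not silent
near-infinite coefficients. The risk score is the linear predictor
$\sum_i \beta_i x_i$ with no intercept.

Stratification scans every midpoint between adjacent distinct scores
leaving at least `minprop` = 0.1 of samples per side and takes the
threshold maximizing the standardized log-rank statistic. The reported
log-rank p at the chosen cutpoint is **not** corrected for the maximal
selection, a deliberate match to common practice and a known optimism
source — treat it as descriptive, not confirmatory. Kaplan–Meier
curves, Harrell's C (ties at 0.5) and rank-based AUC (midrank
Mann–Whitney) complete the evaluation; two-group comparisons use the
Wilcoxon rank-sum test, exact below combined n = 20 without ties.

## Synthetic data: what it emulates and what it does not

The pool generator draws negative-binomial counts (dispersion
$\phi$, variance $\mu + \phi\mu^2$, default $\phi = 0.4$) around
log-normal relative-abundance profiles; each type's markers have their
relative abundance inflated by $e^{\text{logfc}}$ (default logfc = 2, a
strong but realistic marker contrast); library sizes are log-uniform in
[1500, 6000], inside the QC window, and a chosen fraction of cells is
rebuilt with ~100-UMI or ~20,000-UMI libraries so that exactly
`round(frac_qc_fail × n)` cells violate the thresholds. Pseudo-bulk
mixtures follow the two-stage scheme: Dirichlet proportions (default
concentration 1, i.e. uniform on the simplex — the benchmark's
concentration is not otherwise pinned down), multinomial type counts,
and with-replacement cell draws whose counts are summed. Survival
cohorts give each designated gene set a standard-normal latent
activation that (a) shifts member genes' log-expression by
`effect_size` per unit and (b) is correlated (ρ = 0.8 by default) with
one Dirichlet cell-type proportion, so the screen→LASSO→Cox chain has a
recoverable signal; event times are exponential (Weibull shape 1 —
proportional hazards hold exactly), and censoring is exponential with a
covariate-conditional rate chosen so the censoring probability equals
`censor_rate` exactly while remaining independent of the event time
given the covariates. An earlier design that censored at a uniform
fraction of the event time was rejected because it is informative and
visibly biased Cox coverage.

Not modeled: doublets, ambient RNA, batch effects, platform noise,
type-dependent capture efficiency, non-proportional hazards, or
competing risks. Passing tests therefore demonstrate correctness of the
estimators under a clean generative model, not robustness to those
real-data pathologies.

## Problem sizes and defaults

The shipped demo configuration (8 types × 80 cells, 1,200 genes, 40
mixtures of 2,000 cells, 200 gene sets, 200-patient cohort) runs in
about ten seconds and is the package's reference workload; the
self-mixture benchmark uses the larger canonical setting (15 types,
100 mixtures of 10,000 cells) where pooled true-vs-estimated
correlation reaches ~0.997. Test-suite experiments use 50 replicates
for Cox coverage, 20 seeds for LASSO sensitivity, 500 simulations for
test calibration, and 2,000 sets for screen calibration — sizes at
which the measured quantities are stable to within their asserted
bands.

## Known limitations

Marker p-values are BH-corrected within the pre-filtered candidate set,
not all genes; the cutpoint p-value is selection-optimistic (above);
activation scores are rank-based and hence insensitive to
between-sample normalization but also to magnitude; and the screen's
normal calibration is approximate under heavy dependence between sets
(shared genes induce correlated activations).
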