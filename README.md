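# tmerisk

Cell-type deconvolution and functional gene-set risk modeling for bulk
tumor transcriptomes.

## The problem

Bulk tumor RNA profiles mix many cell populations. Two questions follow:
*what is the cellular composition of each sample*, and *which biological
programs, tied to that composition, predict patient outcome*? `tmerisk`
implements a tested end-to-end workflow for both:

1. **Reference profile (RGEP).** From a labeled single-cell count
   matrix: QC filtering (keep cells with 200–3,000 expressed genes and
   500–10,000 UMIs), log-normalization `ln(1 + 10^4 · c/total)`,
   one-vs-rest Wilcoxon marker selection (natural-log fold change ≥ 0.5,
   min.pct ≥ 0.1, BH-adjusted p ≤ 0.05), signature-gene union, and
   per-type averaging into a signature-genes × cell-types matrix **B**.
2. **Deconvolution.** Per bulk sample *y*, solve the gene-weighted
   non-negative least-squares problem
   min<sub>p ≥ 0</sub> Σ<sub>g</sub> w<sub>g</sub>(y<sub>g</sub> − Σ<sub>t</sub> B<sub>gt</sub> p<sub>t</sub>)²,
   with weights updated by IRLS under a Tukey bisquare loss
   (c = 4.685), then renormalize *p* to the unit simplex.
3. **Activation scores.** Per sample and gene set, a GSVA-style
   statistic: Gaussian-kernel CDF per gene (bandwidth sd/4), decreasing
   rank, and a weighted Kolmogorov–Smirnov random walk summarized as
   (max positive deviation) + (min negative deviation) ∈ [−1, 1].
4. **Association screen.** Pearson correlations r<sub>gC</sub> of each
   set *g* with each cell-type proportion *C* are aggregated by the
   Fisher Z-transformation, z̄<sub>g</sub> = ½ Σ<sub>C</sub>
   ln((1+r<sub>gC</sub>)/(1−r<sub>gC</sub>)), standardized robustly,
   S<sub>g</sub> = (z̄<sub>g</sub> − median z)/(1.4826 · MAD z), and
   kept when the two-sided normal p-value is below 0.01.
5. **Risk model.** LASSO-Cox (cross-validated λ·min) selects among the
   screened sets; a multivariate Cox refit gives coefficients β; the
   risk score is the linear predictor Σ β<sub>i</sub>x<sub>i</sub>,
   dichotomized at the maximally selected log-rank cutpoint and
   evaluated by Kaplan–Meier curves, the log-rank test, Harrell's C and
   rank-based AUC.

A synthetic-data module generates every input — negative-binomial cell
pools with planted markers and QC violators, Dirichlet-proportioned
pseudo-bulk mixtures, and survival cohorts whose hazard depends
log-linearly on designated gene-set activations — so all stages are
testable offline with known ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on
synthetic data and write their tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_build_rgep.R
Rscript analysis/03_deconvolve.R
Rscript analysis/04_score_gene_sets.R
Rscript analysis/05_association_screen.R
Rscript analysis/06_survival_model.R
```

Output of a full run (seed 20260101, 8 cell types, 640 cells, 200
gene sets, 200-patient cohort):

```
pool: 1200 genes x 640 cells, 8 types, 32 planted QC violators
QC: kept 608 of 640 cells
markers: 241 genes across 8 types (median 30 per type)
RGEP: 241 signature genes x 8 cell types (linear_cpm scale)
self-mixture benchmark over 40 samples: pooled r = 0.9942, RMSE = 0.0112
activation scores: 200 sets x 200 samples (dropped: 0), range [-0.983, 0.993]
screen: 5 of 200 sets selected at P < 0.01
designated prognostic sets among selected: SET_00001, SET_00002
LASSO-Cox: 2 of 5 screened sets kept at lambda.min = 0.03917
risk model concordance: 0.733
cutpoint 0.316 splits 78 high / 122 low; log-rank p = 3.75e-18
```

Reading this: deconvolution recovers the known mixing proportions
almost exactly (pooled Pearson r = 0.994 across all sample × type
pairs); the screen finds exactly the two gene sets whose activations
were built to track cell-type proportions and drive the hazard; the
LASSO-Cox refit recovers their effect signs (β = +1.06 / −1.42 for
planted +0.8 / −0.8 on the latent scale); and the resulting risk score
splits the cohort into groups with clearly separated survival.

The same chain is available as one call:

```r
library(tmerisk)
run_pipeline(pipeline_config(seed = 1), "results/demo")
```

which also writes a `manifest.json` with the full parameterization and
MD5 hashes of every output (two runs with the same seed are
bit-identical).

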