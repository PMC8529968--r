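# Shared configuration for the numbered analysis scripts.
# Each script sources this file, runs one stage of the workflow and
# writes its tables under results/analysis/.

suppressPackageStartupMessages(library(tmerisk))

OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

CFG <- pipeline_config(
  seed = 20260101,
  # labeled single-cell pool emulating a tumor-microenvironment atlas
  n_types = 8, n_genes = 1200, cells_per_type = 80,
  markers_per_type = 30, marker_logfc = 2, frac_qc_fail = 0.05,
  # pseudo-bulk benchmark
  n_mixtures = 40, cells_per_sample = 2000,
  # functional gene sets + survival cohort
  n_gene_sets = 200, n_cohort = 200, beta_true = c(0.8, -0.8),
  censor_rate = 0.3)

# eight stand-in immune/stromal type names for readability of outputs
TYPE_NAMES <- c("monocyte", "macrophage", "dendritic", "t_naive",
                "t_cytotoxic", "t_reg", "b_cell", "fibroblast")

LINEAGE_MAP <- c(monocyte = "myeloid", macrophage = "myeloid",
                 dendritic = "myeloid", t_naive = "t_cell",
                 t_cytotoxic = "t_cell", t_reg = "t_cell",
                 b_cell = "b_cell", fibroblast = "stromal")
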