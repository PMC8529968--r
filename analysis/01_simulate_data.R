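#!/usr/bin/env Rscript
# Stage 1: generate every input the downstream analyses need — a
# labeled single-cell pool with planted markers and QC violators, a
# random functional gene-set collection, and a survival cohort whose
# hazard depends on two designated gene sets.

source("analysis/00_config.R")

sc_cfg <- sc_sim_config(
  n_types = CFG$n_types, n_genes = CFG$n_genes,
  cells_per_type = CFG$cells_per_type,
  markers_per_type = CFG$markers_per_type,
  marker_logfc = CFG$marker_logfc, frac_qc_fail = CFG$frac_qc_fail,
  seed = CFG$seed, type_names = TYPE_NAMES)
pool <- simulate_cell_pool(sc_cfg)
write_pool(pool, file.path(OUT, "pool"))
cat(sprintf("pool: %d genes x %d cells, %d types, %d planted QC violators\n",
            nrow(pool$counts), ncol(pool$counts),
            length(pool$cell_types), length(pool$qc_fail_cells)))

coll <- random_gene_sets(pool$gene_ids, CFG$n_gene_sets,
                         size_range = CFG$set_size_range,
                         seed = CFG$seed + 1)
write_gmt(coll, file.path(OUT, "gene_sets.gmt"))

beta <- CFG$beta_true
names(beta) <- names(coll$sets)[seq_along(beta)]
truth <- surv_cohort_truth(beta, baseline_scale = CFG$baseline_scale,
                           censor_rate = CFG$censor_rate,
                           seed = CFG$seed + 2)
coh <- simulate_survival_cohort(CFG$n_cohort, coll, truth,
                                effect_size = CFG$cohort_effect_size,
                                rho_prop = CFG$cohort_rho_prop,
                                n_types = 5)
write_expr_tsv(coh$expr, file.path(OUT, "cohort_expr.tsv"))
write_survival_tsv(coh$survival, file.path(OUT, "cohort_survival.tsv"))
write_proportions_tsv(coh$proportions,
                      file.path(OUT, "cohort_proportions.tsv"))
jsonlite::write_json(list(beta_true = as.list(beta)),
                     file.path(OUT, "cohort_truth.json"), auto_unbox = TRUE)
cat(sprintf("cohort: %d samples, %.0f%% events, prognostic sets: %s\n",
            CFG$n_cohort, 100 * mean(coh$survival$event),
            paste(names(beta), collapse = ", ")))
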