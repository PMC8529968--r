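#!/usr/bin/env Rscript
# Stage 5: screen gene sets for association with cellular proportions:
# Pearson correlations per (set, type), Fisher-Z aggregation across
# types, median/MAD standardization, and selection at P < 0.01 on the
# standard normal.

source("analysis/00_config.R")

scores <- read_expr_tsv(file.path(OUT, "activation_scores.tsv"))
props <- read_proportions_tsv(file.path(OUT, "cohort_proportions.tsv"))

tab <- associate_screen(scores, props, alpha = CFG$alpha_screen)
write.table(tab, file.path(OUT, "association.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(n_sets = nrow(tab), n_selected = sum(tab$selected),
       n_clipped = attr(tab, "n_clipped"),
       excluded = attr(tab, "excluded_sets")),
  file.path(OUT, "association_report.json"), auto_unbox = TRUE)

truth <- jsonlite::read_json(file.path(OUT, "cohort_truth.json"))
designated <- names(truth$beta_true)
cat(sprintf("screen: %d of %d sets selected at P < %.2f\n",
            sum(tab$selected), nrow(tab), CFG$alpha_screen))
cat(sprintf("designated prognostic sets among selected: %s\n",
            paste(intersect(designated, tab$set[tab$selected]),
                  collapse = ", ")))
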