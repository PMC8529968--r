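#!/usr/bin/env Rscript
# Stage 4: single-sample activation scores of every functional gene set
# for the survival cohort (kernel-CDF rank random walk, signed
# difference convention).

source("analysis/00_config.R")

expr <- read_expr_tsv(file.path(OUT, "cohort_expr.tsv"))
coll <- read_gmt(file.path(OUT, "gene_sets.gmt"))

scores <- activation_scores(expr, coll)
write_expr_tsv(scores, file.path(OUT, "activation_scores.tsv"))
cat(sprintf("activation scores: %d sets x %d samples (dropped: %d), range [%.3f, %.3f]\n",
            nrow(scores), ncol(scores), length(attr(scores, "dropped")),
            min(scores), max(scores)))
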