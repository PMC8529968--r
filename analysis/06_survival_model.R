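#!/usr/bin/env Rscript
# Stage 6: LASSO-Cox feature selection over the screened gene sets,
# multivariate Cox refit, linear risk scores, optimal cutpoint, KM
# curves, log-rank test and group comparison of the risk score.

source("analysis/00_config.R")

scores <- read_expr_tsv(file.path(OUT, "activation_scores.tsv"))
tab <- read.table(file.path(OUT, "association.tsv"), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
surv <- read_survival_tsv(file.path(OUT, "cohort_survival.tsv"))

selected <- tab$set[tab$selected]
feats <- t(scores[selected, surv$sample, drop = FALSE])
sdat <- survival_data(surv$sample, surv$time, surv$event, feats)

lasso <- lasso_cox(sdat, n_folds = CFG$n_folds, seed = CFG$seed + 20)
cat(sprintf("LASSO-Cox: %d of %d screened sets kept at lambda.min = %.4g\n",
            length(lasso$selected), length(selected), lasso$lambda_min))

refit <- fit_cox(survival_data(sdat$sample, sdat$time, sdat$event,
                               sdat$features[, lasso$selected,
                                             drop = FALSE]))
print(refit)
risk <- risk_score(refit, sdat$features)
write.table(data.frame(sample = names(risk), risk = unname(risk)),
            file.path(OUT, "risk_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cut <- optimal_cutpoint(risk, sdat$time, sdat$event,
                        minprop = CFG$minprop)
grp <- ifelse(risk > cut$threshold, "high", "low")
lr <- log_rank(sdat$time, sdat$event, grp)
km <- km_estimate(sdat$time, sdat$event, grp)
write.table(km, file.path(OUT, "km_curves.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

gd <- group_difference_test(risk, grp)
jsonlite::write_json(
  list(model = as.list(refit$beta), concordance = refit$concordance,
       cutpoint = cut$threshold, n_high = cut$n_high, n_low = cut$n_low,
       logrank_chisq = lr$chisq, logrank_p = lr$p,
       ranksum_p = gd$p),
  file.path(OUT, "stratification.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("risk model concordance: %.3f\n", refit$concordance))
cat(sprintf("cutpoint %.3f splits %d high / %d low; log-rank p = %.3g\n",
            cut$threshold, cut$n_high, cut$n_low, lr$p))
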