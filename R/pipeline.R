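#' Assemble and validate a pipeline configuration
#'
#' One flat configuration drives the whole workflow: simulation sizes,
#' QC/marker thresholds, screen and model parameters, stage toggles and
#' the master seed (every stage derives its own child seed from it).
#' Any field can be overridden; unknown fields are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    # synthetic pool
    n_types = 8, n_genes = 1200, cells_per_type = 80,
    markers_per_type = 30, marker_logfc = 2, nb_dispersion = 0.4,
    libsize_range = c(1500, 6000), frac_qc_fail = 0.05,
    # QC + markers
    min_genes = 200, max_genes = 3000, min_umis = 500, max_umis = 10000,
    logfc_threshold = 0.5, min_pct = 0.1, max_adj_p = 0.05,
    # mixtures
    n_mixtures = 40, cells_per_sample = 2000, dirichlet_alpha = 1,
    # deconvolution
    robust_loss = "tukey_bisquare", rgep_scale = "linear_cpm",
    # gene sets + cohort
    n_gene_sets = 200, set_size_range = c(10, 40),
    n_cohort = 200, beta_true = c(0.8, -0.8), cohort_effect_size = 1,
    cohort_rho_prop = 0.8, censor_rate = 0.3, baseline_scale = 5,
    # screen + model
    alpha_screen = 0.01, n_folds = 10, minprop = 0.1,
    # stage toggles
    run_simulate = TRUE, run_rgep = TRUE, run_deconv = TRUE,
    run_score = TRUE, run_associate = TRUE, run_fit = TRUE,
    run_stratify = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(cfg$seed == as.integer(cfg$seed))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' @param path YAML file of key-value pairs (fields of
#'   [pipeline_config()]).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

stage_step <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full workflow end to end
#'
#' Executes simulate, RGEP building, deconvolution benchmark, gene-set
#' scoring, association screen, LASSO-Cox + multivariate Cox fit and
#' risk stratification in order, writing each stage's outputs under
#' `out_dir` and a `manifest.json` with parameters and per-file MD5
#' hashes. Deterministic for a fixed seed. A disabled stage leaves its
#' outputs absent; downstream stages then abort with a clean error
#' naming the stage.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())

  if (config$run_simulate) stage_step("simulate", {
    sc_cfg <- sc_sim_config(
      n_types = config$n_types, n_genes = config$n_genes,
      cells_per_type = config$cells_per_type,
      markers_per_type = config$markers_per_type,
      marker_logfc = config$marker_logfc,
      nb_dispersion = config$nb_dispersion,
      libsize_range = config$libsize_range,
      frac_qc_fail = config$frac_qc_fail,
      seed = child_seed(config$seed, 11))
    state$pool <- simulate_cell_pool(sc_cfg)
    write_pool(state$pool, file.path(out_dir, "pool"))
    state$collection <- random_gene_sets(
      state$pool$gene_ids, config$n_gene_sets,
      size_range = config$set_size_range,
      seed = child_seed(config$seed, 12))
    write_gmt(state$collection, file.path(out_dir, "gene_sets.gmt"))
    designated <- names(state$collection$sets)[seq_along(config$beta_true)]
    beta <- config$beta_true
    names(beta) <- designated
    truth <- surv_cohort_truth(beta, baseline_scale = config$baseline_scale,
                               censor_rate = config$censor_rate,
                               seed = child_seed(config$seed, 13))
    state$cohort <- simulate_survival_cohort(
      config$n_cohort, state$collection, truth,
      effect_size = config$cohort_effect_size,
      rho_prop = config$cohort_rho_prop,
      n_types = min(5, config$n_types))
    write_expr_tsv(state$cohort$expr, file.path(out_dir, "cohort_expr.tsv"))
    write_survival_tsv(state$cohort$survival,
                       file.path(out_dir, "cohort_survival.tsv"))
    write_proportions_tsv(state$cohort$proportions,
                          file.path(out_dir, "cohort_proportions.tsv"))
    jsonlite::write_json(
      list(beta_true = as.list(beta), censor_rate = config$censor_rate,
           baseline_scale = config$baseline_scale),
      file.path(out_dir, "cohort_truth.json"), auto_unbox = TRUE)
  })

  if (config$run_rgep) stage_step("rgep", {
    if (is.null(state$pool)) stop("missing input: no simulated pool")
    thr <- qc_thresholds(config$min_genes, config$max_genes,
                         config$min_umis, config$max_umis)
    qc <- qc_filter_cells(state$pool$counts, thr)
    labels <- state$pool$labels[qc$kept]
    norm <- normalize_sc(qc$counts)
    markers <- find_markers(norm, labels,
                            marker_criteria(config$logfc_threshold,
                                            config$min_pct,
                                            config$max_adj_p))
    state$signature <- merge_signature_sets(
      split(markers$gene, markers$type),
      universe = rownames(qc$counts))
    state$rgep <- build_rgep(qc$counts, labels, state$signature,
                             scale = config$rgep_scale)
    state$qc_counts <- qc$counts
    state$qc_labels <- labels
    write_rgep(state$rgep, file.path(out_dir, "rgep.tsv"))
    utils::write.table(markers, file.path(out_dir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  if (config$run_deconv) stage_step("deconv", {
    if (is.null(state$rgep)) stop("missing input: no RGEP")
    mix <- simulate_mixtures(state$pool, config$n_mixtures,
                             config$cells_per_sample,
                             alpha = config$dirichlet_alpha,
                             seed = child_seed(config$seed, 21))
    res <- deconvolve(mix$bulk, state$rgep,
                      deconv_options(robust_loss = config$robust_loss))
    metrics <- evaluate_deconv(mix$truth, res)
    write_proportions_tsv(res$proportions,
                          file.path(out_dir, "mixture_proportions_est.tsv"))
    write_proportions_tsv(mix$truth$proportions,
                          file.path(out_dir, "mixture_proportions_true.tsv"))
    jsonlite::write_json(
      list(pearson_r_pooled = metrics$pearson_r_pooled,
           rmse = metrics$rmse),
      file.path(out_dir, "deconv_metrics.json"), auto_unbox = TRUE,
      digits = NA)
    state$deconv_metrics <- metrics
  })

  if (config$run_score) stage_step("score", {
    if (is.null(state$cohort)) stop("missing input: no cohort")
    state$scores <- activation_scores(state$cohort$expr, state$collection)
    write_expr_tsv(state$scores, file.path(out_dir, "activation_scores.tsv"))
  })

  if (config$run_associate) stage_step("associate", {
    if (is.null(state$scores)) stop("missing input: no activation scores")
    tab <- associate_screen(state$scores, state$cohort$proportions,
                            alpha = config$alpha_screen)
    state$assoc <- tab
    utils::write.table(tab, file.path(out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(n_sets = nrow(tab), n_selected = sum(tab$selected),
           n_clipped = attr(tab, "n_clipped") %||% 0,
           excluded = attr(tab, "excluded_sets") %||% character(0)),
      file.path(out_dir, "association_report.json"), auto_unbox = TRUE)
  })

  if (config$run_fit) stage_step("fit", {
    if (is.null(state$assoc))
      stop("missing input: association screen has not run")
    selected <- state$assoc$set[state$assoc$selected]
    if (length(selected) < 2)
      stop("fewer than 2 gene sets passed the screen")
    feats <- t(state$scores[selected, , drop = FALSE])
    sdat <- survival_data(state$cohort$survival$sample,
                          state$cohort$survival$time,
                          state$cohort$survival$event,
                          feats[state$cohort$survival$sample, , drop = FALSE])
    lasso <- lasso_cox(sdat, n_folds = config$n_folds,
                       seed = child_seed(config$seed, 31))
    if (length(lasso$selected) == 0)
      stop("LASSO selected no features")
    refit <- fit_cox(survival_data(sdat$sample, sdat$time, sdat$event,
                                   sdat$features[, lasso$selected,
                                                 drop = FALSE]))
    state$model <- refit
    state$risk <- risk_score(refit, sdat$features)
    jsonlite::write_json(
      list(screen_selected = selected, lasso_selected = lasso$selected,
           lambda_min = lasso$lambda_min,
           beta = as.list(refit$beta), concordance = refit$concordance,
           seed = config$seed),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(
      data.frame(sample = names(state$risk), risk = unname(state$risk)),
      file.path(out_dir, "risk_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  })

  if (config$run_stratify) stage_step("stratify", {
    if (is.null(state$risk)) stop("missing input: no risk scores")
    surv <- state$cohort$survival
    cut <- optimal_cutpoint(state$risk[surv$sample], surv$time, surv$event,
                            minprop = config$minprop)
    grp <- ifelse(state$risk[surv$sample] > cut$threshold, "high", "low")
    lr <- log_rank(surv$time, surv$event, grp)
    km <- km_estimate(surv$time, surv$event, grp)
    utils::write.table(km, file.path(out_dir, "km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(threshold = cut$threshold, statistic = cut$statistic,
           n_low = cut$n_low, n_high = cut$n_high,
           logrank_chisq = lr$chisq, logrank_p = lr$p),
      file.path(out_dir, "stratification.json"), auto_unbox = TRUE,
      digits = NA)
    state$stratification <- lr
  })

  # manifest: full parameterization + hashes of every written file
  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  manifest <- list(config = unclass(config), files = hashes,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
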