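#' Configuration for a synthetic labeled single-cell pool
#'
#' Describes a negative-binomial single-cell count generator with
#' cell-type structure: each type carries a block of marker genes whose
#' mean expression is inflated by `exp(marker_logfc)` relative to the
#' background, per-cell library sizes are drawn log-uniformly within
#' `libsize_range`, and a fraction of cells is deliberately constructed
#' to violate the downstream quality-control thresholds (so that QC
#' filtering has something to remove).
#'
#' @param n_types number of cell types.
#' @param n_genes number of genes in the pool.
#' @param cells_per_type integer vector (length 1 or `n_types`) of cells
#'   per type.
#' @param markers_per_type number of marker genes planted per type
#'   (disjoint blocks).
#' @param marker_logfc natural-log fold change of marker genes in their
#'   own type versus background.
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @param libsize_range length-2 vector, low < high: target per-cell UMI
#'   totals are drawn log-uniformly in this range. Keep it inside the QC
#'   UMI window so only constructed violators fail QC.
#' @param frac_qc_fail fraction of cells built to violate at least one QC
#'   threshold (tiny or oversized libraries).
#' @param seed integer seed.
#' @param type_names optional character vector of type names.
#' @return an object of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_types = 15, n_genes = 2000,
                          cells_per_type = 120, markers_per_type = 40,
                          marker_logfc = 2, nb_dispersion = 0.4,
                          libsize_range = c(1500, 6000),
                          frac_qc_fail = 0.05, seed = 1,
                          type_names = NULL) {
  if (n_types < 1 || n_genes < 1)
    stop("n_types and n_genes must be positive", call. = FALSE)
  if (length(cells_per_type) == 1L)
    cells_per_type <- rep(cells_per_type, n_types)
  if (length(cells_per_type) != n_types || any(cells_per_type < 1))
    stop("cells_per_type must be positive, length 1 or n_types", call. = FALSE)
  if (markers_per_type < 0 || markers_per_type * n_types > n_genes)
    stop("markers_per_type * n_types must not exceed n_genes", call. = FALSE)
  if (marker_logfc < 0) stop("marker_logfc must be >= 0", call. = FALSE)
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive", call. = FALSE)
  if (length(libsize_range) != 2L || libsize_range[1] <= 0 ||
      libsize_range[1] >= libsize_range[2])
    stop("libsize_range must satisfy 0 < low < high", call. = FALSE)
  if (frac_qc_fail < 0 || frac_qc_fail > 1)
    stop("frac_qc_fail must lie in [0,1]", call. = FALSE)
  if (is.null(type_names))
    type_names <- sprintf("type%02d", seq_len(n_types))
  stopifnot(length(type_names) == n_types)
  structure(list(n_types = n_types, n_genes = n_genes,
                 cells_per_type = cells_per_type,
                 markers_per_type = markers_per_type,
                 marker_logfc = marker_logfc,
                 nb_dispersion = nb_dispersion,
                 libsize_range = libsize_range,
                 frac_qc_fail = frac_qc_fail,
                 seed = as.integer(seed),
                 type_names = type_names),
            class = "sc_sim_config")
}

#' Simulate a labeled single-cell count pool
#'
#' Draws negative-binomial UMI counts with per-type marker structure.
#' Each gene has a background relative-abundance weight (log-normal);
#' within type t the weights of t's marker block are multiplied by
#' `exp(marker_logfc)` and renormalized, so markers have their mean
#' inflated by that factor relative to non-marker genes. Per-cell
#' library sizes are log-uniform in `libsize_range`. Exactly
#' `round(frac_qc_fail * n_cells)` cells are constructed as QC violators:
#' alternating tiny libraries (~100 UMIs, below the 500-UMI / 200-gene
#' floors) and oversized libraries (~2x the 10,000-UMI ceiling).
#'
#' @param config an [sc_sim_config()].
#' @return a list of class `cell_pool` with elements `counts`
#'   (genes x cells integer matrix), `gene_ids`, `cell_ids`, `labels`
#'   (type per cell), `cell_types` (declared type order), `truth`
#'   (named list: marker gene ids per type) and `qc_fail_cells`
#'   (ids of constructed violators).
#' @export
simulate_cell_pool <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  types <- config$type_names
  n_cells <- sum(config$cells_per_type)
  gene_ids <- sprintf("G%05d", seq_len(G))
  cell_ids <- sprintf("C%05d", seq_len(n_cells))
  labels <- rep(types, times = config$cells_per_type)

  # background relative abundance; log-normal gives a realistic skew
  base_w <- stats::rlnorm(G, meanlog = 0, sdlog = 1)
  # disjoint marker blocks at the head of the gene list
  truth <- list()
  marker_idx <- matrix(NA_integer_, nrow = 0, ncol = 0)
  k <- config$markers_per_type
  for (t in seq_along(types)) {
    idx <- if (k > 0) ((t - 1) * k + 1):(t * k) else integer(0)
    truth[[types[t]]] <- gene_ids[idx]
  }

  # per-type expected relative expression profiles
  profiles <- matrix(base_w, nrow = G, ncol = length(types))
  for (t in seq_along(types)) {
    idx <- match(truth[[types[t]]], gene_ids)
    profiles[idx, t] <- profiles[idx, t] * exp(config$marker_logfc)
  }
  profiles <- sweep(profiles, 2, colSums(profiles), "/")
  colnames(profiles) <- types

  # library sizes: log-uniform in range; then overwrite the violators
  lr <- log(config$libsize_range)
  libsize <- exp(stats::runif(n_cells, lr[1], lr[2]))
  n_fail <- round(config$frac_qc_fail * n_cells)
  qc_fail_cells <- character(0)
  if (n_fail > 0) {
    fail_idx <- unique(round(seq(1, n_cells, length.out = n_fail)))
    if (length(fail_idx) < n_fail) fail_idx <- seq_len(n_fail)
    # alternate tiny and oversized libraries
    low <- fail_idx[seq_along(fail_idx) %% 2 == 1]
    high <- fail_idx[seq_along(fail_idx) %% 2 == 0]
    libsize[low] <- 100
    libsize[high] <- 20000
    qc_fail_cells <- cell_ids[sort(fail_idx)]
  }

  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, nrow = G, ncol = n_cells,
                   dimnames = list(gene_ids, cell_ids))
  for (t in seq_along(types)) {
    cols <- which(labels == types[t])
    mu <- outer(profiles[, t], libsize[cols])
    counts[, cols] <- matrix(
      stats::rnbinom(length(mu), size = size, mu = mu),
      nrow = G)
  }
  storage.mode(counts) <- "integer"

  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 labels = labels, cell_types = types, truth = truth,
                 qc_fail_cells = qc_fail_cells,
                 profiles = profiles, config = config),
            class = "cell_pool")
}

#' @export
print.cell_pool <- function(x, ...) {
  cat("cell_pool:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      length(x$cell_types), "types\n")
  invisible(x)
}

#' Simulate Dirichlet-proportioned pseudo-bulk mixtures
#'
#' For each sample, cell-type proportions are drawn from a Dirichlet
#' distribution; `cells_per_sample` cell barcodes are then sampled with
#' replacement in two stages (multinomial type counts on the drawn
#' proportions, then uniform draws within each type) and their counts
#' aggregated into one bulk column.
#'
#' @param pool a `cell_pool`.
#' @param n_samples number of pseudo-bulk samples.
#' @param cells_per_sample cells aggregated per sample (>= 1).
#' @param alpha Dirichlet concentration vector, one entry per cell type
#'   in `pool$cell_types` (a scalar is recycled).
#' @param seed integer seed.
#' @return list with `bulk` (genes x samples integer matrix) and `truth`,
#'   a `mixture_truth` object holding the drawn `proportions`
#'   (samples x types, rows on the unit simplex), `cells_per_sample` and
#'   `alpha`.
#' @export
simulate_mixtures <- function(pool, n_samples, cells_per_sample, alpha,
                              seed = 1) {
  stopifnot(inherits(pool, "cell_pool"))
  if (ncol(pool$counts) == 0L) stop("empty pool", call. = FALSE)
  types <- pool$cell_types
  if (length(alpha) == 1L) alpha <- rep(alpha, length(types))
  if (length(alpha) != length(types))
    stop("alpha length must equal the number of cell types", call. = FALSE)
  if (any(alpha <= 0)) stop("alpha entries must be positive", call. = FALSE)
  if (cells_per_sample < 1) stop("cells_per_sample must be >= 1", call. = FALSE)

  set.seed(seed)
  props <- rdirichlet(n_samples, alpha)
  colnames(props) <- types
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  rownames(props) <- sample_ids

  by_type <- lapply(types, function(t) which(pool$labels == t))
  names(by_type) <- types
  if (any(vapply(by_type, length, 1L) == 0L))
    stop("pool has cell types with zero cells", call. = FALSE)

  bulk <- matrix(0, nrow = nrow(pool$counts), ncol = n_samples,
                 dimnames = list(pool$gene_ids, sample_ids))
  for (s in seq_len(n_samples)) {
    n_t <- as.vector(stats::rmultinom(1, cells_per_sample, props[s, ]))
    w <- numeric(ncol(pool$counts))
    for (t in seq_along(types)) {
      if (n_t[t] == 0) next
      cells <- by_type[[t]]
      draw <- sample(cells, n_t[t], replace = TRUE)
      tab <- tabulate(draw, nbins = ncol(pool$counts))
      w <- w + tab
    }
    bulk[, s] <- as.vector(pool$counts %*% w)
  }
  truth <- structure(list(proportions = props,
                          cells_per_sample = cells_per_sample,
                          alpha = alpha),
                     class = "mixture_truth")
  list(bulk = bulk, truth = truth)
}

#' Ground-truth parameters for a synthetic survival cohort
#'
#' @param beta_true named numeric vector of log-hazard coefficients over
#'   designated gene sets.
#' @param baseline_scale positive scale of the exponential baseline
#'   (expected survival time at linear predictor 0).
#' @param censor_rate probability in \[0,1\] that a sample is
#'   independently censored.
#' @param seed integer seed.
#' @return object of class `surv_cohort_truth`.
#' @export
surv_cohort_truth <- function(beta_true, baseline_scale = 5,
                              censor_rate = 0.3, seed = 1) {
  if (baseline_scale <= 0) stop("baseline_scale must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate > 1)
    stop("censor_rate must lie in [0,1]", call. = FALSE)
  if (is.null(names(beta_true)) && length(beta_true) > 0)
    stop("beta_true must be named by gene set", call. = FALSE)
  structure(list(beta_true = beta_true, baseline_scale = baseline_scale,
                 censor_rate = censor_rate, seed = as.integer(seed)),
            class = "surv_cohort_truth")
}

#' Simulate a bulk cohort whose survival depends on gene-set activations
#'
#' Generates a bulk expression matrix, a survival table and the latent
#' per-sample risk. Each designated gene set (the names of
#' `truth$beta_true`) gets a latent activation `a ~ N(0,1)` per sample;
#' member genes of that set have their (log-scale) expression shifted by
#' `effect_size * a`. Event times are exponential with hazard
#' proportional to `exp(beta_true' a)`; censoring is independent with
#' probability `censor_rate` (censored times are uniform on (0, T)).
#'
#' To make the activation -> proportion association screen recoverable,
#' each designated set's latent activation is correlated (coefficient
#' `rho_prop`) with one cell-type proportion of a Dirichlet-drawn
#' proportion matrix that is returned alongside; set `rho_prop = 0` for
#' activations independent of proportions.
#'
#' @param n_samples number of samples (>= 10).
#' @param gene_sets a `gene_set_collection` (see [read_gmt()]); every
#'   designated set must be present.
#' @param truth a [surv_cohort_truth()].
#' @param genes character vector: the gene universe of the expression
#'   matrix (defaults to the union of collection genes plus 200
#'   background genes).
#' @param effect_size log-scale expression shift per unit latent
#'   activation for member genes.
#' @param noise_sd residual log-expression noise s.d.
#' @param rho_prop correlation between each designated set's latent
#'   activation and its paired cell-type proportion.
#' @param n_types number of cell types in the returned proportion matrix.
#' @param alpha Dirichlet concentration for the proportions.
#' @return list with `expr` (log-scale genes x samples), `survival`
#'   (data.frame: sample, time, event), `latent` (samples x designated
#'   sets), `risk` (true linear predictor per sample), `proportions`
#'   (samples x types) and `truth`.
#' @export
simulate_survival_cohort <- function(n_samples, gene_sets, truth,
                                     genes = NULL, effect_size = 1,
                                     noise_sd = 0.5, rho_prop = 0.8,
                                     n_types = 5, alpha = 1) {
  stopifnot(inherits(truth, "surv_cohort_truth"))
  if (n_samples < 10) stop("n_samples must be >= 10", call. = FALSE)
  sets <- gene_sets$sets
  designated <- names(truth$beta_true)
  missing_sets <- setdiff(designated, names(sets))
  if (length(missing_sets))
    stop("designated gene sets absent from collection: ",
         paste(missing_sets, collapse = ", "), call. = FALSE)
  if (abs(rho_prop) > 1) stop("rho_prop must lie in [-1,1]", call. = FALSE)

  set.seed(truth$seed)
  if (is.null(genes))
    genes <- union(unique(unlist(sets)), sprintf("BG%04d", 1:200))
  G <- length(genes)
  sample_ids <- sprintf("P%04d", seq_len(n_samples))

  if (length(alpha) == 1L) alpha <- rep(alpha, n_types)
  props <- rdirichlet(n_samples, alpha)
  colnames(props) <- sprintf("type%02d", seq_len(n_types))
  rownames(props) <- sample_ids

  # latent activations, optionally tied to a cell-type proportion
  D <- length(designated)
  latent <- matrix(stats::rnorm(n_samples * max(D, 1)), nrow = n_samples)
  if (D > 0) {
    latent <- latent[, seq_len(D), drop = FALSE]
    colnames(latent) <- designated
    if (rho_prop != 0) {
      for (d in seq_len(D)) {
        ty <- ((d - 1) %% n_types) + 1
        z <- as.vector(scale(props[, ty]))
        latent[, d] <- rho_prop * z + sqrt(1 - rho_prop^2) * latent[, d]
      }
    }
  } else {
    latent <- matrix(0, nrow = n_samples, ncol = 0)
  }

  base_mu <- stats::rnorm(G, mean = 5, sd = 1.5)
  expr <- matrix(base_mu, nrow = G, ncol = n_samples) +
    matrix(stats::rnorm(G * n_samples, sd = noise_sd), nrow = G)
  dimnames(expr) <- list(genes, sample_ids)
  for (d in seq_along(designated)) {
    members <- intersect(sets[[designated[d]]], genes)
    expr[members, ] <- expr[members, ] +
      matrix(rep(effect_size * latent[, d], each = length(members)),
             nrow = length(members))
  }

  lp <- as.vector(latent %*% truth$beta_true)
  if (length(lp) == 0) lp <- rep(0, n_samples)
  rate_ev <- exp(lp) / truth$baseline_scale
  t_event <- stats::rexp(n_samples, rate = rate_ev)
  # exponential censoring, independent of the event time given the
  # covariates; rate chosen so P(censored) = censor_rate exactly
  cr <- truth$censor_rate
  if (cr <= 0) {
    time <- t_event
    event <- rep(1L, n_samples)
  } else if (cr >= 1) {
    time <- stats::rexp(n_samples, rate = rate_ev)
    event <- rep(0L, n_samples)
  } else {
    t_cens <- stats::rexp(n_samples, rate = rate_ev * cr / (1 - cr))
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  survival <- data.frame(sample = sample_ids, time = time, event = event,
                         stringsAsFactors = FALSE)

  list(expr = expr, survival = survival, latent = latent, risk = lp,
       proportions = props, truth = truth)
}
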