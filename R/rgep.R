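#' Quality-control thresholds for single-cell filtering
#'
#' Cells are kept iff `min_genes <= #expressed genes <= max_genes` and
#' `min_umis <= total UMIs <= max_umis` (bounds inclusive: the discard
#' rule is strictly-below/strictly-above the window).
#'
#' @param min_genes,max_genes window on the number of genes with count > 0.
#' @param min_umis,max_umis window on the per-cell UMI total.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 3000,
                          min_umis = 500, max_umis = 10000) {
  if (min_genes >= max_genes || min_umis >= max_umis)
    stop("QC windows must satisfy min < max", call. = FALSE)
  if (min_genes <= 0 || min_umis <= 0)
    stop("QC thresholds must be positive", call. = FALSE)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_umis = min_umis, max_umis = max_umis),
            class = "qc_thresholds")
}

#' Filter cells by expressed-gene and UMI-count windows
#'
#' @param counts non-negative integer matrix, genes x cells.
#' @param thresholds a [qc_thresholds()].
#' @return list with `counts` (kept columns) and `kept` (logical index
#'   over the input cells).
#' @export
qc_filter_cells <- function(counts, thresholds = qc_thresholds()) {
  assert_matrix_like(counts, "counts")
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n_genes <- Matrix::colSums(counts > 0)
  n_umis <- Matrix::colSums(counts)
  kept <- n_genes >= thresholds$min_genes & n_genes <= thresholds$max_genes &
    n_umis >= thresholds$min_umis & n_umis <= thresholds$max_umis
  list(counts = counts[, kept, drop = FALSE], kept = kept)
}

#' Log-normalize single-cell counts
#'
#' Per cell: `ln(1 + scale * count / cell_total)` with `scale = 10000`.
#'
#' @param counts non-negative matrix, genes x cells; no all-zero cells
#'   (they should have been removed by QC).
#' @param scale library-size scale factor.
#' @return dense numeric matrix of the same shape.
#' @export
normalize_sc <- function(counts, scale = 10000) {
  assert_matrix_like(counts, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cells with zero total count present; run QC filtering first",
         call. = FALSE)
  x <- as.matrix(counts)
  log1p(sweep(x, 2, totals, "/") * scale)
}

#' CPM + natural-log normalize a bulk matrix
#'
#' Per sample: `ln(1 + 1e6 * count / column_total)`.
#'
#' @param counts non-negative matrix, genes x samples, positive column sums.
#' @return numeric matrix of the same shape.
#' @export
normalize_bulk <- function(counts) {
  assert_matrix_like(counts, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("samples with zero total count cannot be CPM-normalized",
         call. = FALSE)
  x <- as.matrix(counts)
  log1p(sweep(x, 2, totals, "/") * 1e6)
}

#' Marker-gene selection criteria
#'
#' @param logfc_threshold minimum natural-log fold change of linear-scale
#'   mean expression (one type vs the rest).
#' @param min_pct minimum fraction of expressing cells required in at
#'   least one of the two groups.
#' @param max_adj_p Benjamini-Hochberg adjusted p-value ceiling for the
#'   rank-sum test.
#' @return object of class `marker_criteria`.
#' @export
marker_criteria <- function(logfc_threshold = 0.5, min_pct = 0.1,
                            max_adj_p = 0.05) {
  if (logfc_threshold < 0) stop("logfc_threshold must be >= 0", call. = FALSE)
  if (min_pct < 0 || min_pct > 1) stop("min_pct must lie in [0,1]",
                                       call. = FALSE)
  structure(list(logfc_threshold = logfc_threshold, min_pct = min_pct,
                 max_adj_p = max_adj_p), class = "marker_criteria")
}

#' One-vs-rest marker genes per cell type
#'
#' For each type, candidate genes must have natural-log fold change of
#' linear-scale mean expression (in-type vs rest) at or above
#' `logfc_threshold` and a fraction of expressing cells of at least
#' `min_pct` in one of the two groups; candidates are then tested by a
#' two-sided Wilcoxon rank-sum test on the normalized expression, with
#' Benjamini-Hochberg correction across the candidates of that type.
#' Fold changes are computed on the linear scale implied by the
#' log-normalized input (`expm1`), with a pseudocount of 1 inside each log.
#'
#' @param norm log-normalized matrix, genes x cells (see [normalize_sc()]).
#' @param labels cell-type label per column.
#' @param criteria a [marker_criteria()].
#' @return data.frame with columns `type`, `gene`, `avg_logfc`, `pct_in`,
#'   `pct_out`, `p`, `p_adj`, sorted by type then decreasing fold change.
#'   Types with fewer than 3 cells are skipped with a warning.
#' @export
find_markers <- function(norm, labels, criteria = marker_criteria()) {
  assert_matrix_like(norm, "norm")
  if (length(labels) != ncol(norm))
    stop("labels length must equal the number of cells", call. = FALSE)
  types <- unique(labels)
  if (length(types) < 2)
    stop("need at least 2 cell types", call. = FALSE)
  lin <- expm1(norm)
  out <- vector("list", length(types))
  for (ti in seq_along(types)) {
    t <- types[ti]
    in_cells <- which(labels == t)
    out_cells <- which(labels != t)
    if (length(in_cells) < 3) {
      warning("type '", t, "' has fewer than 3 cells; skipped",
              call. = FALSE)
      next
    }
    mean_in <- rowMeans(lin[, in_cells, drop = FALSE])
    mean_out <- rowMeans(lin[, out_cells, drop = FALSE])
    lfc <- log(mean_in + 1) - log(mean_out + 1)
    pct_in <- rowMeans(norm[, in_cells, drop = FALSE] > 0)
    pct_out <- rowMeans(norm[, out_cells, drop = FALSE] > 0)
    cand <- which(lfc >= criteria$logfc_threshold &
                    pmax(pct_in, pct_out) >= criteria$min_pct)
    if (length(cand) == 0) next
    p <- vapply(cand, function(g) {
      suppressWarnings(stats::wilcox.test(norm[g, in_cells],
                                          norm[g, out_cells])$p.value)
    }, numeric(1))
    p[is.na(p)] <- 1  # degenerate (all-tied) comparisons carry no evidence
    p_adj <- stats::p.adjust(p, method = "BH")
    keep <- p_adj <= criteria$max_adj_p
    if (!any(keep)) next
    tab <- data.frame(type = t, gene = rownames(norm)[cand][keep],
                      avg_logfc = lfc[cand][keep],
                      pct_in = pct_in[cand][keep],
                      pct_out = pct_out[cand][keep],
                      p = p[keep], p_adj = p_adj[keep],
                      stringsAsFactors = FALSE)
    out[[ti]] <- tab[order(-tab$avg_logfc), ]
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(type = character(0), gene = character(0),
                      avg_logfc = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), p = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Merge signature gene lists into a deduplicated union
#'
#' Order-stable union of one or more gene lists, optionally restricted to
#' a gene universe (e.g. the rownames of the expression matrix); absent
#' genes are reported via the `dropped` attribute.
#'
#' @param lists a character vector or list of character vectors.
#' @param universe optional character vector of admissible genes.
#' @return character vector of unique signature genes, with attribute
#'   `dropped` (genes absent from `universe`).
#' @export
merge_signature_sets <- function(lists, universe = NULL) {
  if (!is.list(lists)) lists <- list(lists)
  genes <- unique(unlist(lists, use.names = FALSE))
  dropped <- character(0)
  if (!is.null(universe)) {
    dropped <- setdiff(genes, universe)
    genes <- genes[genes %in% universe]
  }
  if (length(genes) == 0)
    stop("signature union is empty", call. = FALSE)
  attr(genes, "dropped") <- dropped
  genes
}

#' Build a reference gene expression profile (RGEP)
#'
#' Averages expression per cell type over the signature genes. With
#' `scale = "linear_cpm"` the input counts are converted to per-cell CPM
#' before averaging (the deconvolution basis is linear in expression);
#' with `scale = "lognorm"` averaging is done on the log-normalized
#' values of [normalize_sc()].
#'
#' @param counts genes x cells count matrix (after QC).
#' @param labels cell-type label per cell; every type needs >= 1 cell.
#' @param signature_genes genes to retain as rows (must be present).
#' @param scale `"linear_cpm"` (default) or `"lognorm"`.
#' @return object of class `rgep`: list with `profile` (signature genes
#'   x types), `signature_genes`, `cell_types`, `scale`.
#' @export
build_rgep <- function(counts, labels, signature_genes,
                       scale = c("linear_cpm", "lognorm")) {
  scale <- match.arg(scale)
  assert_matrix_like(counts, "counts")
  if (length(labels) != ncol(counts))
    stop("labels length must equal the number of cells", call. = FALSE)
  if (anyDuplicated(signature_genes))
    stop("signature_genes contains duplicates", call. = FALSE)
  missing_g <- setdiff(signature_genes, rownames(counts))
  if (length(missing_g))
    stop("signature genes absent from matrix: ",
         paste(utils::head(missing_g, 5), collapse = ", "), call. = FALSE)
  types <- sort(unique(labels))  # sorted: invariant to cell order
  n_per <- table(factor(labels, levels = types))
  if (any(n_per == 0)) stop("cell type with zero cells", call. = FALSE)

  expr <- if (scale == "linear_cpm") {
    totals <- Matrix::colSums(counts)
    if (any(totals == 0)) stop("cells with zero totals present", call. = FALSE)
    sweep(as.matrix(counts), 2, totals, "/") * 1e6
  } else {
    normalize_sc(counts)
  }
  expr <- expr[signature_genes, , drop = FALSE]
  profile <- vapply(types, function(t) {
    rowMeans(expr[, labels == t, drop = FALSE])
  }, numeric(length(signature_genes)))
  profile <- matrix(profile, nrow = length(signature_genes),
                    dimnames = list(signature_genes, types))
  if (any(colSums(profile > 0) == 0))
    stop("RGEP column with no positive entry", call. = FALSE)
  structure(list(profile = profile, signature_genes = signature_genes,
                 cell_types = types, scale = scale),
            class = "rgep")
}

#' @export
print.rgep <- function(x, ...) {
  cat("RGEP:", length(x$signature_genes), "signature genes x",
      length(x$cell_types), "cell types (scale:", x$scale, ")\n")
  invisible(x)
}
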