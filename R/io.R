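#' Write a labeled cell pool as MTX + sidecar TSVs
#'
#' Writes `counts.mtx` (MatrixMarket), `genes.tsv`, `barcodes.tsv` and
#' `labels.tsv` (barcode, cell_type) into `dir`.
#'
#' @param pool a `cell_pool`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pool <- function(pool, dir) {
  stopifnot(inherits(pool, "cell_pool"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(pool$counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "counts.mtx"))
  writeLines(pool$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(pool$cell_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(barcode = pool$cell_ids, cell_type = pool$labels),
    file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a labeled cell pool written by [write_pool()]
#'
#' @param dir directory holding `counts.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, `labels.tsv`.
#' @return a `cell_pool` (without simulation truth).
#' @export
read_pool <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  storage.mode(counts) <- "integer"
  gene_ids <- readLines(file.path(dir, "genes.tsv"))
  cell_ids <- readLines(file.path(dir, "barcodes.tsv"))
  lab <- utils::read.table(file.path(dir, "labels.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  dimnames(counts) <- list(gene_ids, cell_ids)
  labels <- lab$cell_type[match(cell_ids, lab$barcode)]
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 labels = labels, cell_types = unique(labels),
                 truth = NULL, qc_fail_cells = character(0)),
            class = "cell_pool")
}

#' Write / read a genes-x-samples expression matrix as TSV
#'
#' First column `gene`, remaining columns one per sample.
#'
#' @param mat numeric matrix with gene rownames.
#' @param path TSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_expr_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expr_tsv
#' @export
read_expr_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a samples-x-types proportion matrix as TSV
#'
#' @param proportions samples x types matrix with sample rownames.
#' @param path TSV path.
#' @export
write_proportions_tsv <- function(proportions, path) {
  df <- data.frame(sample = rownames(proportions), proportions,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proportions_tsv
#' @export
read_proportions_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a survival table (sample, time, event) as TSV
#'
#' @param survival data.frame with columns `sample`, `time`, `event`.
#' @param path TSV path.
#' @export
write_survival_tsv <- function(survival, path) {
  stopifnot(all(c("sample", "time", "event") %in% names(survival)))
  utils::write.table(survival, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write an RGEP as TSV plus a JSON sidecar
#'
#' The TSV holds the profile (rows = signature genes, header = cell
#' types); the sidecar records the scale and dimensions.
#'
#' @param rgep an `rgep`.
#' @param path TSV path; the sidecar is `<path>.json`.
#' @export
write_rgep <- function(rgep, path) {
  stopifnot(inherits(rgep, "rgep"))
  write_expr_tsv(rgep$profile, path)
  meta <- list(scale = rgep$scale,
               n_signature_genes = length(rgep$signature_genes),
               cell_types = rgep$cell_types)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rgep
#' @export
read_rgep <- function(path) {
  profile <- read_expr_tsv(path)
  meta_path <- paste0(path, ".json")
  scale <- "linear_cpm"
  if (file.exists(meta_path))
    scale <- jsonlite::read_json(meta_path)$scale
  structure(list(profile = profile, signature_genes = rownames(profile),
                 cell_types = colnames(profile), scale = scale),
            class = "rgep")
}
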