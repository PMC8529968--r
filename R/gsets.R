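#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one tab-separated line per set — name, description,
#' then member genes. Duplicate member genes within a set are dropped.
#'
#' @param path GMT file path.
#' @return object of class `gene_set_collection`: list with `sets`
#'   (named list of character vectors), `descriptions`, `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than 3 fields", call. = FALSE)
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1], call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  desc <- vapply(parts, `[[`, "", 2L)
  names(desc) <- nm
  gene_set_collection(sets, descriptions = desc, source = path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (unique names required).
#' @param descriptions optional per-set descriptions.
#' @param source free-text tag for provenance.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, source = "") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names", call. = FALSE)
  if (is.null(descriptions)) {
    descriptions <- rep("", length(sets))
    names(descriptions) <- names(sets)
  }
  structure(list(sets = sets, descriptions = descriptions, source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat("gene_set_collection:", length(x$sets), "sets; sizes",
      min(sz), "-", max(sz), "\n")
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]] %||% "",
            collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Generate a random gene-set collection
#'
#' Fixture generator: draws `n_sets` sets of sizes uniform in
#' `size_range` from `genes`, without replacement within a set.
#'
#' @param genes gene universe.
#' @param n_sets number of sets.
#' @param size_range length-2 integer vector of set sizes.
#' @param seed integer seed.
#' @param prefix set-name prefix.
#' @return a `gene_set_collection`.
#' @export
random_gene_sets <- function(genes, n_sets, size_range = c(10, 50),
                             seed = 1, prefix = "SET") {
  stopifnot(n_sets >= 1, size_range[1] >= 1,
            size_range[2] <= length(genes))
  set.seed(seed)
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(genes, k))
  names(sets) <- sprintf("%s_%05d", prefix, seq_len(n_sets))
  gene_set_collection(sets, source = "random_gene_sets")
}

# Gaussian-kernel CDF relative-expression statistic: for gene i,
# z_ij = mean_k Phi((x_ij - x_ik) / h_i), bandwidth h_i = sd_i / 4.
kcdf_stat <- function(x, kernel = c("gaussian", "ecdf")) {
  kernel <- match.arg(kernel)
  n <- ncol(x)
  if (kernel == "gaussian") {
    h <- apply(x, 1, stats::sd) / 4
    z <- x
    for (i in seq_len(nrow(x))) {
      d <- outer(x[i, ], x[i, ], "-") / h[i]
      z[i, ] <- rowMeans(stats::pnorm(d))
    }
    z
  } else {
    t(apply(x, 1, function(v) {
      vapply(v, function(vi) mean(v <= vi), numeric(1))
    }))
  }
}

# Walk extrema from in-set rank positions alone. Positions p (sorted
# increasing) of the k set genes in the N-long decreasing ranking,
# weights w aligned with p. The walk steps up w/W at set genes and down
# 1/(N-k) elsewhere; extrema occur just after (max) and just before
# (min) in-set steps.
walk_extrema <- function(p, w, N) {
  k <- length(p)
  o <- order(p)
  p <- p[o]; w <- w[o]
  W <- sum(w)
  cw <- cumsum(w) / W
  i <- seq_len(k)
  dec <- 1 / (N - k)
  after <- cw - (p - i) * dec
  before <- c(0, cw[-k]) - (p - 1 - (i - 1)) * dec
  list(max_pos = max(0, after), min_neg = min(0, before, after))
}

#' Single-sample gene-set activation scores
#'
#' For each sample and gene set, computes a GSVA-style activation score:
#' (1) per gene, a kernel-smoothed cumulative-distribution statistic of
#' the sample's expression relative to all samples (Gaussian kernel with
#' bandwidth sd/4, or a plain empirical CDF); (2) per sample, genes are
#' ranked by this statistic in decreasing order and given the symmetric
#' rank weight `|N/2 + 1/2 - rank|^tau`; (3) a weighted
#' Kolmogorov-Smirnov-like random walk over the ranking (up by the
#' normalized weight at in-set genes, down by `1/(N - k)` otherwise) is
#' summarized as the signed difference `max positive deviation + min
#' negative deviation` (convention `"diff"`), or as the single deviation
#' of largest magnitude (`"max"`).
#'
#' Genes with zero variance across samples are excluded with a warning;
#' sets falling outside `[min_size, max_size]` after intersection with
#' the matrix genes are dropped and recorded in the `dropped` attribute.
#'
#' @param expr genes x samples matrix on a continuous scale; >= 3 samples.
#' @param collection a `gene_set_collection`.
#' @param kernel `"gaussian"` (default) or `"ecdf"`.
#' @param tau rank-weight exponent.
#' @param convention `"diff"` (default) or `"max"`.
#' @param min_size,max_size retained set-size window after gene
#'   intersection.
#' @return sets x samples numeric matrix with attributes `kernel`,
#'   `tau`, `convention`, `dropped` (names of dropped sets) and
#'   `set_sizes`. All entries lie in \[-1, 1\].
#' @export
activation_scores <- function(expr, collection,
                              kernel = c("gaussian", "ecdf"), tau = 1,
                              convention = c("diff", "max"),
                              min_size = 5, max_size = 2000) {
  kernel <- match.arg(kernel)
  convention <- match.arg(convention)
  assert_matrix_like(expr, "expr")
  stopifnot(inherits(collection, "gene_set_collection"))
  if (ncol(expr) < 3)
    stop("need >= 3 samples for the kernel statistic", call. = FALSE)
  if (is.null(rownames(expr))) stop("expr needs gene rownames", call. = FALSE)

  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance genes excluded", call. = FALSE)
    expr <- expr[sds > 0, , drop = FALSE]
  }
  genes <- rownames(expr)
  N <- length(genes)

  sets <- lapply(collection$sets, function(g) {
    i <- match(intersect(g, genes), genes)
    i[!is.na(i)]
  })
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  dropped <- names(sets)[!keep]
  sets <- sets[keep]
  if (length(sets) == 0)
    stop("no gene set retained after size filtering", call. = FALSE)

  z <- kcdf_stat(expr, kernel)
  n_samp <- ncol(expr)
  scores <- matrix(NA_real_, length(sets), n_samp,
                   dimnames = list(names(sets), colnames(expr)))
  half <- N / 2 + 0.5
  for (j in seq_len(n_samp)) {
    ord <- order(z[, j], seq_len(N), decreasing = c(TRUE, FALSE),
                 method = "radix")
    pos_of_gene <- integer(N)
    pos_of_gene[ord] <- seq_len(N)
    rank_w <- abs(half - seq_len(N))^tau  # weight by position in ranking
    for (si in seq_along(sets)) {
      p <- pos_of_gene[sets[[si]]]
      ex <- walk_extrema(p, rank_w[p], N)
      scores[si, j] <- if (convention == "diff") {
        ex$max_pos + ex$min_neg
      } else {
        if (ex$max_pos >= -ex$min_neg) ex$max_pos else ex$min_neg
      }
    }
  }
  attr(scores, "kernel") <- kernel
  attr(scores, "tau") <- tau
  attr(scores, "convention") <- convention
  attr(scores, "dropped") <- dropped
  attr(scores, "set_sizes") <- lengths(sets)
  scores
}
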