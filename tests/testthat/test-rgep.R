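test_that("QC keeps cells inside the inclusive windows only", {
  # one cell per scenario; 250 genes available
  make_cell <- function(n_expressed, total) {
    v <- integer(250)
    v[seq_len(n_expressed)] <- 1L
    v[1] <- v[1] + as.integer(total - n_expressed)
    v
  }
  counts <- cbind(
    low_genes = make_cell(150, 600),    # 150 expressed genes -> removed
    ok = make_cell(210, 600),
    low_umi = make_cell(210, 400),      # 400 UMIs -> removed
    edge = make_cell(200, 500))         # exactly at the floors -> kept
  rownames(counts) <- sprintf("g%03d", 1:250)
  res <- qc_filter_cells(counts)
  expect_equal(unname(res$kept), c(FALSE, TRUE, FALSE, TRUE))

  # all cells in bounds: identity
  ok <- counts[, c("ok", "edge")]
  res2 <- qc_filter_cells(ok)
  expect_identical(res2$counts, ok)

  # idempotence
  res3 <- qc_filter_cells(res$counts)
  expect_true(all(res3$kept))
})

test_that("QC removes exactly the planted violators", {
  set.seed(21)
  n_genes <- 400
  good <- sapply(1:93, function(i) {
    v <- integer(n_genes)
    on <- sample(n_genes, 250)
    v[on] <- as.integer(rmultinom(1, 2000, rep(1, 250)))
    v
  })
  bad <- sapply(1:7, function(i) {
    v <- integer(n_genes)
    v[sample(n_genes, 50)] <- 1L  # 50 genes, 50 UMIs: violates both floors
    v
  })
  counts <- cbind(good, bad)
  rownames(counts) <- sprintf("g%03d", seq_len(n_genes))
  res <- qc_filter_cells(counts)
  expect_equal(sum(res$kept), 93)
  expect_equal(which(!res$kept), 94:100)
})

test_that("log-normalization matches the closed form and the oracle", {
  # single-gene cell: count 5, total 5 -> ln(10001)
  m <- matrix(c(5, 0), nrow = 2, dimnames = list(c("a", "b"), "c1"))
  norm <- normalize_sc(m)
  expect_equal(norm["a", 1], log(10001))
  expect_equal(norm["b", 1], 0)

  set.seed(31)
  x <- matrix(rpois(100, 5) + 1, 10, 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:10)))
  got <- normalize_sc(x)
  # independent elementwise oracle
  want <- x
  for (j in 1:10) for (i in 1:10)
    want[i, j] <- log(1 + 10000 * x[i, j] / sum(x[, j]))
  expect_equal(got, want, tolerance = 1e-12)

  x0 <- x; x0[, 3] <- 0
  expect_error(normalize_sc(x0), "zero total")
})

test_that("bulk CPM-log normalization is exact and scale invariant", {
  m <- matrix(0, 5, 1, dimnames = list(paste0("g", 1:5), "s1"))
  m[2, 1] <- 7
  expect_equal(normalize_bulk(m)[2, 1], log(1 + 1e6))

  set.seed(32)
  x <- matrix(rpois(60, 20) + 1, 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  got <- normalize_bulk(x)
  want <- x
  for (j in 1:10) for (i in 1:6)
    want[i, j] <- log(1 + 1e6 * x[i, j] / sum(x[, j]))
  expect_equal(got, want, tolerance = 1e-12)

  x2 <- x; x2[, 4] <- x[, 4] * 2
  expect_equal(normalize_bulk(x2)[, 4], got[, 4], tolerance = 1e-12)
})

test_that("marker filters respect min.pct and flat genes are never markers", {
  set.seed(41)
  n <- 40  # cells per group
  norm <- matrix(rnorm(6 * 2 * n, mean = 2, sd = 0.1), nrow = 6)
  rownames(norm) <- paste0("g", 1:6)
  labels <- rep(c("A", "B"), each = n)
  # g6: expressed in 5% of cells of both groups, huge fold change
  norm[6, ] <- 0
  hot <- c(sample(which(labels == "A"), 2), sample(which(labels == "B"), 2))
  norm[6, hot[1:2]] <- 8
  mk <- find_markers(norm, labels,
                     marker_criteria(logfc_threshold = 0.1, min_pct = 0.1))
  expect_false("g6" %in% mk$gene)
  # flat genes g1..g5 are absent everywhere
  expect_false(any(paste0("g", 1:5) %in% mk$gene))
})

test_that("rank-sum p on a 3v3 toy equals the exact permutation oracle", {
  vals <- c(1.3, 2.1, 0.7, 3.9, 4.4, 5.1)
  labels <- rep(c("A", "B"), each = 3)
  norm <- rbind(gX = vals, gflat = rep(1, 6))
  # make gX pass the lfc/pct filters for type B
  mk <- find_markers(norm, labels,
                     marker_criteria(logfc_threshold = 0, min_pct = 0,
                                     max_adj_p = 1))
  p_pkg <- mk$p[mk$gene == "gX" & mk$type == "B"]
  # exhaustive permutation: all C(6,3) assignments of ranks to group A
  r <- rank(vals)
  W_obs <- sum(r[labels == "A"])
  combos <- combn(6, 3)
  W_null <- apply(combos, 2, function(i) sum(r[i]))
  p_exact <- mean(abs(W_null - mean(W_null)) >= abs(W_obs - mean(W_null)))
  expect_equal(p_pkg, p_exact, tolerance = 1e-12)
})

test_that("marker tables are invariant to cell order", {
  p <- tiny_pool(seed = 17)
  norm <- normalize_sc(p$counts)
  mk1 <- find_markers(norm, p$labels)
  set.seed(1)
  perm <- sample(ncol(norm))
  mk2 <- find_markers(norm[, perm], p$labels[perm])
  o1 <- mk1[order(mk1$type, mk1$gene), ]
  o2 <- mk2[order(mk2$type, mk2$gene), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2, tolerance = 1e-12)
})

test_that("signature union deduplicates, keeps order and drops absent genes", {
  expect_equal(merge_signature_sets(list(c("A", "B"), c("B", "C"))),
               c("A", "B", "C"), ignore_attr = TRUE)
  expect_equal(merge_signature_sets(c("A", "A", "B")), c("A", "B"),
               ignore_attr = TRUE)
  u <- merge_signature_sets(list(c("A", "B"), c("C")), universe = c("A", "C"))
  expect_equal(as.vector(u), c("A", "C"))
  expect_equal(attr(u, "dropped"), "B")
  expect_error(merge_signature_sets(list("X"), universe = "Y"), "empty")

  # inclusion-exclusion oracle on planted overlap structure
  set.seed(51)
  pool_genes <- sprintf("g%04d", 1:3000)
  sizes <- c(750, 547, 317, 635)
  lists <- lapply(sizes, function(k) sample(pool_genes, k))
  got <- length(merge_signature_sets(lists))
  want <- length(Reduce(union, lists))  # set-arithmetic oracle
  expect_equal(got, want)
})

test_that("RGEP equals the groupby mean and ignores cell order", {
  # one cell per type: profile equals those cells' expression columns
  counts <- matrix(c(10, 0, 5, 0, 8, 2), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  rg <- build_rgep(counts, c("A", "B"), c("g1", "g2", "g3"))
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  expect_equal(unname(rg$profile), unname(cpm), tolerance = 1e-12)

  p <- tiny_pool(seed = 19)
  sig <- p$gene_ids[1:50]
  rg1 <- build_rgep(p$counts, p$labels, sig)
  set.seed(2)
  perm <- sample(ncol(p$counts))
  rg2 <- build_rgep(p$counts[, perm], p$labels[perm], sig)
  expect_identical(rg1$profile, rg2$profile)

  # groupby-mean oracle on linear CPM
  cpm <- sweep(p$counts, 2, colSums(p$counts), "/") * 1e6
  for (t in p$cell_types) {
    want <- rowMeans(cpm[sig, p$labels == t])
    expect_equal(rg1$profile[, t], want, tolerance = 1e-12)
  }

  # log-scale option agrees with a mean of normalize_sc values
  rg3 <- build_rgep(p$counts, p$labels, sig, scale = "lognorm")
  norm <- normalize_sc(p$counts)
  expect_equal(rg3$profile[, 1],
               rowMeans(norm[sig, p$labels == p$cell_types[1]]),
               tolerance = 1e-12)

  expect_error(build_rgep(p$counts, p$labels, c(sig, sig[1])), "duplicates")
  expect_error(build_rgep(p$counts, p$labels, c(sig, "nope")), "absent")
})
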