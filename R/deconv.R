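# Lawson-Hanson active-set non-negative least squares.
# Solves min ||A x - b||^2 subject to x >= 0. A has few columns here
# (cell types), so the active-set loop is cheap and exact.
nnls_solve <- function(A, b, tol = 1e-10, max_iter = NULL) {
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 10 * n
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      P <- which(passive)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) {
        x <- z
        break
      }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Options for reference-based deconvolution
#'
#' @param robust_loss `"tukey_bisquare"` (default), `"huber"`, or
#'   `"none"` (all gene weights fixed at 1, i.e. plain non-negative
#'   least squares).
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the proportion estimate.
#' @param nonneg constrain coefficients to be non-negative.
#' @param sum_to_one renormalize each sample's coefficients to the unit
#'   simplex.
#' @param tukey_c,huber_k tuning constants of the robust losses.
#' @return object of class `deconv_options`.
#' @export
deconv_options <- function(robust_loss = c("tukey_bisquare", "huber", "none"),
                           max_iter = 30, tol = 1e-7, nonneg = TRUE,
                           sum_to_one = TRUE, tukey_c = 4.685,
                           huber_k = 1.345) {
  robust_loss <- match.arg(robust_loss)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  structure(list(robust_loss = robust_loss, max_iter = max_iter, tol = tol,
                 nonneg = nonneg, sum_to_one = sum_to_one,
                 tukey_c = tukey_c, huber_k = huber_k),
            class = "deconv_options")
}

#' Estimate cell-type proportions by weighted robust regression
#'
#' Per bulk sample, solves a gene-weighted non-negative least-squares
#' problem against the RGEP columns, with weights updated by iteratively
#' reweighted least squares under the chosen robust loss (Tukey bisquare
#' by default, residuals scaled by 1.4826 x MAD), then renormalizes the
#' coefficients to the unit simplex. Deterministic for fixed inputs.
#'
#' Bulk and RGEP must be on comparable linear scales; only shared genes
#' are used (warning below 50% signature overlap, error below 2 genes).
#'
#' @param bulk genes x samples matrix (linear scale).
#' @param rgep an [build_rgep()] result (or a bare matrix genes x types).
#' @param options a [deconv_options()].
#' @return object of class `deconv_result`: `proportions` (samples x
#'   types), `residual_norm` per sample, `weights` (shared genes x
#'   samples), `converged` logical per sample, `genes_used`.
#' @export
deconvolve <- function(bulk, rgep, options = deconv_options()) {
  assert_matrix_like(bulk, "bulk")
  B <- if (inherits(rgep, "rgep")) rgep$profile else rgep
  assert_matrix_like(B, "rgep")
  if (is.null(rownames(bulk)) || is.null(rownames(B)))
    stop("bulk and RGEP need gene rownames", call. = FALSE)

  shared <- intersect(rownames(B), rownames(bulk))
  if (length(shared) < 2)
    stop("fewer than 2 genes shared between bulk and RGEP", call. = FALSE)
  if (length(shared) < 0.5 * nrow(B))
    warning("less than 50% of signature genes found in bulk",
            call. = FALSE)
  B <- B[shared, , drop = FALSE]
  Y <- as.matrix(bulk)[shared, , drop = FALSE]

  # collinearity check: a rank-deficient basis cannot be resolved
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    cc <- stats::cor(B)
    diag(cc) <- 0
    pair <- which(abs(cc) > 1 - 1e-8, arr.ind = TRUE)
    who <- if (nrow(pair)) {
      paste(unique(colnames(B)[pair[, 1]]), collapse = ", ")
    } else {
      paste(colnames(B)[qrB$pivot[(qrB$rank + 1):ncol(B)]], collapse = ", ")
    }
    stop("RGEP is rank deficient; collinear cell types: ", who,
         call. = FALSE)
  }

  n_s <- ncol(Y)
  n_t <- ncol(B)
  P <- matrix(0, n_s, n_t, dimnames = list(colnames(Y), colnames(B)))
  W <- matrix(1, length(shared), n_s, dimnames = list(shared, colnames(Y)))
  rn <- numeric(n_s)
  conv <- logical(n_s)

  solve_wls <- function(A, y, nonneg) {
    if (nonneg) nnls_solve(A, y)
    else as.vector(qr.coef(qr(A), y))
  }

  for (s in seq_len(n_s)) {
    y <- Y[, s]
    w <- rep(1, length(y))
    coef_prev <- rep(Inf, n_t)
    coef <- numeric(n_t)
    n_iter <- if (options$robust_loss == "none") 1L else options$max_iter
    for (it in seq_len(n_iter)) {
      sw <- sqrt(w)
      coef <- solve_wls(B * sw, y * sw, options$nonneg)
      coef[is.na(coef)] <- 0
      scale_ref <- max(sum(abs(coef)), .Machine$double.eps)
      if (max(abs(coef - coef_prev)) < options$tol * scale_ref) {
        conv[s] <- TRUE
        break
      }
      coef_prev <- coef
      if (options$robust_loss == "none") { conv[s] <- TRUE; break }
      r <- y - as.vector(B %*% coef)
      sc <- 1.4826 * stats::median(abs(r - stats::median(r)))
      if (sc <= 0) { conv[s] <- TRUE; break }
      if (options$robust_loss == "tukey_bisquare") {
        u <- r / (options$tukey_c * sc)
        w_new <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      } else { # huber
        u <- abs(r / sc)
        w_new <- pmin(1, options$huber_k / pmax(u, .Machine$double.eps))
      }
      if (all(w_new == 0)) { conv[s] <- TRUE; break }  # keep previous weights
      w <- w_new
    }
    if (options$nonneg) coef[coef < 0] <- 0
    rn[s] <- sqrt(sum((y - as.vector(B %*% coef))^2))
    if (options$sum_to_one) {
      coef <- if (sum(coef) > 0) coef / sum(coef) else rep(1 / n_t, n_t)
    }
    P[s, ] <- coef
    W[, s] <- w
  }

  structure(list(proportions = P, residual_norm = rn, weights = W,
                 converged = conv, genes_used = shared,
                 options = options),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat("deconv_result:", nrow(x$proportions), "samples x",
      ncol(x$proportions), "cell types;", length(x$genes_used),
      "genes used\n")
  invisible(x)
}

#' Score estimated proportions against the ground truth
#'
#' @param truth a `mixture_truth` (or a bare samples x types matrix).
#' @param result a `deconv_result` (or a bare matrix).
#' @return list of class `deconv_metrics`: `pearson_r_pooled` over all
#'   (sample, type) pairs, `pearson_r_per_sample`, and `rmse`.
#' @export
evaluate_deconv <- function(truth, result) {
  Tm <- if (inherits(truth, "mixture_truth")) truth$proportions else truth
  Em <- if (inherits(result, "deconv_result")) result$proportions else result
  if (!all(dim(Tm) == dim(Em)))
    stop("truth and estimate shapes differ", call. = FALSE)
  if (!is.null(rownames(Tm)) && !is.null(rownames(Em)) &&
      setequal(rownames(Tm), rownames(Em)))
    Em <- Em[rownames(Tm), , drop = FALSE]
  if (!is.null(colnames(Tm)) && !is.null(colnames(Em)) &&
      setequal(colnames(Tm), colnames(Em)))
    Em <- Em[, colnames(Tm), drop = FALSE]
  r_pooled <- stats::cor(as.vector(Tm), as.vector(Em))
  r_per <- vapply(seq_len(nrow(Tm)), function(i)
    stats::cor(Tm[i, ], Em[i, ]), numeric(1))
  rmse <- sqrt(mean((Tm - Em)^2))
  structure(list(pearson_r_pooled = r_pooled, pearson_r_per_sample = r_per,
                 rmse = rmse), class = "deconv_metrics")
}

#' Aggregate fine cell-type proportions into lineages
#'
#' @param proportions samples x fine-types matrix.
#' @param mapping named character vector: `names(mapping)` are fine
#'   types, values are lineage names. Must cover all columns.
#' @return samples x lineages matrix; rows keep their simplex sums.
#' @export
aggregate_types <- function(proportions, mapping) {
  assert_matrix_like(proportions, "proportions")
  fine <- colnames(proportions)
  unmapped <- setdiff(fine, names(mapping))
  if (length(unmapped))
    stop("unmapped cell types: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  lineages <- unique(unname(mapping[fine]))
  out <- vapply(lineages, function(L) {
    members <- fine[mapping[fine] == L]
    rowSums(proportions[, members, drop = FALSE])
  }, numeric(nrow(proportions)))
  out <- matrix(out, nrow = nrow(proportions),
                dimnames = list(rownames(proportions), lineages))
  out
}
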