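#' Correlate gene-set activations with cell-type proportions
#'
#' Pearson correlation across samples for every (gene set, cell type)
#' pair. Sample ids are aligned by name (activation columns vs
#' proportion rows). Pairs involving a constant vector are recorded as
#' `NA` with a warning; sets with any undefined pair are flagged via the
#' `undefined_sets` attribute so the Fisher aggregation can exclude them.
#'
#' @param activations sets x samples matrix (see [activation_scores()]).
#' @param proportions samples x cell-types matrix.
#' @return sets x types correlation matrix with attribute
#'   `undefined_sets`.
#' @export
correlate_sets_types <- function(activations, proportions) {
  assert_matrix_like(activations, "activations")
  assert_matrix_like(proportions, "proportions")
  if (!is.null(colnames(activations)) && !is.null(rownames(proportions))) {
    shared <- intersect(colnames(activations), rownames(proportions))
    if (length(shared) < 3)
      stop("fewer than 3 shared samples", call. = FALSE)
    activations <- activations[, shared, drop = FALSE]
    proportions <- proportions[shared, , drop = FALSE]
  } else if (ncol(activations) != nrow(proportions)) {
    stop("sample dimensions do not match and no ids to align by",
         call. = FALSE)
  }
  if (ncol(activations) < 3) stop("need >= 3 samples", call. = FALSE)

  const_a <- apply(activations, 1, stats::sd) == 0
  const_p <- apply(proportions, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(t(activations), proportions))
  if (any(const_a) || any(const_p)) {
    warning("constant activation or proportion vectors produce undefined ",
            "correlations", call. = FALSE)
  }
  undefined <- rownames(r)[apply(r, 1, function(v) any(!is.finite(v)))]
  attr(r, "undefined_sets") <- undefined
  r
}

#' Aggregate per-type correlations by the Fisher Z-transformation
#'
#' Per gene set g: `zbar_g = 1/2 * sum_C ln((1 + r_gC) / (1 - r_gC))`,
#' i.e. the sum over cell types of artanh(r). Correlations with
#' magnitude at or above `1 - clip` are clipped to `+/-(1 - clip)` first
#' so the transform stays finite; the number of clipped entries is
#' reported via the `n_clipped` attribute.
#'
#' @param r sets x types correlation matrix.
#' @param clip clipping margin below 1 (default `1e-7`).
#' @return named numeric vector `zbar` with attribute `n_clipped`.
#' @export
fisher_aggregate <- function(r, clip = 1e-7) {
  assert_matrix_like(r, "r")
  if (any(!is.finite(r)))
    stop("r contains undefined values; exclude those sets first",
         call. = FALSE)
  lim <- 1 - clip
  n_clipped <- sum(abs(r) > lim)
  rc <- pmin(pmax(r, -lim), lim)
  zbar <- 0.5 * rowSums(log((1 + rc) / (1 - rc)))
  names(zbar) <- rownames(r)
  attr(zbar, "n_clipped") <- n_clipped
  zbar
}

#' Standardize aggregated statistics by median and MAD
#'
#' `S_g = (zbar_g - median(z)) / (1.4826 * MAD(z))`, where MAD is the
#' raw median absolute deviation from the median and 1.4826 is the
#' normal-consistency constant, applied explicitly.
#'
#' @param zbar numeric vector with >= 2 distinct values.
#' @return standardized vector `S` (median exactly 0 by construction).
#' @export
standardize_mad <- function(zbar) {
  z <- as.numeric(zbar)
  if (length(unique(z)) < 2)
    stop("need >= 2 distinct values", call. = FALSE)
  med <- stats::median(z)
  mad0 <- stats::median(abs(z - med))
  if (mad0 == 0)
    stop("MAD is zero: the screen is degenerate (more than half of the ",
         "aggregated statistics are identical)", call. = FALSE)
  S <- (z - med) / (1.4826 * mad0)
  names(S) <- names(zbar)
  S
}

#' Flag gene sets by standard-normal p-values on the standardized score
#'
#' @param S standardized statistic vector (finite).
#' @param alpha selection threshold (strictly-below rule).
#' @param sided `"two"` (default): `p = 2 * (1 - Phi(|S|))`; `"one"`:
#'   upper-tail `p = 1 - Phi(S)`.
#' @return data.frame with columns `set`, `S`, `p`, `selected`.
#' @export
select_sets <- function(S, alpha = 0.01, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (any(!is.finite(S))) stop("S must be finite", call. = FALSE)
  p <- if (sided == "two") 2 * stats::pnorm(-abs(S)) else stats::pnorm(-S)
  data.frame(set = names(S) %||% seq_along(S), S = as.numeric(S), p = p,
             selected = p < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Run the full activation-proportion association screen
#'
#' Chains [correlate_sets_types()], [fisher_aggregate()],
#' [standardize_mad()] and [select_sets()]. Sets with undefined
#' correlations are excluded from aggregation and reported.
#'
#' @param activations sets x samples matrix.
#' @param proportions samples x cell-types matrix.
#' @param alpha selection threshold on the normal p-value.
#' @param sided p-value sidedness, see [select_sets()].
#' @param clip correlation clipping margin, see [fisher_aggregate()].
#' @return object of class `association_table`: data.frame with one row
#'   per retained set (`set`, `r_<type>` columns, `zbar`, `S`, `p`,
#'   `selected`), plus attributes `excluded_sets` and `n_clipped`.
#' @export
associate_screen <- function(activations, proportions, alpha = 0.01,
                             sided = "two", clip = 1e-7) {
  r <- correlate_sets_types(activations, proportions)
  excluded <- attr(r, "undefined_sets")
  if (length(excluded)) r <- r[!rownames(r) %in% excluded, , drop = FALSE]
  if (nrow(r) < 2)
    stop("fewer than 2 sets with defined correlations", call. = FALSE)
  zbar <- fisher_aggregate(r, clip = clip)
  S <- standardize_mad(zbar)
  sel <- select_sets(S, alpha = alpha, sided = sided)
  tab <- data.frame(set = rownames(r), stringsAsFactors = FALSE)
  rtab <- as.data.frame(r)
  names(rtab) <- paste0("r_", colnames(r))
  tab <- cbind(tab, rtab, zbar = as.numeric(zbar), S = sel$S, p = sel$p,
               selected = sel$selected)
  rownames(tab) <- NULL
  attr(tab, "excluded_sets") <- excluded
  attr(tab, "n_clipped") <- attr(zbar, "n_clipped")
  class(tab) <- c("association_table", "data.frame")
  tab
}
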