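#' @keywords internal
"_PACKAGE"

# Dirichlet sampler via normalized gamma draws.
# Returns an n x length(alpha) matrix; rows sum to 1 exactly after the
# final renormalization.
rdirichlet <- function(n, alpha) {
  stopifnot(n >= 1, all(alpha > 0))
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  p <- g / rowSums(g)
  # guard against all-zero gamma rows at extreme tiny alpha
  bad <- !is.finite(rowSums(p))
  if (any(bad)) {
    i <- which.max(alpha)
    p[bad, ] <- 0
    p[bad, i] <- 1
  }
  p
}

# derive a reproducible child seed (< 2^31) from a base seed and a tag
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 31L + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_matrix_like <- function(x, what = "matrix") {
  if (!is.matrix(x) && !inherits(x, "Matrix"))
    stop(what, " must be a matrix", call. = FALSE)
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop(what, " is empty", call. = FALSE)
  invisible(x)
}
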