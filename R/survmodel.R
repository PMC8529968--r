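#' Assemble aligned survival data
#'
#' @param sample sample ids.
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param features samples x features numeric matrix (activation scores
#'   or cell-type proportions); rows aligned with `sample`.
#' @return object of class `survival_data`.
#' @export
survival_data <- function(sample, time, event, features) {
  features <- as.matrix(features)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (nrow(features) != length(time) || length(sample) != length(time))
    stop("sample/time/event/features lengths differ", call. = FALSE)
  if (any(!is.finite(features)))
    stop("features contain missing values", call. = FALSE)
  if (is.null(rownames(features))) rownames(features) <- sample
  structure(list(sample = sample, time = as.numeric(time),
                 event = as.integer(event), features = features),
            class = "survival_data")
}

#' Multivariate Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) over all
#' feature columns. Requires >= 10 events and a full-rank feature
#' matrix; monotone-likelihood fits (coefficients diverging) raise an
#' error suggesting penalization.
#'
#' @param data a [survival_data()].
#' @return object of class `cox_fit`: `beta`, `se`, `hr`, `ci_lower`,
#'   `ci_upper`, `p`, `loglik`, `concordance`, `ties`, and the
#'   underlying `fit`.
#' @export
fit_cox <- function(data) {
  stopifnot(inherits(data, "survival_data"))
  if (sum(data$event) < 10)
    stop("need >= 10 events to fit a Cox model", call. = FALSE)
  X <- data$features
  qrX <- qr(scale(X, center = TRUE, scale = FALSE))
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear features: ", paste(aliased, collapse = ", "),
         call. = FALSE)
  }
  y <- survival::Surv(data$time, data$event)
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(y ~ X, ties = "efron",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  if (diverged || any(!is.finite(beta)) || any(abs(beta) > 50))
    stop("monotone partial likelihood (perfect separation); ",
         "consider a penalized fit", call. = FALSE)
  s <- summary(fit)
  se <- s$coefficients[, "se(coef)"]
  names(se) <- colnames(X)
  structure(list(beta = beta, se = se, hr = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 p = s$coefficients[, "Pr(>|z|)"],
                 loglik = fit$loglik[2],
                 concordance = unname(s$concordance[1]),
                 ties = "efron", fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("cox_fit:", length(x$beta), "features; concordance",
      round(x$concordance, 3), "\n")
  print(data.frame(beta = x$beta, hr = x$hr, lower95 = x$ci_lower,
                   upper95 = x$ci_upper, p = x$p))
  invisible(x)
}

#' LASSO-penalized Cox regression with cross-validated lambda
#'
#' Coordinate-descent optimization of the L1-penalized Cox partial
#' likelihood over a lambda grid (features standardized internally,
#' coefficients reported on the original scale), with k-fold
#' cross-validated partial-likelihood deviance; features with nonzero
#' coefficients at `lambda.min` are selected.
#'
#' @param data a [survival_data()].
#' @param lambda optional lambda grid (default: glmnet's own).
#' @param n_folds number of CV folds.
#' @param seed integer seed controlling the fold assignment.
#' @return object of class `risk_model`: `selected` feature names,
#'   `beta` (nonzero coefficients at lambda.min), `lambda_min`,
#'   `n_folds`, `seed` and the `cvfit`.
#' @export
lasso_cox <- function(data, lambda = NULL, n_folds = 10, seed = 1) {
  stopifnot(inherits(data, "survival_data"))
  y <- survival::Surv(data$time, data$event)
  X <- data$features
  if (ncol(X) < 2)
    stop("need >= 2 features for a LASSO path", call. = FALSE)
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = nrow(X)))
  cvfit <- glmnet::cv.glmnet(X, y, family = "cox", alpha = 1,
                             lambda = lambda, foldid = foldid,
                             standardize = TRUE)
  b <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[, 1]
  nz <- b[b != 0]
  path_b <- as.matrix(stats::coef(cvfit$glmnet.fit))
  if (all(path_b == 0))
    stop("all-zero coefficient path: no signal or grid too coarse",
         call. = FALSE)
  structure(list(selected = names(nz), beta = nz,
                 lambda_min = cvfit$lambda.min, n_folds = n_folds,
                 seed = seed, cvfit = cvfit),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("risk_model:", length(x$selected), "features selected at lambda.min =",
      signif(x$lambda_min, 4), "\n")
  invisible(x)
}

#' Linear risk score
#'
#' `score_s = sum_i beta_i * x_si` (no intercept) over the model's
#' features.
#'
#' @param model a named coefficient vector, a `risk_model`, or a
#'   `cox_fit`.
#' @param features samples x features matrix containing every model
#'   feature.
#' @return named numeric vector of per-sample scores.
#' @export
risk_score <- function(model, features) {
  beta <- if (inherits(model, c("risk_model", "cox_fit"))) model$beta
          else model
  if (is.null(names(beta))) stop("coefficients must be named", call. = FALSE)
  features <- as.matrix(features)
  missing_f <- setdiff(names(beta), colnames(features))
  if (length(missing_f))
    stop("missing features: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  drop(features[, names(beta), drop = FALSE] %*% beta)
}

# log-rank O-E/V z-statistic for a binary split (internal, used by the
# cutpoint scan through survdiff)
logrank_z <- function(time, event, group) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  sign_hi <- sign(sd$obs[2] - sd$exp[2])
  sqrt(sd$chisq) * ifelse(sign_hi == 0, 1, sign_hi)
}

#' Optimal risk-score cutpoint by the maximally selected log-rank statistic
#'
#' Scans every admissible threshold (midpoints between adjacent distinct
#' scores leaving at least `minprop` of the samples on each side) and
#' returns the one maximizing the standardized two-group log-rank
#' statistic.
#'
#' @param scores numeric risk scores (>= 2 distinct values).
#' @param time,event survival outcome (>= 1 event).
#' @param minprop minimum fraction of samples per group.
#' @return object of class `cutpoint_result`: `threshold`, `statistic`
#'   (|z| at the optimum), `n_low`, `n_high`, and the scanned
#'   `candidates` data.frame.
#' @export
optimal_cutpoint <- function(scores, time, event, minprop = 0.1) {
  if (length(unique(scores)) < 2)
    stop("need >= 2 distinct scores", call. = FALSE)
  if (sum(event) < 1) stop("need >= 1 event", call. = FALSE)
  n <- length(scores)
  s_sorted <- sort(unique(scores))
  mids <- (s_sorted[-1] + s_sorted[-length(s_sorted)]) / 2
  n_min <- ceiling(minprop * n)
  admissible <- vapply(mids, function(m) {
    nl <- sum(scores <= m)
    nl >= n_min && (n - nl) >= n_min
  }, logical(1))
  mids <- mids[admissible]
  if (length(mids) == 0)
    stop("no admissible threshold at minprop = ", minprop, call. = FALSE)
  z <- vapply(mids, function(m) {
    g <- factor(scores > m, levels = c(FALSE, TRUE))
    if (length(unique(event[g == levels(g)[1]])) == 1 &&
        length(unique(event[g == levels(g)[2]])) == 1 &&
        sum(event) == 0) return(0)
    logrank_z(time, event, g)
  }, numeric(1))
  best <- which.max(abs(z))
  structure(list(threshold = mids[best], statistic = abs(z[best]),
                 z = z[best],
                 n_low = sum(scores <= mids[best]),
                 n_high = sum(scores > mids[best]),
                 candidates = data.frame(threshold = mids, z = z)),
            class = "cutpoint_result")
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator with right censoring; each curve starts at
#' `S(0) = 1`.
#'
#' @param time,event survival outcome.
#' @param group group label per sample (single group if omitted).
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv`, including the `time = 0, surv = 1` anchor row per group.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  stopifnot(length(group) == length(time))
  out <- lapply(unique(group), function(g) {
    i <- group == g
    fit <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    data.frame(group = g,
               time = c(0, fit$time),
               n_risk = c(sum(i), fit$n.risk),
               n_event = c(0, fit$n.event),
               surv = c(1, fit$surv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Log-rank test for equality of survival curves
#'
#' @param time,event survival outcome.
#' @param group group label per sample (>= 2 non-empty groups).
#' @return list with `chisq`, `df` and `p`.
#' @export
log_rank <- function(time, event, group) {
  if (length(unique(group)) < 2)
    stop("need >= 2 groups", call. = FALSE)
  if (sum(event) == 0) stop("no events observed", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Fraction of usable (comparable) pairs in which the sample with the
#' higher risk score experiences the event earlier; tied scores count
#' 0.5.
#'
#' @param scores numeric risk scores.
#' @param time,event survival outcome.
#' @return concordance in \[0, 1\].
#' @export
concordance_index <- function(scores, time, event) {
  cf <- survival::concordance(survival::Surv(time, event) ~ scores,
                              reverse = TRUE)
  counts <- cf$count
  usable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (usable == 0) stop("no comparable pairs", call. = FALSE)
  unname(cf$concordance)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random positive outranks a random negative, ties
#' counted 0.5 — equivalent to the trapezoidal ROC area.
#'
#' @param labels binary labels (0/1 or logical); both classes present.
#' @param scores numeric classifier scores.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Exact enumeration when the combined sample size is below 20 and there
#' are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param values numeric vector.
#' @param groups two-level grouping vector.
#' @return list with `statistic` (rank-sum W for the first level) and
#'   `p`.
#' @export
group_difference_test <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("need exactly 2 groups", call. = FALSE)
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  exact <- (length(x) + length(y)) < 20 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}
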