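test_that("Cox fit matches a brute-force partial-likelihood maximizer", {
  # 5 observations, no ties
  time <- c(2.1, 3.7, 1.2, 5.4, 4.3)
  event <- c(1, 1, 1, 0, 1)
  x <- c(0.5, -1.2, 2.0, 0.3, -0.7)
  sdat <- survival_data(paste0("p", 1:5), time, event,
                        matrix(x, ncol = 1, dimnames = list(NULL, "f")))
  # fit_cox requires >= 10 events; compare against coxph directly here
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  beta_oracle <- stats::optimize(
    function(b) -oracle_cox_loglik(b, time, event, x),
    interval = c(-5, 5), tol = 1e-9)$minimum
  expect_equal(unname(coef(fit)), beta_oracle, tolerance = 1e-6)

  # the exported wrapper agrees with coxph on a larger sample
  set.seed(91)
  n <- 120
  X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f1"))
  sv <- sim_surv(n, X, 1, seed = 91)
  sd2 <- survival_data(paste0("p", 1:n), sv$time, sv$event, X)
  fit2 <- fit_cox(sd2)
  ref <- survival::coxph(survival::Surv(sv$time, sv$event) ~ X,
                         ties = "efron")
  expect_equal(unname(fit2$beta), unname(coef(ref)), tolerance = 1e-8)
  expect_true(fit2$ci_lower < fit2$hr && fit2$hr < fit2$ci_upper)
})

test_that("Cox recovery and null behavior over repeated cohorts", {
  # true log-HR = 1: 95% CI covers the truth in >= 90% of 50 replicates
  cover <- vapply(1:50, function(s) {
    n <- 500
    set.seed(s)
    X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f1"))
    sv <- sim_surv(n, X, 1, seed = s + 1000)
    fit <- fit_cox(survival_data(paste0("p", 1:n), sv$time, sv$event, X))
    fit$beta - 1.96 * fit$se <= 1 && 1 <= fit$beta + 1.96 * fit$se
  }, logical(1))
  expect_gte(mean(cover), 0.9)

  # independent feature: |beta| < 2 se and p > 0.05 in >= 90% of 50 seeds
  nullok <- vapply(1:50, function(s) {
    n <- 500
    set.seed(s + 2000)
    X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f1"))
    sv <- sim_surv(n, X, 0, seed = s + 3000)
    fit <- fit_cox(survival_data(paste0("p", 1:n), sv$time, sv$event, X))
    abs(fit$beta) < 2 * fit$se && fit$p > 0.05
  }, logical(1))
  expect_gte(mean(nullok), 0.9)
})

test_that("Cox fit rejects degenerate designs", {
  n <- 60
  set.seed(92)
  X <- cbind(f1 = rnorm(n))
  sv <- sim_surv(n, X, 1, seed = 92)
  few <- survival_data(paste0("p", 1:20), sv$time[1:20],
                       rep(c(1, 0), c(5, 15)), X[1:20, , drop = FALSE])
  expect_error(fit_cox(few), ">= 10 events")

  X2 <- cbind(f1 = X[, 1], f2 = 2 * X[, 1])
  expect_error(fit_cox(survival_data(paste0("p", 1:n), sv$time, sv$event,
                                     X2)), "collinear")

  # perfect separation: feature = event indicator with early event times
  time <- c(rep(1, 30), rep(10, 30))
  event <- rep(c(1, 0), each = 30)
  X3 <- cbind(f1 = event)
  expect_error(fit_cox(survival_data(paste0("p", 1:60), time, event, X3)),
               "separation|monotone")
})

test_that("LASSO-Cox honors penalty limits and recovers informative features", {
  set.seed(93)
  n <- 400
  X <- matrix(rnorm(n * 50), n, 50,
              dimnames = list(paste0("p", 1:n), sprintf("F%02d", 1:50)))
  sv <- sim_surv(n, X[, 1:3], c(1, 1, -1), seed = 93)
  sdat <- survival_data(rownames(X), sv$time, sv$event, X)

  # huge lambda: everything shrunk to zero at the top of the path
  m <- lasso_cox(sdat, seed = 3)
  path <- as.matrix(coef(m$cvfit$glmnet.fit))
  expect_true(all(path[, 1] == 0))

  # selection sensitivity >= 2/3 across seeds (bound frozen after
  # measuring 1.00 over 20 development seeds)
  sens <- vapply(1:5, function(s) {
    set.seed(s)
    Xs <- matrix(rnorm(n * 50), n, 50,
                 dimnames = list(paste0("p", 1:n), sprintf("F%02d", 1:50)))
    svs <- sim_surv(n, Xs[, 1:3], c(1, 1, -1), seed = s + 500)
    ms <- lasso_cox(survival_data(rownames(Xs), svs$time, svs$event, Xs),
                    seed = s)
    mean(sprintf("F%02d", 1:3) %in% ms$selected)
  }, numeric(1))
  expect_true(all(sens >= 2 / 3))

  # near-zero lambda reproduces the unpenalized fit
  X1 <- X[, 1, drop = FALSE]
  sv1 <- sim_surv(n, X1, 1, seed = 94)
  sd1 <- survival_data(rownames(X), sv1$time, sv1$event,
                       cbind(X1, dummy = rnorm(n) * 1e-3))
  m1 <- lasso_cox(sd1, lambda = c(1, 0.1, 0.0001), seed = 5)
  full <- fit_cox(survival_data(rownames(X), sv1$time, sv1$event, X1))
  b1 <- as.matrix(coef(m1$cvfit$glmnet.fit, s = 0.0001))["F01", 1]
  expect_equal(b1, unname(full$beta), tolerance = 1e-2)
})

test_that("risk scores are exact linear predictors", {
  X <- matrix(1:6, 2, 3, dimnames = list(c("p1", "p2"), c("a", "b", "c")))
  expect_equal(unname(risk_score(c(a = 0, b = 0, c = 0), X)), c(0, 0))
  expect_equal(unname(risk_score(c(b = 2), X)), c(6, 8))

  set.seed(95)
  beta <- rnorm(3); names(beta) <- c("a", "b", "c")
  Xr <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("p", 1:4),
                                                c("a", "b", "c")))
  want <- as.vector(Xr %*% beta)  # dot-product oracle
  expect_equal(unname(risk_score(beta, Xr)), want, tolerance = 1e-12)

  # affine equivariance: scale feature by c, beta by 1/c
  X2 <- Xr; X2[, "b"] <- X2[, "b"] * 10
  beta2 <- beta; beta2["b"] <- beta2["b"] / 10
  expect_equal(risk_score(beta2, X2), risk_score(beta, Xr),
               tolerance = 1e-12)

  expect_error(risk_score(c(zz = 1), Xr), "missing features: zz")
})

test_that("the optimal cutpoint matches an exhaustive scan", {
  set.seed(96)
  n <- 30
  scores <- rnorm(n)
  sv <- sim_surv(n, matrix(scores), 1.5, seed = 96)

  cut <- optimal_cutpoint(scores, sv$time, sv$event, minprop = 0.1)
  # brute-force scan with the hand-coded log-rank statistic
  ss <- sort(unique(scores))
  mids <- (ss[-1] + ss[-length(ss)]) / 2
  n_min <- ceiling(0.1 * n)
  best <- -Inf; best_m <- NA
  for (m in mids) {
    nl <- sum(scores <= m)
    if (nl < n_min || n - nl < n_min) next
    o <- oracle_logrank(sv$time, sv$event, scores > m)
    z <- abs(o$O - o$E) / sqrt(o$V)
    if (z > best) { best <- z; best_m <- m }
  }
  expect_equal(cut$threshold, best_m, tolerance = 1e-12)
  expect_equal(cut$statistic, best, tolerance = 1e-8)

  # permuting samples changes nothing
  perm <- sample(n)
  cut2 <- optimal_cutpoint(scores[perm], sv$time[perm], sv$event[perm])
  expect_equal(cut2$threshold, cut$threshold)

  # bimodal scores with all events in the high mode split between modes
  sc_bi <- c(rnorm(15, 0, 0.1), rnorm(15, 5, 0.1))
  tm <- c(runif(15, 5, 10), runif(15, 0.1, 1))
  ev <- rep(c(0, 1), each = 15)
  cb <- optimal_cutpoint(sc_bi, tm, ev)
  expect_gt(cb$threshold, 1)
  expect_lt(cb$threshold, 4)

  expect_error(optimal_cutpoint(rep(1, 10), runif(10), rep(1, 10)),
               "distinct")
  expect_error(optimal_cutpoint(1:10, runif(10), rep(1, 10), minprop = 0.6),
               "admissible")
})

test_that("KM curves equal the product-limit oracle", {
  # no events: survival stays at 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # n distinct event times, no censoring: S = (n-k)/n
  tt <- c(1, 2, 3, 4, 5)
  km1 <- km_estimate(tt, rep(1, 5))
  expect_equal(km1$surv, c(1, 4 / 5, 3 / 5, 2 / 5, 1 / 5, 0),
               tolerance = 1e-12)

  # censored data vs hand-coded oracle
  set.seed(97)
  n <- 60
  time <- round(rexp(n, 0.2), 2)
  event <- rbinom(n, 1, 0.7)
  km <- km_estimate(time, event)
  want <- oracle_km(time, event)
  got <- km[km$n_event > 0, c("time", "surv")]
  # keep the last row per event time (survfit reports each time once)
  expect_equal(got$surv, want$surv[match(got$time, want$time)],
               tolerance = 1e-12)
})

test_that("log-rank matches hand enumeration and is calibrated", {
  # duplicated data split at random: statistic ~ 0
  time <- rep(c(1, 3, 5, 7, 9, 11), 2)
  event <- rep(c(1, 1, 0, 1, 0, 1), 2)
  grp <- rep(c("a", "b"), each = 6)
  lr <- log_rank(time, event, grp)
  expect_lt(lr$chisq, 1e-10)
  expect_gt(lr$p, 0.999)

  # 2-group toy against the O/E/V oracle
  set.seed(98)
  time2 <- c(2, 4, 1, 7, 3, 8, 6, 5, 9, 10)
  event2 <- c(1, 1, 1, 0, 1, 1, 0, 1, 1, 0)
  grp2 <- rep(c("x", "y"), 5)
  lr2 <- log_rank(time2, event2, grp2)
  o <- oracle_logrank(time2, event2, grp2)
  expect_equal(lr2$chisq, o$chisq, tolerance = 1e-10)

  expect_error(log_rank(time2, rep(0, 10), grp2), "no events")
  expect_error(log_rank(time2, event2, rep("x", 10)), ">= 2 groups")
})

test_that("rank statistics (C-index, AUC, rank-sum) match pair counting", {
  # perfect ordering -> C = 1; constant scores -> 0.5
  time <- c(5, 4, 3, 2, 1)
  event <- rep(1, 5)
  expect_equal(concordance_index(1:5, time, event), 1)
  expect_equal(concordance_index(rep(1, 5), time, event), 0.5)

  set.seed(99)
  n <- 40
  sc <- rnorm(n)
  sv <- sim_surv(n, matrix(sc), 1, seed = 99)
  got <- concordance_index(sc, sv$time, sv$event)
  # O(n^2) pair counting oracle
  num <- 0; den <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ti <- sv$time[i]; tj <- sv$time[j]
    # comparable if the earlier time is an event
    if (ti < tj && sv$event[i] == 1 || tj < ti && sv$event[j] == 1) {
      den <- den + 1
      early <- if (ti < tj) i else j
      late <- if (ti < tj) j else i
      if (sc[early] > sc[late]) num <- num + 1
      else if (sc[early] == sc[late]) num <- num + 0.5
    }
  }
  expect_equal(got, num / den, tolerance = 1e-12)

  # AUC
  expect_equal(auc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(2, 4)), 0.5)
  set.seed(100)
  lab <- rbinom(30, 1, 0.5)
  scr <- rnorm(30) + lab
  got_auc <- auc(lab, scr)
  pos <- scr[lab == 1]; neg <- scr[lab == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(got_auc, mean(pairs), tolerance = 1e-12)
  expect_error(auc(rep(1, 5), rnorm(5)), "both classes")

  # rank-sum: exact enumeration and label-swap symmetry
  gd <- group_difference_test(c(1, 2, 3, 4, 5, 6),
                              rep(c("a", "b"), each = 3))
  expect_equal(gd$p, 0.1, tolerance = 1e-12)
  gd2 <- group_difference_test(c(4, 5, 6, 1, 2, 3),
                               rep(c("a", "b"), each = 3))
  expect_equal(gd2$p, gd$p, tolerance = 1e-12)
})
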