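# Shared fixtures, built in code at test time.

# small labeled pool used across modules
tiny_pool <- function(seed = 7, n_types = 3, n_genes = 400,
                      cells_per_type = 50, markers_per_type = 20,
                      marker_logfc = 2, frac_qc_fail = 0) {
  simulate_cell_pool(sc_sim_config(
    n_types = n_types, n_genes = n_genes, cells_per_type = cells_per_type,
    markers_per_type = markers_per_type, marker_logfc = marker_logfc,
    frac_qc_fail = frac_qc_fail, seed = seed))
}

# survival data with exponential times under a linear predictor and
# covariate-conditional exponential censoring at the target rate
sim_surv <- function(n, X, beta, censor_rate = 0.3, scale = 5, seed = 1) {
  set.seed(seed)
  lp <- as.vector(X %*% beta)
  rate <- exp(lp) / scale
  t_ev <- stats::rexp(n, rate = rate)
  if (censor_rate <= 0) {
    list(time = t_ev, event = rep(1L, n), lp = lp)
  } else {
    t_c <- stats::rexp(n, rate = rate * censor_rate / (1 - censor_rate))
    list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c), lp = lp)
  }
}

# brute-force activation-score oracle: full cumulative random walk over
# the complete ranking (independent of the positions-only shortcut in
# the package)
oracle_walk_score <- function(z_col, set_idx, tau = 1,
                              convention = "diff") {
  N <- length(z_col)
  ord <- order(z_col, seq_len(N), decreasing = c(TRUE, FALSE),
               method = "radix")
  in_set <- ord %in% set_idx
  k <- sum(in_set)
  rank_w <- abs(N / 2 + 0.5 - seq_len(N))^tau
  steps <- ifelse(in_set, rank_w / sum(rank_w[in_set]), -1 / (N - k))
  D <- cumsum(steps)
  max_pos <- max(0, D)
  min_neg <- min(0, D)
  if (convention == "diff") max_pos + min_neg
  else if (max_pos >= -min_neg) max_pos else min_neg
}

# hand-coded Cox partial likelihood (no ties), for brute-force fits
oracle_cox_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  eta <- beta * x
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + eta[i] - log(sum(exp(eta[risk])))
    }
  }
  ll
}

# hand-coded two-group log-rank O, E, V enumeration over event times
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L  # 0/1
  ev_times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(O = O, E = E, V = V, chisq = chisq)
}

# hand-coded Kaplan-Meier product-limit oracle
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in tt) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}
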