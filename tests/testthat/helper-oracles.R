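# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force / first principles, never via package code.

# Benjamini-Hochberg by direct definition: p_(i) * m / i, cumulative min
# from the largest rank down.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}

# two-sided rank-sum p by exhaustive enumeration of group assignments
ranksum_exact_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(n, nx)
  ws <- apply(combos, 2L, function(idx) sum(r[idx]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# product-limit estimator from first principles
km_bruteforce <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    t_ <- ut[i]
    n_risk <- sum(time >= t_)
    d <- sum(time == t_ & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# trapezoidal AUC over the empirical ROC curve (independent of the
# Mann-Whitney identity used by the package)
auc_trapezoid <- function(pred, y) {
  th <- c(Inf, sort(unique(pred), decreasing = TRUE), -Inf)
  fpr <- tpr <- numeric(length(th))
  for (i in seq_along(th)) {
    yy <- pred >= th[i]
    fpr[i] <- sum(yy & y == 0) / sum(y == 0)
    tpr[i] <- sum(yy & y == 1) / sum(y == 1)
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# classical partial-correlation Fisher-z test, computed via recursive
# residualisation (lm), independent of the package's covariance algebra
pcor_z_test <- function(x, y, Z) {
  if (is.null(Z) || (is.matrix(Z) && ncol(Z) == 0)) {
    r <- cor(x, y)
    q <- 0
  } else {
    Z <- as.matrix(Z)
    rx <- residuals(lm(x ~ Z))
    ry <- residuals(lm(y ~ Z))
    r <- cor(rx, ry)
    q <- ncol(Z)
  }
  n <- length(x)
  z <- sqrt(n - q - 3) * atanh(r)
  as.numeric(2 * pnorm(-abs(z)))
}

# tiny scaled-down trauma world for fast unit tests
small_trauma_config <- function(...) {
  trauma_config(
    n_per_outcome = c(resolving = 20L, non_resolving = 30L,
                      early_nonsurvivor = 10L),
    n_healthy = 8L,
    species_counts = c(TAG = 40L, PE = 12L, PC = 10L, DAG = 8L, CE = 4L,
                       SM = 4L, LPC = 6L, LPE = 3L, PI = 3L, FFA = 3L,
                       CER = 6L, HCER = 2L, LCER = 2L, DCER = 2L),
    n_planted = c(extra_pe = 0L, tag = 6L, dag = 2L, cer = 2L,
                  lpc_down = 2L),
    ...)
}

# minimal hand-built lipidomics matrix
toy_matrix <- function(values, species, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(values)))
  lipidomics_matrix(values, sample_ids = ids, species = species)
}
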