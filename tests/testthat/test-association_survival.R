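test_that("correlation_matrix coefficients and t-distribution p-values", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 4)
  cm <- correlation_matrix(data.frame(x = x, y = y), "spearman")
  expect_equal(cm$r["x", "x"], 1)
  # brute-force rank formula: 1 - 6*sum(d^2)/(n(n^2-1))
  d <- rank(x) - rank(y)
  expect_equal(cm$r["x", "y"], 1 - 6 * sum(d^2) / (4 * 15))
  expect_equal(cm$r["x", "y"], 0.8)

  # r = 0 -> t = 0 -> p = 1
  x5 <- c(-2, -1, 0, 1, 2)
  y5 <- c(1, -1, 0, -1, 1)  # orthogonal to x
  cm5 <- correlation_matrix(data.frame(x = x5, y = y5), "pearson")
  expect_equal(cm5$r["x", "y"], 0)
  expect_equal(cm5$p["x", "y"], 1)

  # p from the t transform with n - 2 df
  set.seed(2)
  a <- rnorm(20); b <- a + rnorm(20)
  cmp <- correlation_matrix(data.frame(a = a, b = b), "pearson")
  r <- cor(a, b)
  tstat <- r * sqrt(18 / (1 - r^2))
  expect_equal(cmp$p["a", "b"], 2 * pt(-abs(tstat), 18))

  # constant column -> missing coefficient
  cmc <- correlation_matrix(data.frame(a = a, k = rep(1, 20)))
  expect_true(is.na(cmc$r["a", "k"]))
})

test_that("correlation_network thresholds and per-class selection", {
  set.seed(3)
  n <- 50
  base <- rnorm(n)
  v <- exp(cbind(base, base + rnorm(n, 0, 0.3), rnorm(n)) / 3)
  m <- toy_matrix(v, c("PE(16:0_18:2)", "PE(16:0_20:4)", "PC(16:0_18:1)"))
  net <- correlation_network(m, per_class_top = list(), r_thresh = 0.7)
  expect_equal(nrow(net$edges), 1L)
  expect_setequal(c(net$edges$node1, net$edges$node2),
                  c("PE(16:0_18:2)", "PE(16:0_20:4)"))
  expect_true(all(abs(net$edges$r) >= 0.7))

  # threshold 1: only duplicated columns stay connected
  v2 <- cbind(v, v[, 1])
  m2 <- toy_matrix(v2, c(colnames(v)[0], "PE(16:0_18:2)", "PE(16:0_20:4)",
                         "PC(16:0_18:1)", "PE(18:0_18:1)"))
  net2 <- correlation_network(m2, per_class_top = list(), r_thresh = 1)
  expect_equal(nrow(net2$edges), 1L)

  # per-class retention counts respected
  sim <- generate_trauma_cohort(small_trauma_config(), seed = 9)
  mm <- impute_min(filter_missing(sim$matrix))
  net3 <- correlation_network(mm, per_class_top = list(TAG = 10, PE = 5),
                              r_thresh = 0.7)
  expect_equal(unname(net3$selection[["TAG"]]), 10)
  expect_equal(unname(net3$selection[["PE"]]), 5)
})

test_that("planted correlated block is densely connected in the network", {
  sim <- generate_trauma_cohort(trauma_config(), seed = 14)
  mm <- impute_min(filter_missing(sim$matrix))
  # sample rows where the block factor varies freely
  net <- correlation_network(mm, per_class_top = list(TAG = 100, DAG = 30,
                                                      PE = 40, PC = 40),
                             r_thresh = 0.7)
  blk <- intersect(sim$truth$trauma_elevated, net$nodes)
  inblk <- net$edges$node1 %in% blk & net$edges$node2 %in% blk
  density <- sum(inblk) / choose(length(blk), 2)
  expect_gte(density, 0.8)
  # edge set invariant to sample/species ordering
  perm_s <- sample(nrow(mm$values))
  perm_j <- sample(ncol(mm$values))
  mm2 <- lipidomics_matrix(mm$values[perm_s, perm_j])
  net_perm <- correlation_network(mm2, per_class_top = list(TAG = 100,
                                                            DAG = 30,
                                                            PE = 40,
                                                            PC = 40),
                                  r_thresh = 0.7)
  key <- function(e) sort(paste(pmin(e$node1, e$node2),
                                pmax(e$node1, e$node2)))
  expect_setequal(key(net_perm$edges), key(net$edges))
})

test_that("recovery KM matches hand-computed product-limit values", {
  mk <- function(icu, died = 0, dd = NA, grp = "g") data.frame(
    subject_id = sprintf("p%d", seq_along(icu)), died = died,
    death_day = dd, icu_los_days = icu, group = grp)

  # 4 discharges at days 1..4 -> 0.75 / 0.50 / 0.25 / 0
  km <- recovery_km(mk(1:4), group_col = "group")
  expect_equal(km$curves$g$surv, c(0.75, 0.5, 0.25, 0))

  # all discharged day 1 -> drops to 0 at t = 1
  km1 <- recovery_km(mk(rep(1, 5)), group_col = "group")
  expect_equal(km1$curves$g$surv, 0)
  expect_equal(km1$curves$g$time, 1)

  # a late death among discharges never recovers: curve stays > 0 at end
  d <- mk(c(1, 2, 3, 4, 10), died = c(0, 0, 0, 0, 1),
          dd = c(NA, NA, NA, NA, 10))
  km2 <- recovery_km(d, group_col = "group")
  expect_gt(min(km2$curves$g$surv), 0)
  # the late death is censored at the dataset max stay
  expect_equal(sum(km2$data$event == 0), 1L)
  expect_equal(km2$data$time[km2$data$event == 0], 10)

  # early deaths are excluded entirely
  d3 <- mk(c(1, 2, 2), died = c(0, 0, 1), dd = c(NA, NA, 2))
  km3 <- recovery_km(d3, group_col = "group")
  expect_equal(nrow(km3$data), 2L)

  # > 30 day stays censored at 30
  d4 <- mk(c(5, 45))
  km4 <- recovery_km(d4, group_col = "group")
  expect_equal(max(km4$data$time), 30)
  expect_equal(km4$data$event[km4$data$time == 30], 0L)
})

test_that("KM estimator equals brute-force product-limit on random fixtures", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    icu <- sample(1:35, n, replace = TRUE)
    died <- rbinom(n, 1, 0.3)
    dd <- ifelse(died == 1, pmax(icu, 4), NA)  # late deaths only
    icu[died == 1] <- dd[died == 1]
    d <- data.frame(subject_id = sprintf("p%d", 1:n), died = died,
                    death_day = dd, icu_los_days = icu, group = "g")
    km <- recovery_km(d, group_col = "group")
    # oracle: apply the conventions by hand, then brute-force product-limit
    t_ <- d$icu_los_days
    e_ <- rep(1, n)
    t_[died == 1] <- max(d$icu_los_days)
    e_[died == 1] <- 0
    e_[t_ > 30] <- 0
    t_[t_ > 30] <- 30
    bf <- km_bruteforce(t_, e_)
    got <- km$curves$g
    got_ev <- got[got$n_event > 0, ]
    expect_equal(got_ev$surv, bf$surv, tolerance = 1e-12)
    expect_equal(got_ev$time, bf$time)
  }
})

test_that("log-rank p separates clearly different recovery groups", {
  d <- data.frame(subject_id = sprintf("p%d", 1:40),
                  died = 0, death_day = NA,
                  icu_los_days = c(sample(1:3, 20, TRUE),
                                   sample(12:20, 20, TRUE)),
                  group = rep(c("fast", "slow"), each = 20))
  km <- recovery_km(d, group_col = "group")
  expect_lt(km$logrank$p, 1e-6)
})

test_that("fit_outcome_models recovers a known logistic coefficient", {
  # beta = 1 for the score; 5 seeds (scaled from the full-size 90%-of-seeds
  # check at n = 500), each estimate within +-0.3
  for (s in 1:5) {
    set.seed(700 + s)
    n <- 500
    sc <- rnorm(n)
    site <- sample(1:6, n, TRUE)
    y <- rbinom(n, 1, plogis(-0.5 + 1 * sc))
    df <- data.frame(y = y, score = sc, site_id = site)
    tab <- fit_outcome_models(df, "y", "score", kind = "logistic_gee",
                              cluster = "site_id")
    expect_lt(abs(log(tab$estimate[tab$term == "score"]) - 1), 0.3)
  }

  # null covariate: CI covers 1 in most seeds (coverage sanity; the
  # sandwich needs a reasonable cluster count, hence 25 sites)
  cover <- vapply(1:10, function(s) {
    set.seed(800 + s)
    n <- 300
    df <- data.frame(y = rbinom(n, 1, 0.4), x = rnorm(n),
                     site_id = sample(1:25, n, TRUE))
    tab <- fit_outcome_models(df, "y", "x", kind = "logistic_gee",
                              cluster = "site_id")
    tab$conf.low[1] <= 1 && tab$conf.high[1] >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.8)
})

test_that("single-cluster data: clustered fit equals the ordinary fit", {
  set.seed(23)
  n <- 120
  df <- data.frame(x = rnorm(n), site_id = 1L)
  df$y <- rbinom(n, 1, plogis(df$x))
  gee <- fit_outcome_models(df, "y", "x", kind = "logistic_gee",
                            cluster = "site_id")
  plain <- fit_outcome_models(df, "y", "x", kind = "logistic")
  expect_equal(gee$estimate, plain$estimate, tolerance = 1e-8)
})

test_that("cox_mixed applies the recovery conventions and finds LRS effects", {
  sim <- generate_trauma_cohort(trauma_config(), seed = 31)
  pp <- preprocess_lipidomics(sim$matrix)
  cc <- sim$cohort[match(pp$imputed$sample_ids, sim$cohort$sample_id), ]
  cc$..lrs <- compute_lrs(
    lrs_model(core_pe_panel(), pp$z$ref_mean, pp$z$ref_sd), pp$z)
  d72 <- cc[cc$timepoint == "72h", ]
  tab <- fit_outcome_models(d72, outcome = NULL,
                            covariates = c("..lrs", "age", "iss", "tbi",
                                           "arm"),
                            kind = "cox_mixed")
  hr <- tab$estimate[tab$term == "..lrs"]
  expect_lt(hr, 1)  # higher score -> slower recovery
  expect_lt(tab$p[tab$term == "..lrs"], 0.05)
})
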