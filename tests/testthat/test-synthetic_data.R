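# MC seed counts here are scaled down from the full-size runs in
# test-acceptance.R to keep the default suite fast.

test_that("generators are byte-identical under the same seed", {
  cfg <- small_trauma_config()
  a <- generate_trauma_cohort(cfg, seed = 5)
  b <- generate_trauma_cohort(cfg, seed = 5)
  expect_identical(a, b)
  c1 <- generate_covid_cohort(covid_config(), seed = 5)
  c2 <- generate_covid_cohort(covid_config(), seed = 5)
  expect_identical(c1, c2)
  sc <- random_sem_config(5, n = 100, seed = 3)
  expect_identical(generate_sem(sc, 7), generate_sem(sc, 7))
})

test_that("invalid configs raise validation errors listing the problem", {
  expect_error(trauma_config(rho = 1.2), "rho")
  expect_error(trauma_config(rise72h = -1), "multipliers")
  expect_error(trauma_config(tp_attenuation = 2), "tp_attenuation")
  expect_error(covid_config(pe_effect = 0), "pe_effect")
  expect_error(covid_config(n = c(healthy = 0L, non_severe = 5L,
                                  severe = 5L)), "counts")
})

test_that("generated matrices pass container validation and study design", {
  sim <- generate_trauma_cohort(small_trauma_config(), seed = 2)
  expect_s3_class(sim$matrix, "lipidomics_matrix")
  expect_identical(sim$matrix$species,
                   canonical_lipid_labels(sim$matrix$species))
  expect_true(all(sim$matrix$values >= 0, na.rm = TRUE))
  # early non-survivors sampled at 0h only
  tab <- table(sim$cohort$outcome, sim$cohort$timepoint)
  expect_equal(sum(tab["early_nonsurvivor", c("24h", "72h")]), 0L)
  expect_gt(tab["early_nonsurvivor", "0h"], 0L)
  # planted subset is inside the panel
  expect_true(all(sim$truth$trauma_elevated %in% sim$matrix$species))
  # outcome labels re-derivable from the survival fields
  re <- assign_outcome(sim$cohort[, setdiff(names(sim$cohort), "outcome")])
  expect_equal(re$outcome, sim$cohort$outcome)
})

test_that("null world is calibrated: no spurious group differences", {
  # all multipliers 1 => any-species two-group KS test rejects ~ alpha.
  # Scaled to 40 seeds (the full-size MC uses 200).
  cfg <- small_trauma_config(
    drop0h = c(resolving = 1, non_resolving = 1, early_nonsurvivor = 1),
    supp24h = c(resolving = 1, non_resolving = 1),
    supp72h = c(resolving = 1, non_resolving = 1),
    rise72h = 1, down72h = 1, tp_attenuation = 0, missing_rate = 0)
  rej <- logical(40)
  for (s in seq_along(rej)) {
    sim <- generate_trauma_cohort(cfg, seed = 100 + s)
    cc <- sim$cohort[match(sim$matrix$sample_ids, sim$cohort$sample_id), ]
    keep <- cc$timepoint == "0h" &
      cc$outcome %in% c("resolving", "early_nonsurvivor")
    x <- sim$matrix$values[keep, 1L]
    g <- cc$outcome[keep]
    rej[s] <- suppressWarnings(
      stats::ks.test(x[g == "resolving"],
                     x[g == "early_nonsurvivor"])$p.value) < 0.05
  }
  # binomial(40, 0.05): reject H0 of calibration only far outside range
  expect_lte(sum(rej), 8)
})

test_that("planted PE effect is visible at 72h in non-resolvers", {
  # full-size check (n = 100/group, 50 seeds) runs in acceptance; here
  # 8 seeds at default group sizes, all must clear the 0.5 z gap
  gaps <- numeric(8)
  for (s in seq_along(gaps)) {
    sim <- generate_trauma_cohort(trauma_config(), seed = 300 + s)
    pp <- impute_min(filter_missing(sim$matrix))
    z <- zscore(pp)
    cc <- sim$cohort[match(pp$sample_ids, sim$cohort$sample_id), ]
    zz <- rowMeans(z$values[, sim$truth$elevated_species, drop = FALSE])
    at72 <- cc$timepoint == "72h"
    gaps[s] <- mean(zz[at72 & cc$outcome == "non_resolving"]) -
      mean(zz[at72 & cc$outcome == "resolving"])
  }
  expect_true(all(gaps > 0.5))
})

test_that("increasing rise72h strictly increases the 72h group contrast", {
  gaps <- vapply(c(1.2, 1.8, 2.5), function(r) {
    cfg <- small_trauma_config(rise72h = r)
    sim <- generate_trauma_cohort(cfg, seed = 77)
    pp <- impute_min(filter_missing(sim$matrix))
    cc <- sim$cohort[match(pp$sample_ids, sim$cohort$sample_id), ]
    sp <- intersect(sim$truth$elevated_species, pp$species)
    v <- log(rowMeans(pp$values[, sp, drop = FALSE]))
    at72 <- cc$timepoint == "72h"
    mean(v[at72 & cc$outcome == "non_resolving"]) -
      mean(v[at72 & cc$outcome == "resolving"])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("TP attenuates the 0h drop", {
  sim <- generate_trauma_cohort(trauma_config(), seed = 8)
  pp <- impute_min(filter_missing(sim$matrix))
  cc <- sim$cohort[match(pp$sample_ids, sim$cohort$sample_id), ]
  tot <- log(rowSums(pp$values))
  at0 <- cc$timepoint == "0h" & cc$outcome %in%
    c("resolving", "non_resolving")
  expect_gt(mean(tot[at0 & cc$arm == "TP"]),
            mean(tot[at0 & cc$arm == "standard_care"]))
})

test_that("covid cohort couples severity to CRP/lymphocyte and plants PE", {
  sim <- generate_covid_cohort(covid_config(), seed = 4)
  cc <- sim$cohort
  expect_gt(mean(cc$crp[cc$severity == "severe"]),
            mean(cc$crp[cc$severity == "non_severe"]))
  expect_lt(mean(cc$lymphocyte[cc$severity == "severe"]),
            mean(cc$lymphocyte[cc$severity == "non_severe"]))

  # zero-effect null: LRS difference centred at 0 across seeds
  diffs <- vapply(1:10, function(s) {
    null <- generate_covid_cohort(covid_config(pe_effect = 1), seed = s)
    z <- zscore(impute_min(filter_missing(null$matrix)))
    sc <- rowMeans(z$values[, null$truth$elevated_species, drop = FALSE])
    g <- null$cohort$severity
    mean(sc[g == "severe"]) - mean(sc[g == "non_severe"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.25)

  # default effect: logistic coefficient of the mean-z score has the
  # right sign (10 seeds, scaled from the full-size 50)
  signs <- vapply(1:10, function(s) {
    sim <- generate_covid_cohort(covid_config(), seed = 100 + s)
    z <- zscore(impute_min(filter_missing(sim$matrix)))
    sc <- rowMeans(z$values[, sim$truth$elevated_species, drop = FALSE])
    cc <- sim$cohort
    keep <- cc$severity != "healthy"
    fit <- glm(cc$severe[keep] ~ sc[keep], family = binomial())
    sign(coef(fit)[2])
  }, numeric(1))
  expect_true(all(signs > 0))
})

test_that("SEM generator matches closed-form implications", {
  # chain X -> Y -> Z with weights 0.8: r(X, Z) ~ product of path weights
  # on the standardized scale; partial r(X, Z | Y) ~ 0
  vars <- data.frame(name = c("X", "Y", "Z"), type = "continuous")
  edges <- data.frame(from = c("X", "Y"), to = c("Y", "Z"),
                      weight = c(0.8, 0.8))
  cfg <- sem_config(vars, edges, n = 5000L)
  sem <- generate_sem(cfg, seed = 10)
  d <- sem$data
  sx <- scale(d$X); sy <- scale(d$Y); sz <- scale(d$Z)
  r_expect <- 0.8 / sqrt(1 + 0.8^2) * 0.8 / sqrt(1 + 0.8^2 * (1 + 0.8^2) /
                                                   (1 + 0.8^2))
  # marginal correlation: product of standardized path coefficients
  r_xy <- 0.8 / sqrt(0.8^2 + 1)
  r_yz <- cor(d$Y, d$Z)
  expect_equal(cor(d$X, d$Z), cor(d$X, d$Y) * r_yz, tolerance = 0.05)
  expect_gt(cor(d$X, d$Z), 0.45)  # ~0.64 on the raw-weight scale
  pr <- cor(residuals(lm(d$X ~ d$Y)), residuals(lm(d$Z ~ d$Y)))
  expect_lt(abs(pr), 0.05)

  # empty edge set: all pairwise |r| small at n = 5000
  cfg0 <- sem_config(data.frame(name = c("A", "B", "C"),
                                type = "continuous"),
                     data.frame(from = character(0), to = character(0),
                                weight = numeric(0)), n = 5000L)
  s0 <- generate_sem(cfg0, seed = 3)
  cm <- cor(s0$data)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)

  # binary children via logistic link
  cfgb <- sem_config(data.frame(name = c("X", "B"),
                                type = c("continuous", "binary")),
                     data.frame(from = "X", to = "B", weight = 2),
                     n = 4000L)
  sb <- generate_sem(cfgb, seed = 2)
  expect_true(all(sb$data$B %in% 0:1))
  expect_gt(coef(glm(B ~ X, binomial(), data = sb$data))[2], 1.5)

  # cycles rejected
  expect_error(sem_config(vars,
                          data.frame(from = c("X", "Y", "Z"),
                                     to = c("Y", "Z", "X"), weight = 1)),
               "cycle")
})
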