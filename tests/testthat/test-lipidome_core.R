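test_that("parse_lipid_name handles the standard nomenclature and dialects", {
  x <- parse_lipid_name("PE (16:0_18:2)")
  expect_equal(x$lipid_class, "PE")
  expect_equal(unname(x$chains[, "carbons"]), c(16L, 18L))
  expect_equal(unname(x$chains[, "double_bonds"]), c(0L, 2L))
  expect_identical(format_lipid_name(x), "PE(16:0_18:2)")

  ce <- parse_lipid_name("CE(18:1)")
  expect_equal(nrow(ce$chains), 1L)

  # summation oracle over chain tuples
  chains <- list(c(16, 0), c(18, 1), c(18, 2))
  tag <- parse_lipid_name("TAG(16:0_18:1_18:2)")
  expect_equal(unname(tag$total["carbons"]),
               sum(vapply(chains, `[`, 0, 1)))
  expect_equal(unname(tag$total["double_bonds"]),
               sum(vapply(chains, `[`, 0, 2)))

  # sphingolipid dialect with base prefix and slash
  sm <- parse_lipid_name("SM(d18:1/16:0)")
  expect_identical(format_lipid_name(sm), "SM(16:0_18:1)")

  # summed TAG dialect is read-only
  ts <- parse_lipid_name("TAG52:3")
  expect_true(ts$summed)
  expect_equal(unname(ts$total), c(52L, 3L))

  expect_error(parse_lipid_name("XYZ(16:0)"), "unknown lipid class")
  expect_error(parse_lipid_name("PE(16:0)"), "arity")
  expect_error(parse_lipid_name("PE(16:0_18:2_20:4)"), "arity")
})

test_that("parse/format round-trips on randomly generated labels", {
  set.seed(42)
  for (i in 1:50) {
    cls <- sample(lipid_classes(), 1)
    arity <- c(TAG = 3, DAG = 2, PE = 2, PC = 2, PI = 2, SM = 2, CER = 2,
               HCER = 2, LCER = 2, DCER = 2, MAG = 1, LPE = 1, LPC = 1,
               CE = 1, FFA = 1)[[cls]]
    c_ <- sample(seq(12, 22, 2), arity, replace = TRUE)
    d_ <- vapply(c_, function(cc) sample(0:4, 1), 0L)
    lab <- sprintf("%s(%s)", cls, paste(sprintf("%d:%d", c_, d_),
                                        collapse = "_"))
    x <- parse_lipid_name(lab)
    y <- parse_lipid_name(format_lipid_name(x))
    expect_true(x == y)
  }
})

test_that("filter_missing applies the strict 'over 20%' rule", {
  v <- matrix(rlnorm(30), 10, 3)
  v[1:3, 1] <- NA   # 30% missing -> removed
  v[1:2, 2] <- NA   # 20% missing -> retained (not 'over 20%')
  m <- toy_matrix(v, c("PE(16:0_18:2)", "PC(16:0_18:1)", "TAG(16:0_16:0_18:1)"))
  f <- filter_missing(m, 0.20)
  expect_equal(f$species, c("PC(16:0_18:1)", "TAG(16:0_16:0_18:1)"))
  expect_equal(nrow(f$values), 10L)
  expect_equal(f$log$filter_missing$removed, "PE(16:0_18:2)")

  # no missing -> identity
  m2 <- toy_matrix(matrix(rlnorm(20), 5, 4),
                   c("PE(16:0_18:2)", "PC(16:0_18:1)", "CE(18:1)",
                     "FFA(18:2)"))
  expect_equal(filter_missing(m2)$values, m2$values)
  expect_error(filter_missing(m, -0.1), "max_frac")
})

test_that("impute_min fills missing cells with per-species minima", {
  v <- matrix(c(2, NA, 5, 1, 1, 1), 3, 2)
  m <- toy_matrix(v, c("PE(16:0_18:2)", "PC(16:0_18:1)"))
  imp <- impute_min(m)
  expect_equal(unname(imp$values[, 1]), c(2, 2, 5))
  expect_equal(impute_min(imp)$values, imp$values)  # identity on complete

  # constant observed column
  v2 <- matrix(c(3, NA, 3), 3, 1)
  m2 <- toy_matrix(v2, "CE(18:1)")
  expect_equal(unname(impute_min(m2)$values[, 1]), c(3, 3, 3))

  v3 <- matrix(NA_real_, 3, 1)
  expect_error(impute_min(toy_matrix(v3, "CE(18:1)")), "no observed")
})

test_that("class_summaries: totals, FA composition, SFA/USFA split", {
  v <- matrix(c(1, 3, 2, 4), 1, 4)
  m <- toy_matrix(v, c("PE(16:0_18:2)", "PE(16:0_20:4)", "CE(18:0)",
                       "CE(18:1)"), ids = "s1")
  cs <- class_summaries(m)
  expect_equal(unname(cs$class_totals[, "PE"]), 4)
  expect_equal(unname(cs$class_totals[, "CE"]), 6)
  expect_equal(cs$total_lipid[["s1"]], 10)
  # equal-chain weighting: PE(16:0_18:2) alone splits 50/50
  m1 <- toy_matrix(matrix(2, 1, 1), "PE(16:0_18:2)", ids = "s1")
  fa <- class_summaries(m1)$fa_composition$PE
  expect_equal(unname(fa[1, "16:0"]), 0.5)
  expect_equal(unname(fa[1, "18:2"]), 0.5)
  # all-saturated class -> zero USFA
  expect_equal(unname(class_summaries(
    toy_matrix(matrix(5, 1, 1), "CE(18:0)", ids = "s1"))$usfa[, "CE"]), 0)
  # FA proportions sum to 1
  expect_equal(unname(rowSums(cs$fa_composition$PE)), 1)
  # SFA + USFA decomposition is exhaustive (equals class totals)
  expect_equal(cs$sfa + cs$usfa, cs$class_totals)
})

test_that("class totals are invariant to species ordering", {
  sp <- c("PE(16:0_18:2)", "PE(16:0_20:4)", "CE(18:1)")
  v <- matrix(rlnorm(15), 5, 3)
  m1 <- toy_matrix(v, sp)
  perm <- c(3, 1, 2)
  m2 <- toy_matrix(v[, perm], sp[perm])
  c1 <- class_summaries(m1)
  c2 <- class_summaries(m2)
  expect_equal(c1$class_totals, c2$class_totals)
  expect_equal(rowSums(c1$class_totals), c1$total_lipid)
})

test_that("zscore uses the sample-sd convention and stores reference stats", {
  m <- toy_matrix(cbind(c(1, 2, 3)), "CE(18:1)")
  z <- zscore(m)
  expect_equal(unname(z$values[, 1]), c(-1, 0, 1))
  expect_equal(unname(z$ref_sd[1]), sd(c(1, 2, 3)))

  # reference-set columns have mean 0 / sd 1
  m2 <- toy_matrix(matrix(rlnorm(60), 12, 5),
                   sprintf("FFA(18:%d)", 0:4))
  z2 <- zscore(m2)
  expect_lt(max(abs(colMeans(z2$values))), 1e-9)
  expect_lt(max(abs(apply(z2$values, 2, sd) - 1)), 1e-9)

  # all-equal column errors
  expect_error(zscore(toy_matrix(cbind(rep(2, 4)), "CE(18:1)")),
               "zero-variance")

  # held-out sample at the reference mean scores 0
  held <- matrix(z2$ref_mean, 1, dimnames = list("new", z2$species))
  expect_equal(max(abs(apply_zscore(z2, held))), 0)

  # inverse transform recovers original values
  expect_equal(inverse_zscore(z2), m2$values, tolerance = 1e-9)
})

test_that("filter -> impute -> zscore is idempotent on its own output", {
  set.seed(7)
  v <- matrix(rlnorm(200), 20, 10)
  v[sample(length(v), 30)] <- NA
  m <- toy_matrix(v, sprintf("FFA(%d:%d)", seq(12, 30, 2), rep(0:1, 5)))
  p1 <- impute_min(filter_missing(m))
  p2 <- impute_min(filter_missing(p1))
  expect_equal(p2$values, p1$values)
  expect_equal(zscore(p2)$values, zscore(p1)$values)
})

test_that("assign_outcome implements the three-way rule with boundaries", {
  ch <- data.frame(
    sample_id = sprintf("p%d.0h", 1:5),
    subject_id = sprintf("p%d", 1:5),
    timepoint = "0h",
    died = c(0, 1, 0, 1, 0),
    death_day = c(NA, 2, NA, 4, NA),
    icu_los_days = c(4, 2, 7, 4, 30))
  out <- assign_outcome(ch)
  expect_equal(out$outcome,
               c("resolving",          # survivor, ICU 4 < 7
                 "early_nonsurvivor",  # death day 2 <= 3
                 "non_resolving",      # survivor, ICU exactly 7
                 "non_resolving",      # death day 4 > 3
                 "non_resolving"))
  # exactly one label each; healthy handled
  hc <- data.frame(sample_id = "h1.HC", subject_id = "h1",
                   timepoint = "HC", died = 0, death_day = NA,
                   icu_los_days = 0)
  expect_equal(assign_outcome(rbind(ch, hc))$outcome[6], "healthy")
  bad <- ch; bad$death_day[2] <- NA
  expect_error(assign_outcome(bad), "death_day")
})

test_that("embedding separates well-separated clusters and is deterministic", {
  set.seed(3)
  n <- 40; p <- 30
  lab <- rep(0:1, each = n / 2)
  v <- matrix(rnorm(n * p), n, p) + outer(lab * 10, rep(1, p))
  m <- toy_matrix(exp(v / 5), sprintf("FFA(%d:%d)", rep(seq(12, 40, 2), 2)[1:p],
                                      rep(0:1, each = 15)))
  z <- zscore(m)
  e1 <- embed_lipidome(z, n_pcs = 10, seed = 5)
  e2 <- embed_lipidome(z, n_pcs = 10, seed = 5)
  expect_identical(e1, e2)
  # 1-nearest-neighbour label purity oracle
  d <- as.matrix(dist(e1))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  expect_gt(mean(lab[nn] == lab), 0.95)
})
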