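#' Pairwise correlation matrix with t-distribution p-values
#'
#' Spearman or Pearson coefficients over complete pairs; p-values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Constant columns give `NA` coefficients.
#'
#' @param table Numeric matrix or data.frame (columns = variables).
#' @param method `"spearman"` or `"pearson"`.
#' @return List with `r`, `p` and `n` matrices.
#' @export
correlation_matrix <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- as.matrix(as.data.frame(table))
  storage.mode(x) <- "double"
  p_ <- ncol(x)
  r <- matrix(NA_real_, p_, p_, dimnames = list(colnames(x), colnames(x)))
  pm <- r
  nm <- matrix(0L, p_, p_, dimnames = dimnames(r))
  for (i in seq_len(p_)) for (j in i:p_) {
    ok <- stats::complete.cases(x[, c(i, j)])
    n <- sum(ok)
    nm[i, j] <- nm[j, i] <- n
    if (n < 4L) next
    xi <- x[ok, i]; xj <- x[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    rij <- stats::cor(xi, xj, method = method)
    r[i, j] <- r[j, i] <- rij
    if (abs(rij) >= 1) {
      pm[i, j] <- pm[j, i] <- 0
    } else {
      tstat <- rij * sqrt((n - 2) / (1 - rij^2))
      pm[i, j] <- pm[j, i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  diag(pm) <- ifelse(is.na(r[cbind(1:p_, 1:p_)]), NA, 0)
  list(r = r, p = pm, n = nm)
}

# vst-style variable-feature score: standardized residual of log variance
# from a local-regression mean-variance trend (global trend, rank within
# class). Returns residuals on the log-variance scale.
.vst_residual <- function(means, vars) {
  ok <- means > 0 & vars > 0
  res <- rep(NA_real_, length(means))
  lx <- log10(means[ok]); ly <- log10(vars[ok])
  if (sum(ok) >= 10L) {
    fit <- stats::loess(ly ~ lx, span = 0.5, degree = 2,
                        family = "gaussian")
    res[ok] <- ly - stats::predict(fit, lx)
  } else if (sum(ok) >= 3L) {
    fit <- stats::lm(ly ~ lx)
    res[ok] <- stats::residuals(fit)
  } else {
    res[ok] <- ly
  }
  res
}

#' Thresholded Pearson correlation network over variable species
#'
#' Species are first down-selected per class by a variance-stabilised
#' variability rank (residual from a fitted mean-variance trend), keeping
#' the top `per_class_top[[class]]` species (classes not listed are kept
#' in full). A Pearson correlation matrix over all samples is then
#' thresholded at `|r| >= r_thresh`.
#'
#' @param m An imputed `lipidomics_matrix` (concentrations; the trend is
#'   fitted on per-species mean/variance).
#' @param per_class_top Named list/vector of per-class retention counts,
#'   default `list(TAG = 100, DAG = 30, PE = 40, PC = 40)`.
#' @param r_thresh Edge threshold on `|r|` (default 0.7).
#' @return A `correlation_network`: list with `edges` (data.frame `node1`,
#'   `node2`, `r`), `nodes`, `selection` (per-class retained counts),
#'   `threshold` and `intra`/`inter` class edge counts.
#' @export
correlation_network <- function(m,
                                per_class_top = list(TAG = 100, DAG = 30,
                                                     PE = 40, PC = 40),
                                r_thresh = 0.7) {
  stopifnot(inherits(m, "lipidomics_matrix"))
  if (anyNA(m$values)) stop("matrix must be imputed first", call. = FALSE)
  cls <- lipid_class_of(m$species)
  means <- colMeans(m$values)
  vars <- apply(m$values, 2L, stats::var)
  score <- .vst_residual(means, vars)

  keep <- rep(TRUE, length(m$species))
  for (cl in names(per_class_top)) {
    idx <- which(cls == cl)
    k <- min(per_class_top[[cl]], length(idx))
    if (length(idx) > k) {
      ord <- idx[order(score[idx], decreasing = TRUE)]
      keep[setdiff(idx, ord[seq_len(k)])] <- FALSE
    }
  }
  v <- m$values[, keep, drop = FALSE]
  r <- stats::cor(v)
  sel <- which(abs(r) >= r_thresh - 1e-12 & upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(node1 = colnames(v)[sel[, 1L]],
                      node2 = colnames(v)[sel[, 2L]],
                      r = r[sel], stringsAsFactors = FALSE)
  c1 <- lipid_class_of(edges$node1)
  c2 <- lipid_class_of(edges$node2)
  structure(list(edges = edges, nodes = colnames(v),
                 selection = table(cls[keep]), threshold = r_thresh,
                 intra = sum(c1 == c2), inter = sum(c1 != c2)),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network> %d nodes, %d edges (|r| >= %.2f; %d intra-, %d inter-class)\n",
              length(x$nodes), nrow(x$edges), x$threshold, x$intra, x$inter))
  invisible(x)
}

#' Kaplan-Meier recovery analysis with ICU censoring conventions
#'
#' Event = discharge from ICU at `icu_los_days`. Early deaths (death day
#' <= `early_death_cut`) are excluded. Patients who died after day
#' `early_death_cut` can never recover: they are censored at the
#' dataset-maximum observed ICU stay. Stays beyond `max_day` are censored
#' at `max_day` (default 30).
#'
#' @param cohort Cohort table with `outcome`, `died`, `death_day`,
#'   `icu_los_days` and the grouping column; one row per subject is used
#'   (first row per `subject_id`).
#' @param group_col Column defining the curves (e.g. `"lrs_category"` or
#'   `"outcome"`).
#' @param max_day Administrative censoring horizon (default 30).
#' @param early_death_cut Early-death exclusion day (default 3).
#' @return A `recovery_curves` object: per-group `survfit`-derived step
#'   curves (`time`, `surv` = probability of still being in ICU,
#'   `n_risk`, `n_event`, `n_censor`), the prepared per-subject data, and
#'   pairwise log-rank p-values.
#' @export
recovery_km <- function(cohort, group_col = "outcome", max_day = 30,
                        early_death_cut = 3) {
  need <- c("subject_id", "died", "death_day", "icu_los_days", group_col)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- cohort[!duplicated(cohort$subject_id), need, drop = FALSE]
  if ("outcome" %in% names(cohort)) {
    oc <- cohort$outcome[!duplicated(cohort$subject_id)]
    d <- d[oc != "healthy", , drop = FALSE]
  }
  early <- d$died %in% 1 & d$death_day <= early_death_cut
  d <- d[!early, , drop = FALSE]
  if (!nrow(d)) stop("no subjects left after exclusions", call. = FALSE)

  time <- d$icu_los_days
  event <- rep(1L, nrow(d))
  late_death <- d$died %in% 1
  max_stay <- max(d$icu_los_days, na.rm = TRUE)
  time[late_death] <- max_stay
  event[late_death] <- 0L
  over <- time > max_day
  event[over] <- 0L
  time[over] <- max_day

  grp <- as.character(d[[group_col]])
  if (any(table(grp) == 0L)) stop("empty group", call. = FALSE)
  d$time <- time; d$event <- event; d$group <- grp

  fits <- lapply(split(seq_len(nrow(d)), grp), function(idx) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                            data = d[idx, , drop = FALSE])
    data.frame(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
               n_event = sf$n.event, n_censor = sf$n.censor)
  })

  groups <- sort(unique(grp))
  logrank <- NULL
  if (length(groups) > 1L) {
    pairs <- utils::combn(groups, 2L)
    logrank <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                          p = NA_real_, stringsAsFactors = FALSE)
    for (k in seq_len(ncol(pairs))) {
      sub <- d[grp %in% pairs[, k], , drop = FALSE]
      if (length(unique(sub$group)) < 2L || sum(sub$event) == 0L) next
      sd_ <- survival::survdiff(survival::Surv(time, event) ~ group,
                                data = sub)
      logrank$p[k] <- stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
    }
  }
  structure(list(curves = fits, data = d, logrank = logrank,
                 max_day = max_day, max_stay = max_stay),
            class = "recovery_curves")
}

#' @export
print.recovery_curves <- function(x, ...) {
  cat(sprintf("<recovery_curves> %d groups, %d subjects, censored at day %d\n",
              length(x$curves), nrow(x$data), x$max_day))
  invisible(x)
}

# cluster-robust (sandwich) covariance for a glm: independence-working GEE
.cluster_vcov <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  u <- stats::residuals(fit, type = "response") * X  # score contributions
  us <- rowsum(u, cluster)
  bread <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  g <- nrow(us)
  adj <- if (g > 1) g / (g - 1) else 1
  adj * bread %*% crossprod(us) %*% bread
}

#' Fit clustered / mixed outcome models and return tidy effect tables
#'
#' Three model kinds: `"logistic"` (plain logistic regression, odds
#' ratios), `"logistic_gee"` (logistic with cluster-robust sandwich
#' standard errors over `cluster`, an independence-working GEE), and
#' `"cox_mixed"` (proportional hazards for time-to-recovery with a
#' gamma frailty on `cluster`, hazard ratios).
#'
#' For `"cox_mixed"` the response is built with the recovery conventions
#' of [recovery_km()] from `died`/`death_day`/`icu_los_days`.
#'
#' @param data Data.frame (cohort-like).
#' @param outcome Outcome column (binary 0/1 for logistic kinds).
#' @param covariates Character vector of predictor columns.
#' @param kind One of `"logistic"`, `"logistic_gee"`, `"cox_mixed"`.
#' @param cluster Cluster id column (site), required for clustered kinds.
#' @return Data.frame: one row per term with `estimate` (OR or HR),
#'   `conf.low`, `conf.high`, `p`, `converged`.
#' @export
fit_outcome_models <- function(data, outcome, covariates,
                               kind = c("logistic", "logistic_gee",
                                        "cox_mixed"),
                               cluster = "site_id") {
  kind <- match.arg(kind)
  miss <- setdiff(c(if (kind != "cox_mixed") outcome, covariates),
                  names(data))
  if (length(miss))
    stop("data lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (nm in covariates)
    if (is.character(data[[nm]])) data[[nm]] <- factor(data[[nm]])

  tidy_row <- function(term, est, se, p, conv = TRUE)
    data.frame(term = term, estimate = exp(est),
               conf.low = exp(est - 1.96 * se),
               conf.high = exp(est + 1.96 * se), p = p,
               converged = conv, stringsAsFactors = FALSE)

  if (kind %in% c("logistic", "logistic_gee")) {
    f <- stats::as.formula(paste(outcome, "~",
                                 paste(covariates, collapse = " + ")))
    fit <- suppressWarnings(stats::glm(f, data = data,
                                       family = stats::binomial()))
    cf <- stats::coef(fit)
    V <- if (kind == "logistic_gee") {
      cl <- data[[cluster]][as.integer(rownames(stats::model.frame(fit)))]
      .cluster_vcov(fit, cl)
    } else stats::vcov(fit)
    se <- sqrt(diag(V))
    pv <- 2 * stats::pnorm(-abs(cf / se))
    out <- do.call(rbind, lapply(seq_along(cf), function(i)
      tidy_row(names(cf)[i], cf[i], se[i], pv[i], fit$converged)))
    return(out[out$term != "(Intercept)", , drop = FALSE])
  }

  # cox_mixed: time-to-recovery with frailty on cluster
  d <- data[!duplicated(data$subject_id), , drop = FALSE]
  if ("outcome" %in% names(d)) d <- d[d$outcome != "healthy", , drop = FALSE]
  early <- d$died %in% 1 & d$death_day <= 3
  d <- d[!early, , drop = FALSE]
  time <- d$icu_los_days
  event <- rep(1L, nrow(d))
  late <- d$died %in% 1
  time[late] <- max(d$icu_los_days, na.rm = TRUE)
  event[late] <- 0L
  event[time > 30] <- 0L
  time[time > 30] <- 30
  d$..time <- time; d$..event <- event
  f <- stats::as.formula(paste(
    "survival::Surv(..time, ..event) ~",
    paste(covariates, collapse = " + "),
    if (!is.null(cluster) && cluster %in% names(d))
      sprintf("+ survival::frailty(%s)", cluster) else ""))
  fit <- tryCatch(survival::coxph(f, data = d),
                  error = function(e) NULL)
  if (is.null(fit)) {
    return(data.frame(term = covariates, estimate = NA_real_,
                      conf.low = NA_real_, conf.high = NA_real_,
                      p = NA_real_, converged = FALSE,
                      stringsAsFactors = FALSE))
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[seq_along(cf)]
  pv <- 2 * stats::pnorm(-abs(cf / se))
  do.call(rbind, lapply(seq_along(cf), function(i)
    tidy_row(names(cf)[i], cf[i], se[i], pv[i])))
}
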