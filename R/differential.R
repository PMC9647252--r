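#' Covariate-adjusted logistic differential screen
#'
#' Per species, fits `outcome ~ species_z + covariates` by logistic
#' regression and collects the Wald p-value of the species term; p-values
#' are Benjamini-Hochberg adjusted across species within this analysis.
#' The log2 fold change is the log2 ratio of arithmetic group means of
#' concentrations (group2 / group1). A species passes when its adjusted
#' p-value is below `p_adj_thresh` and `|log2FC|` exceeds `lfc_thresh`.
#'
#' @param z A `zmatrix` over the analysis samples.
#' @param cohort Cohort table (rows matched to `z` by `sample_id`).
#' @param contrast Length-2 character: `c(group1, group2)` levels of
#'   `group_col`; the model codes group2 as 1. Default
#'   `c("resolving", "non_resolving")`.
#' @param group_col Cohort column holding the contrast levels.
#' @param timepoint Restrict to this timepoint (default `"72h"`; `NULL`
#'   keeps all rows).
#' @param covariates Cohort columns entered as covariates (default age,
#'   ISS, treatment arm).
#' @param p_adj_thresh,lfc_thresh Pass thresholds (defaults 0.01 and 0.4).
#' @param use_z Regress on z-scores (default) or raw concentrations.
#' @return A `differential_result`: data.frame (one row per species,
#'   sorted by adjusted p) with `species`, `direction`, `log2fc`, `p`,
#'   `p_adj`, `passes`, `flagged` (separation sentinel: `p = NA`,
#'   excluded from the pass list), plus metadata attributes.
#' @export
diff_logistic <- function(z, cohort,
                          contrast = c("resolving", "non_resolving"),
                          group_col = "outcome", timepoint = "72h",
                          covariates = c("age", "iss", "arm"),
                          p_adj_thresh = 0.01, lfc_thresh = 0.4,
                          use_z = TRUE) {
  stopifnot(inherits(z, "zmatrix"), length(contrast) == 2L)
  keep <- cohort[[group_col]] %in% contrast
  if (!is.null(timepoint)) keep <- keep & cohort$timepoint %in% timepoint
  cc <- cohort[keep, , drop = FALSE]
  cc <- cc[cc$sample_id %in% z$sample_ids, , drop = FALSE]
  miss_cov <- setdiff(covariates, names(cc))
  if (length(miss_cov))
    stop("covariates absent from cohort: ",
         paste(miss_cov, collapse = ", "), call. = FALSE)
  y <- as.integer(cc[[group_col]] == contrast[2L])
  if (sum(y == 0L) < 3L || sum(y == 1L) < 3L)
    stop("each contrast group needs >= 3 samples", call. = FALSE)

  zv <- z$values[cc$sample_id, , drop = FALSE]
  xv <- if (use_z) zv else
    sweep(sweep(zv, 2L, z$ref_sd, "*"), 2L, z$ref_mean, "+")
  conc <- sweep(sweep(zv, 2L, z$ref_sd, "*"), 2L, z$ref_mean, "+")

  # fixed covariate design, species column swapped in per fit
  X0 <- if (length(covariates)) {
    cov_df <- cc[, covariates, drop = FALSE]
    for (nm in names(cov_df))
      if (is.character(cov_df[[nm]])) cov_df[[nm]] <- factor(cov_df[[nm]])
    stats::model.matrix(~ ., data = cov_df)
  } else {
    matrix(1, nrow(cc), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  X <- cbind(X0, species = 0)
  k <- ncol(X)

  nsp <- ncol(zv)
  p <- rep(NA_real_, nsp)
  beta <- rep(NA_real_, nsp)
  flagged <- rep(FALSE, nsp)
  for (j in seq_len(nsp)) {
    X[, k] <- xv[, j]
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    cf <- fit$coefficients[k]
    sep <- !fit$converged || is.na(cf) || abs(cf * stats::sd(X[, k])) > 15
    if (sep) { flagged[j] <- TRUE; next }
    # Wald: se from the unscaled covariance of the IRLS fit
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    se <- tryCatch(sqrt(diag(chol2inv(chol(XtWX))))[k],
                   error = function(e) NA_real_)
    if (!is.finite(se) || se <= 0) { flagged[j] <- TRUE; next }
    zstat <- cf / se
    p[j] <- 2 * stats::pnorm(-abs(zstat))
    beta[j] <- cf
  }
  m1 <- colMeans(conc[y == 0L, , drop = FALSE])
  m2 <- colMeans(conc[y == 1L, , drop = FALSE])
  log2fc <- log2(m2 / m1)
  p_adj <- rep(NA_real_, nsp)
  ok <- !is.na(p)
  p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  passes <- ok & p_adj < p_adj_thresh & abs(log2fc) > lfc_thresh

  res <- data.frame(species = z$species,
                    direction = ifelse(log2fc >= 0, "up", "down"),
                    log2fc = log2fc, beta = beta, p = p, p_adj = p_adj,
                    passes = passes, flagged = flagged,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p_adj, res$p), ]
  attr(res, "rule") <- "logistic"
  attr(res, "contrast") <- contrast
  attr(res, "covariates") <- covariates
  attr(res, "thresholds") <- c(p_adj = p_adj_thresh, lfc = lfc_thresh)
  class(res) <- c("differential_result", class(res))
  res
}

#' Two-group Wilcoxon differential screen
#'
#' Two-sided rank-sum p-value per species (exact for group sizes <= 10
#' without ties; normal approximation with tie correction otherwise), with
#' the one-directional pass rule of the Fig-4-style screen: raw `p <
#' p_thresh` and `log2FC > lfc_thresh` (group2 higher than group1).
#' All-tied species get `p = 1`.
#'
#' @param m A `lipidomics_matrix` (imputed) or numeric matrix of
#'   concentrations.
#' @param groups Factor/character of length `nrow` with exactly two
#'   levels; the second level (`contrast[2]`) is the "higher" group.
#' @param contrast Optional explicit level ordering `c(group1, group2)`.
#' @param p_thresh,lfc_thresh Pass thresholds (defaults 0.05 and 0.4).
#' @return A `differential_result` data.frame as in [diff_logistic()].
#' @export
diff_wilcoxon <- function(m, groups, contrast = NULL, p_thresh = 0.05,
                          lfc_thresh = 0.4) {
  v <- if (inherits(m, "lipidomics_matrix")) m$values else as.matrix(m)
  if (anyNA(v)) stop("matrix must be imputed first", call. = FALSE)
  groups <- as.character(groups)
  lev <- if (is.null(contrast)) unique(groups) else contrast
  if (length(lev) != 2L || !all(groups %in% lev))
    stop("groups must have exactly two levels", call. = FALSE)
  g1 <- groups == lev[1L]; g2 <- groups == lev[2L]
  if (sum(g1) < 3L || sum(g2) < 3L)
    stop("each group needs >= 3 samples", call. = FALSE)

  nsp <- ncol(v)
  p <- numeric(nsp)
  for (j in seq_len(nsp)) {
    x2 <- v[g2, j]; x1 <- v[g1, j]
    if (all(x2 == x2[1L]) && all(x1 == x1[1L]) && x1[1L] == x2[1L]) {
      p[j] <- 1
      next
    }
    ties <- anyDuplicated(c(x1, x2)) > 0L
    exact <- !ties && max(sum(g1), sum(g2)) <= 10L
    p[j] <- suppressWarnings(
      stats::wilcox.test(x2, x1, exact = exact, correct = !exact)$p.value)
  }
  m1 <- colMeans(v[g1, , drop = FALSE])
  m2 <- colMeans(v[g2, , drop = FALSE])
  log2fc <- log2(m2 / m1)
  p_adj <- stats::p.adjust(p, method = "BH")
  passes <- p < p_thresh & log2fc > lfc_thresh

  res <- data.frame(species = colnames(v),
                    direction = ifelse(log2fc >= 0, "up", "down"),
                    log2fc = log2fc, p = p, p_adj = p_adj,
                    passes = passes, flagged = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p), ]
  attr(res, "rule") <- "wilcoxon"
  attr(res, "contrast") <- lev
  attr(res, "thresholds") <- c(p = p_thresh, lfc = lfc_thresh)
  class(res) <- c("differential_result", class(res))
  res
}
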