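#' Species common to several lipidomics datasets
#'
#' Intersection of canonical labels (class + sorted chains). Summed-TAG
#' dialect labels match by class + total carbons:double bonds.
#'
#' @param datasets List of `lipidomics_matrix` objects (>= 2).
#' @return Character vector of canonical labels present in every dataset.
#' @export
common_lipids <- function(datasets) {
  stopifnot(length(datasets) >= 2L)
  info <- lapply(datasets, function(m) {
    parsed <- lapply(m$species, parse_lipid_name)
    list(labels = m$species,
         summed = vapply(parsed, `[[`, logical(1), "summed"),
         total_key = vapply(parsed, function(p)
           sprintf("%s|%d:%d", p$lipid_class, p$total[["carbons"]],
                   p$total[["double_bonds"]]), character(1)))
  })
  first <- info[[1L]]
  keep <- vapply(seq_along(first$labels), function(i) {
    all(vapply(info[-1L], function(d) {
      # exact canonical match, or total-composition match when either
      # side uses the summed dialect
      first$labels[i] %in% d$labels ||
        any(d$total_key == first$total_key[i] &
              (d$summed | first$summed[i]))
    }, logical(1)))
  }, logical(1))
  first$labels[keep]
}

#' Sign-consistency screen of candidate panel species
#'
#' Correlates (Pearson) each candidate pool member with every passing
#' differential lipid across the z-matrix samples. A pool member is
#' retained when it correlates positively (r > `min_r`) with every
#' up-regulated lipid and negatively (r < `-min_r`) with every
#' down-regulated lipid.
#'
#' @param pool Character vector of candidate species (subset of
#'   `z$species`).
#' @param diff A `differential_result`.
#' @param z A `zmatrix`.
#' @param min_r Correlation magnitude threshold (default 0: sign only).
#' @param samples Optional sample ids over which correlations are
#'   computed (default: all samples of `z`); pass the contrast samples of
#'   the differential screen so that oppositely-moving lipids correlate
#'   negatively rather than through shared time-course structure.
#' @return List with `retained` (character), `correlations` (pool x
#'   differential-lipid matrix) and `up`/`down` lipid sets.
#' @export
screen_candidates <- function(pool, diff, z, min_r = 0, samples = NULL) {
  stopifnot(inherits(z, "zmatrix"))
  pool <- canonical_lipid_labels(pool)
  bad <- setdiff(pool, z$species)
  if (length(bad))
    stop("pool species absent from z-matrix: ",
         paste(bad, collapse = ", "), call. = FALSE)
  up <- diff$species[diff$passes & diff$direction == "up"]
  down <- diff$species[diff$passes & diff$direction == "down"]
  targets <- c(up, down)
  if (!length(targets))
    return(list(retained = pool,
                correlations = matrix(numeric(0), length(pool), 0,
                                      dimnames = list(pool, NULL)),
                up = up, down = down))
  targets <- intersect(targets, z$species)
  rows <- if (is.null(samples)) z$sample_ids else
    intersect(samples, z$sample_ids)
  r <- stats::cor(z$values[rows, pool, drop = FALSE],
                  z$values[rows, targets, drop = FALSE])
  ok <- vapply(pool, function(s) {
    # a pool member that is itself a target trivially satisfies its own cell
    all(r[s, intersect(up, targets)] > min_r) &&
      all(r[s, intersect(down, targets)] < -min_r)
  }, logical(1))
  list(retained = pool[ok], correlations = r, up = up, down = down)
}

#' Candidate panels by cross-dataset support
#'
#' Builds nested candidate sets from a screened pool the way the study's
#' 8/5/1 panels arise: for each support level `s = D..1`, the set of pool
#' members elevated (passing, direction up) in at least `s` of the `D`
#' per-dataset differential screens. Duplicate and empty sets are dropped.
#'
#' @param pool Screened candidate species.
#' @param diffs List of `differential_result` objects, one per dataset.
#' @return Named list of character vectors (`support_D`, ...,
#'   `support_1`).
#' @export
candidate_sets_by_support <- function(pool, diffs) {
  support <- sapply(pool, function(s) {
    sum(vapply(diffs, function(d) {
      any(d$species == s & d$passes & d$direction == "up")
    }, logical(1)))
  })
  sets <- list()
  for (s in rev(seq_along(diffs))) {
    mem <- sort(pool[support >= s])
    if (!length(mem)) next
    if (length(sets) && identical(sets[[length(sets)]], mem)) next
    sets[[sprintf("support_%d", s)]] <- mem
  }
  sets
}

#' Sensitivity analysis: select the panel with the strongest
#' cross-dataset outcome association
#'
#' Each candidate set is scored on each dataset as the mean z-score of its
#' members. Trauma-type datasets contribute a mixed-effects proportional-
#' hazards recovery effect (hazard ratio; lower HR = stronger adverse
#' association); severity-type datasets a logistic odds ratio. Within each
#' dataset, sets are ranked by the signed log effect in the hypothesised
#' direction (higher score -> slower recovery / higher severity); average
#' ranks across datasets decide, ties toward the smaller panel.
#'
#' @param candidate_sets Named list of species-label vectors.
#' @param datasets List of dataset descriptors, each a list with `z` (a
#'   `zmatrix`), `cohort`, and `kind` (`"trauma"` or `"severity"`);
#'   severity datasets need a binary `severe` cohort column, trauma
#'   datasets the recovery fields.
#' @param covariates_trauma,covariates_severity Adjustment covariates for
#'   the two model families.
#' @return An `lrs_model` built from the winning set, with the full
#'   sensitivity table in `$provenance$sensitivity` (one row per set x
#'   dataset: effect, CI, availability).
#' @export
sensitivity_select <- function(candidate_sets, datasets,
                               covariates_trauma = c("age", "iss", "tbi",
                                                     "arm"),
                               covariates_severity = c("age", "sex")) {
  stopifnot(length(candidate_sets) >= 1L, length(datasets) >= 1L)
  if (is.null(names(candidate_sets)))
    names(candidate_sets) <- sprintf("set_%d", seq_along(candidate_sets))

  rows <- list()
  signed <- matrix(NA_real_, length(candidate_sets), length(datasets),
                   dimnames = list(names(candidate_sets), NULL))
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    for (si in seq_along(candidate_sets)) {
      set <- candidate_sets[[si]]
      avail <- all(set %in% ds$z$species)
      eff <- NA_real_; lo <- NA_real_; hi <- NA_real_; pv <- NA_real_
      if (avail) {
        sc <- rowMeans(ds$z$values[, set, drop = FALSE])
        # standardise so effects are per score-SD: panels of different
        # sizes have different mean-z variances, and raw per-unit effects
        # would mechanically favour the noisier (smaller-variance) score
        sc <- (sc - mean(sc)) / stats::sd(sc)
        cc <- ds$cohort[match(rownames(ds$z$values), ds$cohort$sample_id), ]
        cc$..score <- sc
        if (ds$kind == "trauma") {
          keep <- cc$timepoint == "72h" & cc$outcome != "healthy"
          covs <- intersect(covariates_trauma, names(cc))
          tab <- fit_outcome_models(cc[keep, , drop = FALSE],
                                    outcome = NULL,
                                    covariates = c("..score", covs),
                                    kind = "cox_mixed")
          r <- tab[tab$term == "..score", ]
          if (nrow(r) == 1L && isTRUE(r$converged) && is.finite(r$estimate)) {
            eff <- r$estimate; lo <- r$conf.low; hi <- r$conf.high
            pv <- r$p
            signed[si, di] <- -log(eff)  # lower recovery HR = adverse
          }
        } else {
          covs <- intersect(covariates_severity, names(cc))
          keep <- if ("severity" %in% names(cc))
            cc$severity != "healthy" else rep(TRUE, nrow(cc))
          tab <- fit_outcome_models(cc[keep, , drop = FALSE],
                                    outcome = "severe",
                                    covariates = c("..score", covs),
                                    kind = "logistic")
          r <- tab[tab$term == "..score", ]
          if (nrow(r) == 1L && isTRUE(r$converged) && is.finite(r$estimate)) {
            eff <- r$estimate; lo <- r$conf.low; hi <- r$conf.high
            pv <- r$p
            signed[si, di] <- log(eff)  # higher severity OR = adverse
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        set = names(candidate_sets)[si], n_species = length(set),
        dataset = if (!is.null(ds$z$dataset_id)) ds$z$dataset_id else
          sprintf("dataset_%d", di),
        kind = ds$kind, available = avail,
        effect = eff, conf.low = lo, conf.high = hi, p = pv,
        stringsAsFactors = FALSE)
    }
  }
  sens <- do.call(rbind, rows)

  # rank within dataset by signed effect (desc); unavailable/failed sets
  # are penalised to the bottom
  ranks <- apply(signed, 2L, function(col) {
    col[is.na(col)] <- -Inf
    rank(-col, ties.method = "average")
  })
  if (is.null(dim(ranks))) ranks <- matrix(ranks, ncol = length(datasets))
  avg_rank <- rowMeans(ranks)
  sizes <- lengths(candidate_sets)
  best <- order(avg_rank, sizes)[1L]
  winner <- candidate_sets[[best]]

  # reference stats from the first trauma dataset (or first dataset)
  ref_i <- which(vapply(datasets, function(d) d$kind == "trauma",
                        logical(1)))[1L]
  if (is.na(ref_i)) ref_i <- 1L
  zref <- datasets[[ref_i]]$z
  lrs_model(panel = winner,
            ref_mean = zref$ref_mean[winner],
            ref_sd = zref$ref_sd[winner],
            provenance = list(candidate_sets = candidate_sets,
                              sensitivity = sens,
                              avg_rank = avg_rank,
                              selected = names(candidate_sets)[best]))
}

#' Construct a Lipid Reprogramming Score model
#'
#' @param panel Character vector of panel species (canonical labels).
#' @param ref_mean,ref_sd Named per-species reference statistics used to
#'   z-score raw concentrations.
#' @param cutpoints Optional tertile cutpoints `c(lower, upper)`.
#' @param provenance Free-form provenance list.
#' @return An `lrs_model`.
#' @export
lrs_model <- function(panel, ref_mean, ref_sd, cutpoints = NULL,
                      provenance = list()) {
  panel <- canonical_lipid_labels(panel)
  if (!length(panel)) stop("panel must be non-empty", call. = FALSE)
  if (!is.null(cutpoints) && diff(cutpoints) < 0)
    stop("cutpoints must be ordered", call. = FALSE)
  structure(list(panel = panel,
                 ref_mean = ref_mean[panel], ref_sd = ref_sd[panel],
                 cutpoints = cutpoints, provenance = provenance),
            class = "lrs_model")
}

#' @export
print.lrs_model <- function(x, ...) {
  cat("<lrs_model> panel of", length(x$panel), "species:\n ",
      paste(x$panel, collapse = ", "), "\n")
  if (!is.null(x$cutpoints))
    cat(sprintf("  tertile cutpoints: %.4f / %.4f\n",
                x$cutpoints[1], x$cutpoints[2]))
  invisible(x)
}

#' Compute the Lipid Reprogramming Score
#'
#' The arithmetic mean z-score of the panel species per sample. Raw
#' concentration input is z-scored with the model's stored reference
#' statistics.
#'
#' @param model An `lrs_model`.
#' @param x A `zmatrix`, `lipidomics_matrix`, or numeric matrix
#'   (samples x species; raw concentrations unless a `zmatrix`).
#' @param min_present Minimum number of panel species that must be
#'   present (default: all). Scores average over present species.
#' @return Named numeric vector of scores.
#' @export
compute_lrs <- function(model, x, min_present = length(model$panel)) {
  stopifnot(inherits(model, "lrs_model"))
  if (inherits(x, "zmatrix")) {
    have <- intersect(model$panel, x$species)
    zi <- x$values[, have, drop = FALSE]
  } else {
    v <- if (inherits(x, "lipidomics_matrix")) x$values else as.matrix(x)
    have <- intersect(model$panel, colnames(v))
    zi <- sweep(sweep(v[, have, drop = FALSE], 2L, model$ref_mean[have],
                      "-"), 2L, model$ref_sd[have], "/")
  }
  if (length(have) < min_present)
    stop("panel species absent beyond policy: missing ",
         paste(setdiff(model$panel, have), collapse = ", "),
         call. = FALSE)
  rowMeans(zi)
}

#' Tertile categorisation of scores
#'
#' Cutpoints are the 1/3 and 2/3 type-7 quantiles of a declared reference
#' population (for the study: patients alive at 72 h); categories are
#' assigned to all scored samples with `Low` = score <= lower cutpoint,
#' `Medium` = (lower, upper], `High` = above upper.
#'
#' @param scores Numeric scores to categorise.
#' @param population Scores defining the cutpoints (default: `scores`).
#' @return List with `category` (factor Low/Medium/High) and `cutpoints`.
#' @export
lrs_categories <- function(scores, population = scores) {
  if (length(population) < 3L || length(unique(population)) < 3L)
    stop("population needs >= 3 distinct values", call. = FALSE)
  cp <- stats::quantile(population, c(1, 2) / 3, type = 7, names = FALSE)
  cat_ <- cut(scores, breaks = c(-Inf, cp, Inf),
              labels = c("Low", "Medium", "High"), right = TRUE)
  list(category = cat_, cutpoints = cp)
}

#' Serialise / restore an LRS model as JSON
#'
#' @param model An `lrs_model`.
#' @param path JSON file path.
#' @return [read_lrs_model()]: an `lrs_model`.
#' @export
write_lrs_model <- function(model, path) {
  stopifnot(inherits(model, "lrs_model"))
  obj <- list(panel = model$panel,
              ref_mean = as.list(model$ref_mean),
              ref_sd = as.list(model$ref_sd),
              cutpoints = model$cutpoints,
              selected = model$provenance$selected)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_lrs_model
#' @export
read_lrs_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lrs_model(panel = obj$panel,
            ref_mean = unlist(obj$ref_mean),
            ref_sd = unlist(obj$ref_sd),
            cutpoints = if (length(obj$cutpoints)) obj$cutpoints else NULL,
            provenance = list(selected = obj$selected))
}

#' End-to-end LRS construction from a trauma and further datasets
#'
#' Convenience wrapper over the whole construction procedure:
#' intersect species across datasets, take the PE species of the
#' intersection as candidate pool, run the covariate-adjusted logistic
#' screen on the trauma dataset (non-resolving vs resolving at 72 h) and
#' a Wilcoxon screen on each severity dataset, sign-screen the pool,
#' build support-based candidate sets and select by sensitivity analysis.
#' Tertile cutpoints are fitted on trauma patients alive at 72 h.
#'
#' @param trauma List with `matrix` (imputed `lipidomics_matrix`... raw is
#'   accepted and preprocessed) and `cohort`.
#' @param others List of further datasets, each a list with `matrix`,
#'   `cohort` and `kind` (`"trauma"` or `"severity"`).
#' @param max_missing Missingness filter threshold.
#' @return An `lrs_model` with cutpoints and full provenance.
#' @export
build_lrs <- function(trauma, others, max_missing = 0.2) {
  prep <- function(m) impute_min(filter_missing(m, max_missing))
  m_tr <- prep(trauma$matrix)
  z_tr <- zscore(m_tr)
  diffs <- list()
  datasets <- list(list(z = z_tr, cohort = trauma$cohort, kind = "trauma"))
  d_tr <- diff_logistic(z_tr, trauma$cohort)
  diffs[[1L]] <- d_tr

  mats <- list(m_tr)
  for (o in others) {
    mo <- prep(o$matrix)
    zo <- zscore(mo)
    mats[[length(mats) + 1L]] <- mo
    datasets[[length(datasets) + 1L]] <-
      list(z = zo, cohort = o$cohort, kind = o$kind)
    if (o$kind == "severity") {
      cc <- o$cohort[match(mo$sample_ids, o$cohort$sample_id), ]
      keep <- cc$severity %in% c("non_severe", "severe")
      dsub <- lipidomics_matrix(mo$values[keep, , drop = FALSE],
                                dataset_id = mo$dataset_id)
      diffs[[length(diffs) + 1L]] <-
        diff_wilcoxon(dsub, cc$severity[keep],
                      contrast = c("non_severe", "severe"))
    } else {
      zo2 <- zo
      diffs[[length(diffs) + 1L]] <- diff_logistic(zo2, o$cohort)
    }
  }

  shared <- common_lipids(mats)
  pool <- shared[lipid_class_of(shared) == "PE"]
  if (!length(pool)) stop("no common PE species across datasets",
                          call. = FALSE)
  cc_tr <- trauma$cohort[match(m_tr$sample_ids, trauma$cohort$sample_id), ]
  contrast_samples <- m_tr$sample_ids[
    cc_tr$timepoint == "72h" &
      cc_tr$outcome %in% c("resolving", "non_resolving")]
  scr <- screen_candidates(pool, d_tr, z_tr, samples = contrast_samples)
  pool2 <- if (length(scr$retained)) scr$retained else pool
  sets <- candidate_sets_by_support(pool2, diffs)
  if (!length(sets)) sets <- list(support_0 = pool2)
  model <- sensitivity_select(sets, datasets)

  cc <- trauma$cohort[match(m_tr$sample_ids, trauma$cohort$sample_id), ]
  alive72 <- cc$timepoint == "72h" & cc$outcome %in%
    c("resolving", "non_resolving")
  pop <- compute_lrs(model, zscore(m_tr))[alive72]
  model$cutpoints <- lrs_categories(pop, pop)$cutpoints
  model$provenance$screen <- scr["retained"]
  model$provenance$pool <- pool
  model
}
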