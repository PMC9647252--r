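#' Validate a cohort table
#'
#' A cohort table has one row per sample (subject x timepoint) with
#' clinical annotation. Required columns: `sample_id`, `subject_id`,
#' `timepoint` (`HC`, `0h`, `24h`, `72h` for trauma; `baseline`,
#' `pre_progression`, `post_progression` for severity cohorts), `died`
#' (0/1), `death_day` (NA unless died), `icu_los_days`. Optional columns
#' carry covariates (`age`, `sex`, `iss`, `tbi`, `triss`, `inr`,
#' `site_id`, `bmi`, `arm`, biomarkers...).
#'
#' @param cohort A data.frame.
#' @return The validated data.frame (invisibly classed `cohort_table`).
#' @export
validate_cohort <- function(cohort) {
  req <- c("sample_id", "subject_id", "timepoint")
  miss <- setdiff(req, names(cohort))
  if (length(miss))
    stop("cohort table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cohort$sample_id))
    stop("duplicate sample ids in cohort table", call. = FALSE)
  if (anyDuplicated(cohort[, c("subject_id", "timepoint")]))
    stop("a subject has duplicate rows at one timepoint", call. = FALSE)
  if ("died" %in% names(cohort) && "death_day" %in% names(cohort)) {
    bad <- cohort$died %in% 1 & is.na(cohort$death_day)
    if (any(bad))
      stop("died flag set without death_day for subject(s): ",
           paste(unique(cohort$subject_id[bad]), collapse = ", "),
           call. = FALSE)
  }
  if ("icu_los_days" %in% names(cohort) &&
      any(cohort$icu_los_days < 0, na.rm = TRUE))
    stop("negative icu_los_days", call. = FALSE)
  if ("triss" %in% names(cohort) &&
      any(cohort$triss < 0 | cohort$triss > 1, na.rm = TRUE))
    stop("triss outside [0, 1]", call. = FALSE)
  class(cohort) <- unique(c("cohort_table", class(cohort)))
  invisible(cohort)
}

#' Assign the three-way clinical outcome
#'
#' Labels each patient: `resolving` (survival with ICU stay < `icu_cut_days`
#' days), `non_resolving` (survival with ICU stay >= `icu_cut_days` days,
#' or death after day `early_death_cut_days`), `early_nonsurvivor` (death
#' on or before day `early_death_cut_days`). Healthy controls (timepoint
#' `HC`) are labelled `healthy`.
#'
#' @param cohort A cohort table with `died`, `death_day`, `icu_los_days`.
#' @param icu_cut_days ICU length-of-stay threshold (default 7).
#' @param early_death_cut_days Early-death day threshold (default 3).
#' @return The cohort table with an `outcome` column.
#' @export
assign_outcome <- function(cohort, icu_cut_days = 7L,
                           early_death_cut_days = 3L) {
  cohort <- validate_cohort(cohort)
  need <- c("died", "death_day", "icu_los_days")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("assign_outcome needs columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  healthy <- cohort$timepoint == "HC"
  died <- cohort$died %in% 1
  if (any(died & is.na(cohort$death_day)))
    stop("died without death_day", call. = FALSE)
  out <- character(nrow(cohort))
  out[healthy] <- "healthy"
  pat <- !healthy
  out[pat & died & cohort$death_day <= early_death_cut_days] <-
    "early_nonsurvivor"
  out[pat & died & cohort$death_day > early_death_cut_days] <-
    "non_resolving"
  surv <- pat & !died
  out[surv & cohort$icu_los_days >= icu_cut_days] <- "non_resolving"
  out[surv & cohort$icu_los_days < icu_cut_days] <- "resolving"
  if (any(out == ""))
    stop("could not label some rows (missing survival/ICU fields?)",
         call. = FALSE)
  cohort$outcome <- out
  cohort
}

#' Read / write cohort tables
#'
#' @param path TSV (or CSV if the extension is `.csv`) with a `sample_id`
#'   column; booleans as 0/1.
#' @return A validated cohort table.
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  validate_cohort(df)
  df
}

#' @param cohort Cohort table to write.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(cohort, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' PCA + UMAP embedding of a z-scored lipidome
#'
#' Principal components are computed on the z-scored species matrix and
#' the first `n_pcs` component scores are embedded in two dimensions with
#' UMAP. The embedding is for reporting only and is deterministic under a
#' fixed seed (single-threaded optimisation).
#'
#' @param z A `zmatrix`.
#' @param n_pcs Number of principal components fed to UMAP (default 20).
#' @param n_neighbors,min_dist UMAP neighbourhood parameters.
#' @param seed Integer seed.
#' @return Matrix (samples x 2) of embedding coordinates, with the PC
#'   scores attached as attribute `"pcs"`.
#' @export
embed_lipidome <- function(z, n_pcs = 20L, n_neighbors = 15L,
                           min_dist = 0.1, seed = 1L) {
  stopifnot(inherits(z, "zmatrix"))
  if (ncol(z$values) < 2L) stop("need at least 2 species", call. = FALSE)
  n <- nrow(z$values)
  n_pcs <- min(n_pcs, n - 1L, ncol(z$values))
  if (n < n_pcs + 1L) stop("need more samples than PCs", call. = FALSE)
  pcs <- stats::prcomp(z$values, center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  set.seed(seed)
  emb <- uwot::umap(pcs, n_neighbors = min(n_neighbors, n - 1L),
                    min_dist = min_dist, n_threads = 1, n_sgd_threads = 0)
  rownames(emb) <- z$sample_ids
  colnames(emb) <- c("UMAP1", "UMAP2")
  attr(emb, "pcs") <- pcs
  emb
}
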