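#' Run the preprocessing stage: filter, impute, z-score
#'
#' @param m A raw `lipidomics_matrix`.
#' @param max_missing Missingness filter threshold (default 0.2).
#' @param reference Reference sample ids for the z-scores (default all).
#' @return List with `filtered`, `imputed` (`lipidomics_matrix`), `z`
#'   (`zmatrix`) and a `report` list (species counts, removals, imputed
#'   cell count).
#' @export
preprocess_lipidomics <- function(m, max_missing = 0.2, reference = NULL) {
  f <- filter_missing(m, max_missing)
  imp <- impute_min(f)
  z <- zscore(imp, reference)
  report <- list(
    dataset_id = m$dataset_id,
    n_samples = nrow(m$values),
    n_species_in = ncol(m$values),
    n_species_removed = f$log$filter_missing$n_removed,
    removed_species = f$log$filter_missing$removed,
    n_imputed_cells = imp$log$impute_min$n_imputed,
    max_missing = max_missing)
  list(filtered = f, imputed = imp, z = z, report = report)
}

#' Percentage from a printed count table
#'
#' Computes `100 * numerator / denominator` for a (variable, group) cell
#' of a demographic count table, as printed percentages in cohort tables
#' are derived from their counts.
#'
#' @param counts Data.frame with columns `variable`, `group`,
#'   `numerator`, `denominator`.
#' @param variable,group Cell selector.
#' @param digits Rounding digits (default 1, matching printed tables).
#' @return Percentage (numeric scalar).
#' @export
demographic_percent <- function(counts, variable, group, digits = 1L) {
  row <- counts[counts$variable == variable & counts$group == group, ]
  if (nrow(row) != 1L)
    stop("no unique (variable, group) cell: ", variable, " / ", group,
         call. = FALSE)
  round(100 * row$numerator / row$denominator, digits)
}

#' Difference in percentage points between two event rates
#'
#' @param p1,p2 Event rates in percent.
#' @param digits Rounding digits (default 1).
#' @return `p1 - p2`, percentage points.
#' @export
percentage_point_difference <- function(p1, p2, digits = 1L) {
  round(p1 - p2, digits)
}
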