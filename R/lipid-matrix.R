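#' Construct a lipidomics concentration matrix
#'
#' Samples x species concentration container with an explicit missingness
#' marker (`NA`). Species labels are canonicalised on construction.
#'
#' @param values Numeric matrix (samples x species), non-negative or `NA`.
#' @param sample_ids Character vector of unique sample identifiers;
#'   defaults to `rownames(values)`.
#' @param species Character vector of species labels (any accepted
#'   dialect); defaults to `colnames(values)`.
#' @param dataset_id Free-text dataset identifier.
#' @param units Concentration units (default micromolar).
#' @return A `lipidomics_matrix` object.
#' @export
lipidomics_matrix <- function(values, sample_ids = rownames(values),
                              species = colnames(values),
                              dataset_id = "dataset", units = "uM") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(species))
    stop("sample_ids and species must be supplied (or set as dimnames)",
         call. = FALSE)
  if (nrow(values) != length(sample_ids) || ncol(values) != length(species))
    stop("dimension mismatch between values and sample_ids/species",
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids", call. = FALSE)
  labs <- canonical_lipid_labels(species)
  if (anyDuplicated(labs))
    stop("duplicate species labels after canonicalisation: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("negative concentrations", call. = FALSE)
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite concentrations", call. = FALSE)
  dimnames(values) <- list(sample_ids, labs)
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         species = labs, dataset_id = dataset_id, units = units,
         log = list()),
    class = "lipidomics_matrix"
  )
}

#' @export
print.lipidomics_matrix <- function(x, ...) {
  cat(sprintf("<lipidomics_matrix> %s: %d samples x %d species (%s), %d missing cells\n",
              x$dataset_id, nrow(x$values), ncol(x$values), x$units,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.lipidomics_matrix <- function(x) dim(x$values)

#' Discard species with excess missingness
#'
#' Species whose fraction of missing values is strictly greater than
#' `max_frac` ("over 20%") are dropped; the sample set is unchanged. The
#' removal is recorded in the object's `log`.
#'
#' @param m A `lipidomics_matrix`.
#' @param max_frac Maximum tolerated missing fraction (default 0.20).
#' @return Filtered `lipidomics_matrix`.
#' @export
filter_missing <- function(m, max_frac = 0.20) {
  stopifnot(inherits(m, "lipidomics_matrix"))
  if (ncol(m$values) == 0L || nrow(m$values) == 0L)
    stop("empty matrix", call. = FALSE)
  if (!(max_frac >= 0 && max_frac < 1))
    stop("max_frac must be in [0, 1)", call. = FALSE)
  frac <- colMeans(is.na(m$values))
  drop <- frac > max_frac
  out <- m
  out$values <- m$values[, !drop, drop = FALSE]
  out$species <- m$species[!drop]
  out$log <- c(m$log, list(filter_missing = list(
    max_frac = max_frac, n_removed = sum(drop),
    removed = m$species[drop], missing_frac = frac)))
  out
}

#' Impute missing cells with the per-species minimum
#'
#' @param m A `lipidomics_matrix`; every species must have at least one
#'   observed value (run [filter_missing()] first).
#' @return `lipidomics_matrix` with no missing cells.
#' @export
impute_min <- function(m) {
  stopifnot(inherits(m, "lipidomics_matrix"))
  v <- m$values
  all_miss <- colSums(!is.na(v)) == 0L
  if (any(all_miss))
    stop("species with no observed values (filter first): ",
         paste(m$species[all_miss], collapse = ", "), call. = FALSE)
  n_imp <- sum(is.na(v))
  if (n_imp > 0L) {
    mins <- apply(v, 2L, min, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- mins[idx[, 2L]]
  }
  out <- m
  out$values <- v
  out$log <- c(m$log, list(impute_min = list(n_imputed = n_imp)))
  out
}

#' Class totals, fatty-acid composition and SFA/USFA decomposition
#'
#' Class totals are the sum of all species within a class. Fatty-acid
#' composition is the proportion of each class contributed by each acyl
#' chain key `"c:d"` under equal-chain weighting: each chain of a species
#' carries `concentration / n_chains`. Chains with zero double bonds count
#' as saturated (SFA), the rest as unsaturated (USFA).
#'
#' @param m An imputed `lipidomics_matrix` (no missing cells).
#' @return A list with `class_totals` (samples x classes matrix),
#'   `total_lipid` (per-sample sum over all species), `fa_composition`
#'   (per class: samples x chain-key proportion matrix), `sfa` and `usfa`
#'   (samples x classes chain-mass matrices) and `sfa_total`/`usfa_total`.
#' @export
class_summaries <- function(m) {
  stopifnot(inherits(m, "lipidomics_matrix"))
  if (anyNA(m$values)) stop("matrix must be imputed first", call. = FALSE)
  parsed <- lapply(m$species, parse_lipid_name)
  cls <- vapply(parsed, `[[`, character(1), "lipid_class")
  classes <- sort(unique(cls))
  v <- m$values

  class_totals <- vapply(classes, function(cl)
    rowSums(v[, cls == cl, drop = FALSE]), numeric(nrow(v)))
  if (nrow(v) == 1L) class_totals <- matrix(class_totals, nrow = 1L,
                                            dimnames = list(m$sample_ids, classes))

  fa_comp <- list()
  sfa <- matrix(0, nrow(v), length(classes),
                dimnames = list(m$sample_ids, classes))
  usfa <- sfa
  for (cl in classes) {
    sp_idx <- which(cls == cl)
    keys <- character(0)
    contrib <- list()
    for (j in sp_idx) {
      p <- parsed[[j]]
      if (p$summed) {
        # summed dialect carries no chain breakdown; count total as one key
        kk <- sprintf("%d:%d", p$total[["carbons"]], p$total[["double_bonds"]])
        w <- setNames(1, kk)
      } else {
        kk <- apply(p$chains, 1L, function(ch) sprintf("%d:%d", ch[1], ch[2]))
        w <- tapply(rep(1 / nrow(p$chains), nrow(p$chains)), kk, sum)
      }
      contrib[[length(contrib) + 1L]] <- list(j = j, w = w)
      keys <- union(keys, names(w))
    }
    keys <- keys[order(as.numeric(sub(":.*", "", keys)),
                       as.numeric(sub(".*:", "", keys)))]
    mass <- matrix(0, nrow(v), length(keys),
                   dimnames = list(m$sample_ids, keys))
    for (co in contrib) {
      mass[, names(co$w)] <- mass[, names(co$w), drop = FALSE] +
        outer(v[, co$j], unname(co$w))
    }
    db0 <- as.numeric(sub(".*:", "", keys)) == 0
    sfa[, cl] <- rowSums(mass[, db0, drop = FALSE])
    usfa[, cl] <- rowSums(mass[, !db0, drop = FALSE])
    tot <- rowSums(mass)
    prop <- mass / ifelse(tot > 0, tot, 1)
    prop[tot == 0, ] <- NA_real_
    fa_comp[[cl]] <- prop
  }

  list(class_totals = class_totals,
       total_lipid = rowSums(v),
       fa_composition = fa_comp,
       sfa = sfa, usfa = usfa,
       sfa_total = rowSums(sfa), usfa_total = rowSums(usfa))
}

#' z-score normalise a lipidomics matrix
#'
#' Per-species standardisation `(x - mean_ref) / sd_ref` where the
#' reference statistics are computed (with the sample, n-1, standard
#' deviation) over a declared reference sample set and stored so that new
#' samples can be scored on the same scale.
#'
#' @param m An imputed `lipidomics_matrix`.
#' @param reference Character vector of sample ids defining the reference
#'   population (default: all samples).
#' @return A `zmatrix`: list with `values` (z-scores for all samples of
#'   `m`), `ref_mean`, `ref_sd`, `reference_set`, plus sample/species
#'   metadata.
#' @export
zscore <- function(m, reference = NULL) {
  stopifnot(inherits(m, "lipidomics_matrix"))
  if (anyNA(m$values)) stop("matrix must be imputed first", call. = FALSE)
  if (is.null(reference)) reference <- m$sample_ids
  if (!all(reference %in% m$sample_ids))
    stop("reference contains unknown sample ids", call. = FALSE)
  if (length(reference) < 2L)
    stop("reference must contain at least 2 samples", call. = FALSE)
  ref <- m$values[reference, , drop = FALSE]
  mu <- colMeans(ref)
  sd_ <- apply(ref, 2L, stats::sd)
  bad <- !(sd_ > 0)
  if (any(bad))
    stop("zero-variance species over the reference set: ",
         paste(m$species[bad], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(m$values, 2L, mu, "-"), 2L, sd_, "/")
  structure(
    list(values = z, ref_mean = mu, ref_sd = sd_,
         reference_set = reference, sample_ids = m$sample_ids,
         species = m$species, dataset_id = m$dataset_id),
    class = "zmatrix"
  )
}

#' @export
print.zmatrix <- function(x, ...) {
  cat(sprintf("<zmatrix> %s: %d samples x %d species (reference: %d samples)\n",
              x$dataset_id, nrow(x$values), ncol(x$values),
              length(x$reference_set)))
  invisible(x)
}

#' Score new samples with stored reference statistics
#'
#' @param z A `zmatrix` (carries reference mean/sd).
#' @param newdata Numeric matrix or `lipidomics_matrix` of raw
#'   concentrations with (a superset of) the z-matrix's species.
#' @return Numeric matrix of z-scores for the new samples.
#' @export
apply_zscore <- function(z, newdata) {
  stopifnot(inherits(z, "zmatrix"))
  v <- if (inherits(newdata, "lipidomics_matrix")) newdata$values else
    as.matrix(newdata)
  miss <- setdiff(z$species, colnames(v))
  if (length(miss))
    stop("newdata lacks species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  v <- v[, z$species, drop = FALSE]
  sweep(sweep(v, 2L, z$ref_mean, "-"), 2L, z$ref_sd, "/")
}

#' Invert a z-matrix back to concentrations
#'
#' @param z A `zmatrix`.
#' @return Numeric matrix of reconstructed concentrations.
#' @export
inverse_zscore <- function(z) {
  stopifnot(inherits(z, "zmatrix"))
  sweep(sweep(z$values, 2L, z$ref_sd, "*"), 2L, z$ref_mean, "+")
}

#' Read / write lipidomics matrices as TSV/CSV
#'
#' First column is the sample id; remaining columns are species labels.
#' Missing values are empty cells or `"NA"`.
#'
#' @param path File path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param dataset_id,units Passed to [lipidomics_matrix()].
#' @return [read_lipidomics()]: a `lipidomics_matrix`.
#' @export
read_lipidomics <- function(path, dataset_id = basename(path), units = "uM") {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- as.character(df[[1L]])
  lipidomics_matrix(v, dataset_id = dataset_id, units = units)
}

#' @param m A `lipidomics_matrix` to write.
#' @rdname read_lipidomics
#' @export
write_lipidomics <- function(m, path) {
  stopifnot(inherits(m, "lipidomics_matrix"))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- data.frame(sample_id = m$sample_ids, m$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}
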