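#' Configuration for the synthetic COVID-like severity cohort
#'
#' Emulates a severity-stratified cohort measured on a smaller
#' cross-platform panel: the eight candidate PE species shared with the
#' trauma panel plus 21 other species (29 in total, matching the number of
#' lipids found in common across the study's four datasets). The five core
#' PE species are selectively elevated in severe patients; CRP rises and
#' lymphocyte count falls with severity.
#'
#' @param n Named counts for `healthy`, `non_severe`, `severe`.
#' @param pe_effect Multiplier on the core PE panel in severe patients.
#' @param rho Within-block correlation of the core PE panel.
#' @param noise_cv Lognormal noise CV.
#' @param missing_rate Bernoulli missingness rate per cell.
#' @return A `covid_config` list.
#' @export
covid_config <- function(n = c(healthy = 25L, non_severe = 25L,
                               severe = 20L),
                         pe_effect = 1.8, rho = 0.8, noise_cv = 0.35,
                         missing_rate = 0.02) {
  problems <- character(0)
  if (any(n < 1)) problems <- c(problems, "counts must be >= 1")
  if (pe_effect <= 0) problems <- c(problems, "pe_effect must be > 0")
  if (!(rho >= 0 && rho < 1)) problems <- c(problems, "rho must be in [0, 1)")
  if (length(problems))
    stop("invalid covid_config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  structure(list(n = n, pe_effect = pe_effect, rho = rho,
                 noise_cv = noise_cv, missing_rate = missing_rate),
            class = "covid_config")
}

#' Generate a synthetic COVID-like severity cohort
#'
#' @param cfg A [covid_config()].
#' @param seed Integer seed.
#' @return List with `matrix`, `cohort` (columns `severity`, `severe`,
#'   `age`, `sex`, `crp`, `lymphocyte`) and `truth` (`elevated_species` =
#'   the five core PE).
#' @export
generate_covid_cohort <- function(cfg = covid_config(), seed = 1L) {
  stopifnot(inherits(cfg, "covid_config"))
  set.seed(seed)

  other <- c(
    sprintf("PC(16:0_%d:%d)", c(16, 18, 18, 20, 20, 22), c(0, 1, 2, 3, 4, 6)),
    sprintf("PC(18:0_%d:%d)", c(18, 20, 22, 18), c(1, 4, 6, 2)),
    sprintf("PI(%d:0_%d:%d)", c(16, 16, 18, 18, 16), c(18, 20, 18, 20, 22),
            c(1, 4, 1, 4, 6)),
    sprintf("SM(18:1_%d:%d)", c(14, 16, 18, 20, 22, 24), c(0, 0, 0, 0, 0, 1)))
  panel <- canonical_lipid_labels(c(.CORE_PE, .EXTRA_PE, other))
  core_j <- panel %in% canonical_lipid_labels(.CORE_PE)

  groups <- rep(names(cfg$n), cfg$n)
  ns <- length(groups)
  subject_id <- sprintf("CV_%03d", seq_len(ns))
  sample_id <- paste(subject_id, "baseline", sep = ".")

  mu <- stats::runif(length(panel), -0.5, 1.5)
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  logmult <- matrix(0, ns, length(panel))
  logmult[groups == "severe", core_j] <- log(cfg$pe_effect)
  eps <- matrix(stats::rnorm(ns * length(panel)), ns)
  f <- stats::rnorm(ns)
  eps[, core_j] <- sqrt(cfg$rho) * f + sqrt(1 - cfg$rho) * eps[, core_j]
  vals <- exp(matrix(mu, ns, length(panel), byrow = TRUE) + logmult +
                sdlog * eps)
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(vals)) < cfg$missing_rate, ns)
    keep <- apply(mask, 2L, all)
    mask[1L, keep] <- FALSE
    vals[mask] <- NA_real_
  }
  dimnames(vals) <- list(sample_id, panel)
  mat <- lipidomics_matrix(vals,
                           dataset_id = sprintf("synthetic_covid_s%d", seed))

  crp_mu <- c(healthy = log(3), non_severe = log(20), severe = log(70))
  lym_mu <- c(healthy = log(2), non_severe = log(1.5), severe = log(0.8))
  cohort <- data.frame(
    sample_id = sample_id, subject_id = subject_id,
    timepoint = "baseline", severity = groups,
    severe = as.integer(groups == "severe"),
    age = pmin(pmax(round(stats::rnorm(ns, 55, 14)), 20L), 90L),
    sex = stats::rbinom(ns, 1L, 0.55),
    crp = round(stats::rlnorm(ns, crp_mu[groups], 0.6), 2),
    lymphocyte = round(stats::rlnorm(ns, lym_mu[groups], 0.3), 3),
    stringsAsFactors = FALSE)
  validate_cohort(cohort)

  truth <- list(elevated_species = canonical_lipid_labels(.CORE_PE),
                config = cfg, seed = seed)
  list(matrix = mat, cohort = cohort, truth = truth)
}
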