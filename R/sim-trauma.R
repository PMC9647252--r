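#' Configuration for the synthetic trauma cohort generator
#'
#' Defaults state the emulated world once: the study's own outcome-group
#' sizes (41 resolving / 101 non-resolving / 51 early non-survivors, 17
#' healthy controls) and arm split, a 996-species panel with the published
#' per-class counts (TAG 518, PE 128, PC 121, DAG 58, remainder spread
#' over the other classes), log-normal concentrations with multiplicative
#' group/time effects (0 h drop 0.6/0.6/0.3 of the healthy mean, deepest
#' in early non-survivors; persistent suppression thereafter; a correlated
#' x1.8 selective rise of a planted PE/TAG/DAG/CER subset at 72 h in
#' non-resolvers; attenuation of the 0 h drop under prehospital plasma),
#' and three signed mediator subsets.
#'
#' @param n_per_outcome Named counts for `resolving`, `non_resolving`,
#'   `early_nonsurvivor`.
#' @param tp_frac Fraction of each outcome group in the TP arm.
#' @param n_healthy Number of healthy controls.
#' @param species_counts Named per-class species counts (sums to 996 by
#'   default).
#' @param class_loc Named log-scale location (log uM) per class.
#' @param species_spread Half-width of the uniform spread of species
#'   locations around their class location (log scale).
#' @param drop0h Named 0 h multipliers per outcome (fraction of healthy
#'   mean).
#' @param supp24h,supp72h Named 24 h / 72 h multipliers for resolving and
#'   non-resolving patients.
#' @param rise72h Multiplier applied to the planted up-subset in
#'   non-resolvers at 72 h.
#' @param down72h Multiplier applied to the planted down-subset (LPC) in
#'   non-resolvers at 72 h.
#' @param tp_attenuation In `[0, 1]`: 0 leaves the 0 h drop untouched, 1
#'   restores TP-arm patients to the healthy mean at 0 h.
#' @param rho Within-block correlation of the planted up-subset.
#' @param noise_cv Lognormal measurement/biological noise CV.
#' @param missing_rate Bernoulli missingness rate per cell.
#' @param n_planted Named counts of planted species: `extra_pe`, `tag`,
#'   `dag`, `cer` (up in non-resolvers), `lpc_down` (down). The five core
#'   PE species are always planted and named after the canonical panel.
#' @param mediator_beta Named log-scale severity couplings for mediator
#'   `subset1` (pro-inflammatory, positive), `subset2`/`subset3`
#'   (negative), `endothelial` (positive) and `adiponectin` (negative).
#' @return A `trauma_config` list.
#' @export
trauma_config <- function(
    n_per_outcome = c(resolving = 41L, non_resolving = 101L,
                      early_nonsurvivor = 51L),
    tp_frac = c(resolving = 16 / 41, non_resolving = 53 / 101,
                early_nonsurvivor = 15 / 51),
    n_healthy = 17L,
    species_counts = c(TAG = 518L, PE = 128L, PC = 121L, DAG = 58L,
                       CE = 30L, SM = 30L, LPC = 20L, LPE = 15L, PI = 20L,
                       FFA = 20L, CER = 12L, HCER = 8L, LCER = 8L,
                       DCER = 8L),
    class_loc = c(TAG = 1.0, PE = 0.5, PC = 1.5, DAG = 0.0, CE = 2.0,
                  SM = 1.5, LPC = 1.0, LPE = 0.0, PI = 0.5, FFA = 1.5,
                  CER = -0.5, HCER = -1.0, LCER = -1.2, DCER = -1.5),
    species_spread = 0.8,
    drop0h = c(resolving = 0.6, non_resolving = 0.6,
               early_nonsurvivor = 0.3),
    supp24h = c(resolving = 0.55, non_resolving = 0.55),
    supp72h = c(resolving = 0.5, non_resolving = 0.5),
    rise72h = 1.8,
    down72h = 0.55,
    tp_attenuation = 0.5,
    rho = 0.8,
    noise_cv = 0.35,
    missing_rate = 0.02,
    n_planted = c(extra_pe = 0L, tag = 27L, dag = 6L, cer = 4L,
                  lpc_down = 3L),
    mediator_beta = c(subset1 = 0.5, subset2 = -0.3, subset3 = -0.3,
                      endothelial = 0.4, adiponectin = -0.3)) {
  cfg <- list(n_per_outcome = n_per_outcome, tp_frac = tp_frac,
              n_healthy = n_healthy, species_counts = species_counts,
              class_loc = class_loc, species_spread = species_spread,
              drop0h = drop0h, supp24h = supp24h, supp72h = supp72h,
              rise72h = rise72h, down72h = down72h,
              tp_attenuation = tp_attenuation, rho = rho,
              noise_cv = noise_cv, missing_rate = missing_rate,
              n_planted = n_planted, mediator_beta = mediator_beta)
  problems <- character(0)
  if (any(c(cfg$drop0h, cfg$supp24h, cfg$supp72h, cfg$rise72h,
            cfg$down72h) <= 0))
    problems <- c(problems, "all effect multipliers must be > 0")
  if (!(cfg$rho >= 0 && cfg$rho < 1))
    problems <- c(problems, "rho must be in [0, 1)")
  if (!(cfg$tp_attenuation >= 0 && cfg$tp_attenuation <= 1))
    problems <- c(problems, "tp_attenuation must be in [0, 1]")
  if (any(cfg$n_per_outcome < 1) || cfg$n_healthy < 1 ||
      any(cfg$species_counts < 1))
    problems <- c(problems, "counts must be >= 1")
  if (length(problems))
    stop("invalid trauma_config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  class(cfg) <- "trauma_config"
  cfg
}

# The five canonical PE species of the reprogramming-score panel.
.CORE_PE <- c("PE(16:0_18:2)", "PE(16:0_20:4)", "PE(16:0_22:6)",
              "PE(18:0_18:1)", "PE(18:0_22:6)")
.EXTRA_PE <- c("PE(16:0_18:1)", "PE(18:0_20:4)", "PE(18:1_18:2)")

#' The canonical five-species PE panel
#' @return Character vector of the five PE labels.
#' @export
core_pe_panel <- function() .CORE_PE

# Build a species panel with the requested per-class counts, always
# containing the core and extra PE species; chains are drawn from a
# plausible pool (uses the active RNG, so panels are seed-reproducible).
.build_panel <- function(species_counts) {
  chain_pool <- expand.grid(c = seq(12L, 22L, by = 2L), d = 0:6)
  chain_pool <- chain_pool[chain_pool$d <= chain_pool$c / 3, ]
  make <- function(cls, n, arity, fixed = character(0)) {
    labs <- fixed
    tries <- 0L
    while (length(labs) < n) {
      tries <- tries + 1L
      if (tries > 50L)
        stop("cannot build ", n, " unique ", cls, " labels", call. = FALSE)
      draw <- max(2L * (n - length(labs)), 32L)
      idx <- matrix(sample.int(nrow(chain_pool), draw * arity,
                               replace = TRUE), draw, arity)
      cand <- vapply(seq_len(draw), function(i) {
        ch <- chain_pool[idx[i, ], , drop = FALSE]
        o <- order(ch$c, ch$d)  # canonical chain sort
        sprintf("%s(%s)", cls,
                paste(sprintf("%d:%d", ch$c[o], ch$d[o]), collapse = "_"))
      }, character(1))
      labs <- c(labs, setdiff(unique(cand), labs))
    }
    labs[seq_len(n)]
  }
  out <- character(0)
  for (cls in names(species_counts)) {
    arity <- .LIPID_CLASS_ARITY[[cls]]
    fixed <- if (cls == "PE") c(.CORE_PE, .EXTRA_PE) else character(0)
    fixed <- fixed[seq_len(min(length(fixed), species_counts[[cls]]))]
    out <- c(out, make(cls, species_counts[[cls]], arity, fixed))
  }
  out
}

#' Generate a synthetic trauma cohort with planted ground truth
#'
#' Longitudinal design mirrors the study: healthy controls sampled once
#' (`HC`); resolving and non-resolving patients at 0, 24 and 72 h; early
#' non-survivors at 0 h only. Concentrations are log-normal with
#' multiplicative group/time effects; the planted up-subset shares a
#' per-sample latent factor giving within-block correlation `rho`.
#'
#' @param cfg A [trauma_config()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `matrix` (a `lipidomics_matrix`), `cohort` (a cohort
#'   table with outcomes assigned) and `truth` (planted ground truth:
#'   `elevated_species` = the five core PE, `trauma_elevated` = full
#'   planted up-subset, `down_species`, mediator coupling signs, config).
#' @export
generate_trauma_cohort <- function(cfg = trauma_config(), seed = 1L) {
  stopifnot(inherits(cfg, "trauma_config"))
  set.seed(seed)
  panel <- .build_panel(cfg$species_counts)
  cls <- lipid_class_of(panel)

  pick_first <- function(klass, n, exclude = character(0)) {
    cand <- setdiff(panel[cls == klass], exclude)
    cand[seq_len(min(n, length(cand)))]
  }
  planted_up <- c(.CORE_PE,
                  pick_first("PE", cfg$n_planted[["extra_pe"]], .CORE_PE),
                  pick_first("TAG", cfg$n_planted[["tag"]]),
                  pick_first("DAG", cfg$n_planted[["dag"]]),
                  pick_first("CER", cfg$n_planted[["cer"]]))
  planted_down <- pick_first("LPC", cfg$n_planted[["lpc_down"]])

  # species log-locations
  mu <- cfg$class_loc[cls] +
    stats::runif(length(panel), -cfg$species_spread, cfg$species_spread)
  names(mu) <- panel

  # subjects
  subj <- list()
  add_subjects <- function(outcome, n, tpfrac) {
    arm <- ifelse(seq_len(n) <= round(n * tpfrac), "TP", "standard_care")
    data.frame(subject_id = sprintf("%s_%02d", toupper(substr(outcome, 1, 3)),
                                    seq_len(n)),
               group = outcome, arm = arm, stringsAsFactors = FALSE)
  }
  subs <- rbind(
    data.frame(subject_id = sprintf("HC_%02d", seq_len(cfg$n_healthy)),
               group = "healthy", arm = "none", stringsAsFactors = FALSE),
    add_subjects("resolving", cfg$n_per_outcome[["resolving"]],
                 cfg$tp_frac[["resolving"]]),
    add_subjects("non_resolving", cfg$n_per_outcome[["non_resolving"]],
                 cfg$tp_frac[["non_resolving"]]),
    add_subjects("early_nonsurvivor",
                 cfg$n_per_outcome[["early_nonsurvivor"]],
                 cfg$tp_frac[["early_nonsurvivor"]])
  )
  ns <- nrow(subs)

  # subject-level covariates
  sev <- c(healthy = 0, resolving = 1, non_resolving = 2,
           early_nonsurvivor = 3)[subs$group]
  age <- pmin(pmax(round(stats::rnorm(ns, 45, 15)), 18L), 89L)
  sex <- stats::rbinom(ns, 1L, 0.75)
  iss_mu <- c(healthy = NA, resolving = 21, non_resolving = 30,
              early_nonsurvivor = 24)[subs$group]
  iss <- suppressWarnings(
    pmin(pmax(round(stats::rnorm(ns, iss_mu, 9)), 1L), 75L))
  tbi <- stats::rbinom(ns, 1L, c(healthy = 0, resolving = 0.34,
                                 non_resolving = 0.65,
                                 early_nonsurvivor = 0.57)[subs$group])
  triss_ab <- rbind(healthy = c(NA, NA), resolving = c(9, 1.5),
                    non_resolving = c(5, 2), early_nonsurvivor = c(2, 3))
  triss <- suppressWarnings(
    stats::rbeta(ns, triss_ab[subs$group, 1], triss_ab[subs$group, 2]))
  inr <- stats::rlnorm(ns, log(c(healthy = 1.0, resolving = 1.2,
                                 non_resolving = 1.3,
                                 early_nonsurvivor = 1.6)[subs$group]), 0.15)
  site_id <- sample.int(6L, ns, replace = TRUE)
  bmi <- round(stats::rnorm(ns, 27, 4), 1)

  died <- rep(0L, ns)
  death_day <- rep(NA_real_, ns)
  icu <- rep(NA_real_, ns)
  res_i <- subs$group == "resolving"
  icu[res_i] <- sample(1:6, sum(res_i), replace = TRUE)
  nres_i <- which(subs$group == "non_resolving")
  late_death <- stats::rbinom(length(nres_i), 1L, 0.15) == 1L
  icu[nres_i[!late_death]] <-
    pmin(7 + stats::rgeom(sum(!late_death), 0.12), 60)
  dd <- sample(4:20, sum(late_death), replace = TRUE)
  died[nres_i[late_death]] <- 1L
  death_day[nres_i[late_death]] <- dd
  icu[nres_i[late_death]] <- dd
  early_i <- which(subs$group == "early_nonsurvivor")
  dd <- sample(1:3, length(early_i), replace = TRUE, prob = c(.4, .4, .2))
  died[early_i] <- 1L
  death_day[early_i] <- dd
  icu[early_i] <- dd
  icu[subs$group == "healthy"] <- 0

  # sample rows (subject x timepoint)
  tp_of <- function(g) switch(g,
    healthy = "HC",
    early_nonsurvivor = "0h",
    c("0h", "24h", "72h"))
  rows <- do.call(rbind, lapply(seq_len(ns), function(i) {
    data.frame(subject_idx = i, timepoint = tp_of(subs$group[i]),
               stringsAsFactors = FALSE)
  }))
  nsam <- nrow(rows)
  sample_id <- paste(subs$subject_id[rows$subject_idx], rows$timepoint,
                     sep = ".")

  # multiplicative effects (log scale), per sample x species
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  up_j <- panel %in% planted_up
  down_j <- panel %in% planted_down
  g_s <- subs$group[rows$subject_idx]
  a_s <- subs$arm[rows$subject_idx]
  t_s <- rows$timepoint
  base_m <- rep(1, nsam)
  at0 <- t_s == "0h"
  base_m[at0] <- cfg$drop0h[g_s[at0]]
  tp0 <- at0 & a_s == "TP"
  base_m[tp0] <- base_m[tp0] + cfg$tp_attenuation * (1 - base_m[tp0])
  at24 <- t_s == "24h"
  base_m[at24] <- cfg$supp24h[g_s[at24]]
  at72 <- t_s == "72h"
  base_m[at72] <- cfg$supp72h[g_s[at72]]
  logmult <- matrix(log(base_m), nsam, length(panel))
  sel72 <- at72 & g_s == "non_resolving"
  logmult[sel72, up_j] <- logmult[sel72, up_j] + log(cfg$rise72h)
  logmult[sel72, down_j] <- logmult[sel72, down_j] + log(cfg$down72h)

  # noise with a shared latent factor over the planted up-block
  eps <- matrix(stats::rnorm(nsam * length(panel)), nsam)
  f <- stats::rnorm(nsam)
  eps[, up_j] <- sqrt(cfg$rho) * f + sqrt(1 - cfg$rho) * eps[, up_j]
  logx <- matrix(mu, nsam, length(panel), byrow = TRUE) + logmult +
    sdlog * eps
  vals <- exp(logx)

  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(vals)) < cfg$missing_rate,
                   nrow(vals))
    # keep at least one observed value per species
    keep <- apply(mask, 2L, all)
    mask[1L, keep] <- FALSE
    vals[mask] <- NA_real_
  }
  dimnames(vals) <- list(sample_id, panel)
  mat <- lipidomics_matrix(vals, dataset_id = sprintf("synthetic_trauma_s%d", seed))

  # mediators, per sample (log-normal, coupled to outcome severity)
  med_sets <- list(
    subset1 = c("IL6", "IL8", "IL10", "MCP1", "IP10", "MIG"),
    subset2 = c("IL2", "IL4", "IL5", "IL7", "IL17A", "GMCSF"),
    subset3 = c("IL9", "IL21", "IL22", "IL23", "IL25", "IL27", "IL33"),
    endothelial = c("syndecan1", "thrombomodulin", "sVEGFR", "sICAM1",
                    "sVCAM1", "ANG2"),
    adiponectin = "adiponectin")
  sev_sample <- sev[rows$subject_idx]
  med <- list()
  for (set in names(med_sets)) {
    beta <- cfg$mediator_beta[[set]]
    shared <- stats::rnorm(nsam)
    for (mk in med_sets[[set]]) {
      med[[mk]] <- stats::rlnorm(nsam,
        meanlog = 2 + beta * sev_sample + 0.4 * shared, sdlog = 0.4)
    }
  }

  cohort <- data.frame(
    sample_id = sample_id,
    subject_id = subs$subject_id[rows$subject_idx],
    timepoint = rows$timepoint,
    arm = subs$arm[rows$subject_idx],
    died = died[rows$subject_idx],
    death_day = death_day[rows$subject_idx],
    icu_los_days = icu[rows$subject_idx],
    age = age[rows$subject_idx], sex = sex[rows$subject_idx],
    iss = iss[rows$subject_idx], tbi = tbi[rows$subject_idx],
    triss = triss[rows$subject_idx], inr = round(inr[rows$subject_idx], 2),
    site_id = site_id[rows$subject_idx], bmi = bmi[rows$subject_idx],
    stringsAsFactors = FALSE)
  for (mk in names(med)) cohort[[mk]] <- round(med[[mk]], 4)
  cohort <- assign_outcome(cohort)

  truth <- list(
    elevated_species = .CORE_PE,
    trauma_elevated = planted_up,
    down_species = planted_down,
    mediator_signs = sign(cfg$mediator_beta),
    config = cfg, seed = seed)

  list(matrix = mat, cohort = cohort, truth = truth)
}
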