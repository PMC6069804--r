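#' Specify a panel of simulated SNPs
#'
#' Builds the per-SNP parameter table used by [simulate_genotypes()] and
#' [sim_config()]. Each SNP is described by its minor-allele frequency and a
#' missing-call rate; genotypes are later drawn under Hardy-Weinberg
#' equilibrium with dosage coding 0/1/2 (copies of the minor allele).
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param maf minor-allele frequencies, each in (0, 0.5].
#' @param missing_rate per-SNP probability that a genotype call is missing,
#'   each in \[0, 1).
#' @return a data.frame with columns `snp_id`, `maf`, `missing_rate`.
#' @export
snp_spec <- function(snp_id, maf, missing_rate = 0) {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id)) stop("snp_id values must be unique")
  maf <- rep_len(as.numeric(maf), length(snp_id))
  missing_rate <- rep_len(as.numeric(missing_rate), length(snp_id))
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    stop("maf must lie in (0, 0.5]")
  }
  if (any(!is.finite(missing_rate)) || any(missing_rate < 0) ||
      any(missing_rate >= 1)) {
    stop("missing_rate must lie in [0, 1)")
  }
  data.frame(snp_id = snp_id, maf = maf, missing_rate = missing_rate,
             stringsAsFactors = FALSE)
}

.check_snp_specs <- function(snp_specs) {
  req <- c("snp_id", "maf", "missing_rate")
  if (!is.data.frame(snp_specs) || !all(req %in% names(snp_specs))) {
    stop("snp_specs must be a data.frame with columns snp_id, maf, missing_rate")
  }
  snp_spec(snp_specs$snp_id, snp_specs$maf, snp_specs$missing_rate)
}

#' Simulate a genotype dosage matrix under Hardy-Weinberg equilibrium
#'
#' Each SNP is drawn independently: the dosage of subject i at SNP j is
#' Binomial(2, q_j), giving genotype probabilities
#' ((1-q)^2, 2q(1-q), q^2) for minor-allele frequency q. Calls are then
#' masked missing-completely-at-random at the SNP's `missing_rate`.
#'
#' @param snp_specs data.frame from [snp_spec()].
#' @param n_subjects number of subjects (rows), at least 1.
#' @param seed optional integer; when supplied the draw is a pure function of
#'   (snp_specs, n_subjects, seed).
#' @return numeric matrix (subjects x SNPs) with entries 0/1/2 or `NA`,
#'   dimnames = (subject ids, SNP ids).
#' @export
simulate_genotypes <- function(snp_specs, n_subjects, seed = NULL) {
  snp_specs <- .check_snp_specs(snp_specs)
  n_subjects <- as.integer(n_subjects)
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 1L) {
    stop("n_subjects must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(snp_specs)
  G <- matrix(NA_real_, n_subjects, p,
              dimnames = list(sprintf("S%05d", seq_len(n_subjects)),
                              snp_specs$snp_id))
  for (j in seq_len(p)) {
    d <- stats::rbinom(n_subjects, 2L, snp_specs$maf[j])
    mr <- snp_specs$missing_rate[j]
    if (mr > 0) d[stats::runif(n_subjects) < mr] <- NA_real_
    G[, j] <- d
  }
  G
}

#' Build a simulation configuration
#'
#' Defines the structural model used by [simulate_cohort()]:
#' \deqn{X = \mu_x + \sum_j \gamma_j Z_j + \kappa_x U + a_x \tilde{age} + s_x sex + \epsilon_x}
#' \deqn{Y_m = \mu_{y,m} + \beta_m X + \sum_j \alpha_{jm} Z_j + \kappa_{y,m} U
#'   + s_m(\sqrt{\rho_b} F_b + \sqrt{1-\rho_b}\, e_m)}
#' where U is a standard-normal latent confounder shared by exposure and
#' outcomes, F_b is a standard-normal factor shared by all outcomes in block
#' b (giving within-block residual correlation rho_b), and age is centred at
#' its mean. X is the log of BMI; outcomes are log concentrations.
#' Instruments with any nonzero pleiotropic effect `alpha[j, ]` are invalid
#' in the sense of the exclusion-restriction condition.
#'
#' @param n_subjects cohort size.
#' @param snp_specs SNP panel from [snp_spec()].
#' @param gamma per-SNP instrument-exposure effects (log-BMI units per minor
#'   allele); length = number of SNPs.
#' @param beta per-outcome causal effect of X on Y (log-concentration units
#'   per log-BMI unit); scalars are recycled over `n_outcomes`.
#' @param n_outcomes number of outcomes; defaults to `length(beta)`.
#' @param alpha SNP x outcome matrix of direct (pleiotropic) effects;
#'   default all zero.
#' @param kappa_x,kappa_y confounder loadings on the exposure (scalar) and on
#'   each outcome (recycled vector).
#' @param age_effect_x,sex_effect_x,age_effect_y,sex_effect_y covariate
#'   coefficients; the outcome coefficients are recycled per outcome.
#' @param outcome_blocks integer/character block label per outcome; defaults
#'   to a single block.
#' @param block_cor within-block residual correlation in \[0, 1); recycled
#'   per block (order of `unique(outcome_blocks)`).
#' @param noise_sd_x residual SD of the exposure.
#' @param noise_sd_y residual SD of each outcome (excluding the confounder
#'   term), recycled.
#' @param mu_x mean log BMI; `exp(mu_x)` is the typical BMI in kg/m^2.
#' @param mu_y per-outcome intercepts, recycled.
#' @param outcome_missing_rate MCAR missingness applied to the reported
#'   concentrations.
#' @param seed integer seed; mandatory so that a config fully determines the
#'   cohort.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects, snp_specs, gamma, beta, n_outcomes = length(beta),
                       alpha = NULL, kappa_x = 0, kappa_y = 0,
                       age_effect_x = 0, sex_effect_x = 0,
                       age_effect_y = 0, sex_effect_y = 0,
                       outcome_blocks = rep(1L, n_outcomes), block_cor = 0,
                       noise_sd_x = 1, noise_sd_y = 1,
                       mu_x = log(26.5), mu_y = 0,
                       outcome_missing_rate = 0, seed) {
  snp_specs <- .check_snp_specs(snp_specs)
  p <- nrow(snp_specs)
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed is mandatory in a simulation config")
  }
  if (length(gamma) != p) {
    stop(sprintf("gamma has length %d but there are %d SNPs (field 'gamma')",
                 length(gamma), p))
  }
  n_outcomes <- as.integer(n_outcomes)
  if (n_outcomes < 1L) stop("n_outcomes must be >= 1 (field 'n_outcomes')")
  beta <- rep_len(as.numeric(beta), n_outcomes)
  if (is.null(alpha)) alpha <- matrix(0, p, n_outcomes)
  alpha <- as.matrix(alpha)
  if (nrow(alpha) != p || ncol(alpha) != n_outcomes) {
    stop(sprintf(
      "alpha must be %d SNPs x %d outcomes, got %d x %d (field 'alpha')",
      p, n_outcomes, nrow(alpha), ncol(alpha)))
  }
  if (length(outcome_blocks) != n_outcomes) {
    stop("outcome_blocks must have one label per outcome (field 'outcome_blocks')")
  }
  blocks <- as.character(outcome_blocks)
  block_cor <- rep_len(as.numeric(block_cor), length(unique(blocks)))
  names(block_cor) <- unique(blocks)
  if (any(block_cor < 0) || any(block_cor >= 1)) {
    stop("within-block correlation must lie in [0, 1) (field 'block_cor')")
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    snp_specs = snp_specs,
    gamma = as.numeric(gamma),
    beta = beta,
    n_outcomes = n_outcomes,
    alpha = alpha,
    kappa_x = as.numeric(kappa_x),
    kappa_y = rep_len(as.numeric(kappa_y), n_outcomes),
    age_effect_x = as.numeric(age_effect_x),
    sex_effect_x = as.numeric(sex_effect_x),
    age_effect_y = rep_len(as.numeric(age_effect_y), n_outcomes),
    sex_effect_y = rep_len(as.numeric(sex_effect_y), n_outcomes),
    outcome_blocks = blocks,
    block_cor = block_cor,
    noise_sd_x = as.numeric(noise_sd_x),
    noise_sd_y = rep_len(as.numeric(noise_sd_y), n_outcomes),
    mu_x = as.numeric(mu_x),
    mu_y = rep_len(as.numeric(mu_y), n_outcomes),
    outcome_missing_rate = as.numeric(outcome_missing_rate),
    seed = as.integer(seed)
  )
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1 (field 'n_subjects')")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a full cohort with known ground truth
#'
#' Draws genotypes, a latent confounder, age and sex, then the exposure and
#' block-correlated outcomes from the linear normal additive structural model
#' described in [sim_config()]. Missing dosages are mean-imputed before they
#' enter the exposure and outcome equations, so the structural effects refer
#' to the (partially observed) true dosage scale. The returned cohort table
#' reports BMI and concentrations on the natural scale; the analysis pipeline
#' takes logs.
#'
#' @param config a `sim_config`.
#' @return a list with elements
#'   \describe{
#'     \item{genotypes}{subjects x SNPs dosage matrix with `NA` for missing.}
#'     \item{cohort}{data.frame `subject_id`, `bmi`, `age`, `sex`, then one
#'       column per outcome (`M001`, ...) holding concentrations.}
#'     \item{truth}{ground truth: the config, per-subject confounder values,
#'       the realised log-BMI vector, the outcome block labels and the set of
#'       invalid instruments (SNPs with any nonzero pleiotropic effect).}
#'   }
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be built by sim_config()")
  set.seed(config$seed)
  n <- config$n_subjects
  m <- config$n_outcomes
  G <- simulate_genotypes(config$snp_specs, n)
  U <- stats::rnorm(n)
  age <- stats::runif(n, 25, 74)
  sex <- stats::rbinom(n, 1L, 0.5)
  Zimp <- G
  for (j in seq_len(ncol(Zimp))) {
    nas <- is.na(Zimp[, j])
    if (any(nas)) Zimp[nas, j] <- mean(Zimp[, j], na.rm = TRUE)
  }
  age_c <- age - 49.5
  X <- config$mu_x + drop(Zimp %*% config$gamma) + config$kappa_x * U +
    config$age_effect_x * age_c + config$sex_effect_x * sex +
    stats::rnorm(n, 0, config$noise_sd_x)

  blocks <- config$outcome_blocks
  ub <- unique(blocks)
  Fb <- matrix(stats::rnorm(n * length(ub)), n, length(ub),
               dimnames = list(NULL, ub))
  Y <- matrix(NA_real_, n, m)
  for (k in seq_len(m)) {
    rho <- config$block_cor[[blocks[k]]]
    s <- config$noise_sd_y[k]
    resid <- s * (sqrt(rho) * Fb[, blocks[k]] +
                    sqrt(1 - rho) * stats::rnorm(n))
    Y[, k] <- config$mu_y[k] + config$beta[k] * X +
      drop(Zimp %*% config$alpha[, k]) + config$kappa_y[k] * U +
      config$age_effect_y[k] * age_c + config$sex_effect_y[k] * sex + resid
  }
  conc <- exp(Y)
  if (config$outcome_missing_rate > 0) {
    conc[matrix(stats::runif(n * m) < config$outcome_missing_rate, n, m)] <- NA_real_
  }
  outcome_ids <- sprintf("M%03d", seq_len(m))
  colnames(conc) <- outcome_ids
  cohort <- data.frame(subject_id = rownames(G), bmi = exp(X),
                       age = age, sex = sex, stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(conc))
  rownames(cohort) <- NULL
  invalid <- config$snp_specs$snp_id[apply(config$alpha != 0, 1, any)]
  truth <- list(config = config, confounder = U, log_bmi = X,
                outcome_ids = outcome_ids,
                outcome_blocks = stats::setNames(blocks, outcome_ids),
                invalid_instruments = invalid)
  list(genotypes = G, cohort = cohort, truth = truth)
}

# Default instrument panel: a rare-to-common minor-allele-frequency spectrum.
.default_mafs <- c(0.02, 0.02, 0.03, 0.03, 0.04, 0.05, 0.05, 0.10, 0.10,
                   0.15, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.45, 0.50)

# Per-SNP effects gamma_j chosen so the 18 instruments jointly explain
# `r2` of the exposure variance, with per-SNP explained variance allocated
# inversely to heterozygosity 2q(1-q): rarer alleles carry larger per-allele
# effects, mirroring the usual inverse frequency-effect size relationship.
.default_gamma <- function(mafs, sd_x = 0.15, r2 = 0.05) {
  v <- 2 * mafs * (1 - mafs)
  K <- r2 * sd_x^2 / sum(1 / v)
  sqrt(K) / v
}

#' Preset simulation scenarios
#'
#' Named configurations covering the canonical instrument-validity regimes:
#' \describe{
#'   \item{valid}{all direct (pleiotropic) effects zero.}
#'   \item{balanced_pleiotropy}{every instrument pleiotropic with zero-mean
#'     effects drawn independently of instrument strength.}
#'   \item{directional_inside}{every instrument pleiotropic with positive-mean
#'     effects, still drawn independently of instrument strength (the InSIDE
#'     condition holds by construction).}
#'   \item{directional_violating_inside}{pleiotropic effects correlated with
#'     instrument strength (InSIDE violated).}
#'   \item{null_effect}{no causal effect (beta = 0), no pleiotropy.}
#' }
#' All presets share an 18-SNP panel with minor-allele frequencies spanning
#' 0.02-0.50 and per-SNP effects calibrated so each instrument is selectable
#' at p <= 1e-5 with 90\% power at the `power_n` reference size (see below),
#' a latent confounder explaining 9\% of the exposure and of each outcome,
#' sd(log BMI) = 0.15 and outcome residual sd 0.3; see the methods vignette
#' for the reasoning behind these defaults.
#'
#' @param name one of `valid`, `balanced_pleiotropy`, `directional_inside`,
#'   `directional_violating_inside`, `null_effect`.
#' @param n_subjects,n_outcomes cohort dimensions.
#' @param beta causal effect(s); default 0.3 (0 for `null_effect`).
#' @param seed seed stored in the config (also used here for the random
#'   pleiotropy draws of the non-valid presets).
#' @param block_cor within-block residual correlation of the three outcome
#'   blocks.
#' @param power_n reference cohort size at which the default per-SNP effects
#'   give each instrument 90\% power to pass the p <= 1e-5 selection filter
#'   (default 2000, the default cohort size). A cohort whose own association
#'   scan selected its instruments necessarily shows at least
#'   threshold-level apparent strength, so this is the regime in which the
#'   selection stage retains a full panel and the estimators operate as
#'   advertised.
#' @param instrument_r2 optional; when supplied the default effects are
#'   replaced by a deliberately weak panel jointly explaining this fraction
#'   of the exposure variance (per-SNP explained variance allocated
#'   inversely to heterozygosity), for studying weak-instrument behaviour.
#' @return a `sim_config`.
#' @export
mr_scenario <- function(name, n_subjects = 2000, n_outcomes = 30, beta = NULL,
                        seed = 1L, block_cor = 0.6, power_n = 2000,
                        instrument_r2 = NULL) {
  presets <- c("valid", "balanced_pleiotropy", "directional_inside",
               "directional_violating_inside", "null_effect")
  if (length(name) != 1L || !name %in% presets) {
    stop("unknown scenario; valid names: ", paste(presets, collapse = ", "))
  }
  specs <- snp_spec(sprintf("SNP%02d", seq_along(.default_mafs)), .default_mafs)
  p <- nrow(specs)
  gamma <- if (is.null(instrument_r2)) {
    v <- 2 * specs$maf * (1 - specs$maf)
    z_needed <- stats::qnorm(1 - 5e-6) + stats::qnorm(0.9)
    # self-consistent per-SNP explained variance c: the residual variance in
    # a single-SNP association scan includes the other p-1 instruments, so
    # c = z^2 (b0 + (p-1) c) / n with b0 the non-genetic exposure variance
    b0 <- 0.019293 + (0.3 * 0.15)^2 + (4e-4)^2 * 49^2 / 12 + 0.01^2 / 4
    denom <- power_n - (p - 1) * z_needed^2
    if (denom <= 0) {
      stop("power_n too small to calibrate ", p,
           " selectable instruments; supply instrument_r2 instead")
    }
    cc <- z_needed^2 * b0 / denom
    sqrt(cc / v)
  } else {
    .default_gamma(specs$maf, r2 = instrument_r2)
  }
  if (is.null(beta)) beta <- if (name == "null_effect") 0 else 0.3
  set.seed(seed)
  alpha <- matrix(0, p, n_outcomes)
  if (name == "balanced_pleiotropy") {
    alpha <- matrix(stats::rnorm(p * n_outcomes, 0, 0.02), p, n_outcomes)
  } else if (name == "directional_inside") {
    alpha <- matrix(stats::rnorm(p * n_outcomes, 0.05, 0.01), p, n_outcomes)
  } else if (name == "directional_violating_inside") {
    base <- 0.4 * gamma - mean(0.4 * gamma) + 0.05
    alpha <- base + matrix(stats::rnorm(p * n_outcomes, 0, 0.005), p, n_outcomes)
  }
  blocks <- rep(seq_len(3L), length.out = n_outcomes)
  sim_config(
    n_subjects = n_subjects, snp_specs = specs, gamma = gamma,
    beta = beta, n_outcomes = n_outcomes, alpha = alpha,
    kappa_x = 0.3 * 0.15, kappa_y = 0.3 * 0.3,
    age_effect_x = 4e-4, sex_effect_x = 0.01,
    age_effect_y = 1e-3, sex_effect_y = 0.02,
    outcome_blocks = sort(blocks), block_cor = block_cor,
    noise_sd_x = sqrt(0.15^2 * (1 - 0.05 - 0.09) - (4e-4 * sqrt(49^2 / 12))^2 -
                        0.01^2 / 4),
    noise_sd_y = sqrt(0.3^2 * (1 - 0.09)),
    mu_x = log(26.5), mu_y = 0, seed = seed
  )
}
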