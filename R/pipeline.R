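#' Build an analysis configuration
#'
#' Collects everything [run_analysis()] needs: input locations (paths, or
#' in-memory objects for programmatic use), QC thresholds, the MR methods to
#' run, bootstrap size, the number of outcome clusters, the significance
#' level and the master seed. All stage-specific random streams (bootstrap
#' resampling, cross-validation folds) are derived deterministically from
#' the single seed.
#'
#' @param genotypes path to a VCF/TSV genotype file, or a dosage matrix.
#' @param cohort path to a cohort TSV, or a cohort data.frame.
#' @param outcomes character vector of outcome column names; default every
#'   column after `subject_id`, `bmi`, `age`, `sex`.
#' @param thresholds instrument-selection thresholds ([qc_thresholds()]).
#' @param methods subset of `c("egger", "wme")`; IVW and per-SNP ratio
#'   estimates are always computed alongside Egger regression.
#' @param bootstrap_B bootstrap replicates for the weighted-median SE
#'   (>= 100).
#' @param run_sisvive whether to run the invalid-instrument count per
#'   outcome.
#' @param cluster_k number of outcome clusters to cut.
#' @param alpha two-sided significance level for the enrichment stage.
#' @param significance_method method whose p-values feed the enrichment
#'   stage (default the weighted median).
#' @param seed master integer seed.
#' @param output_dir directory for the result tables.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(genotypes, cohort, outcomes = NULL,
                            thresholds = qc_thresholds(),
                            methods = c("egger", "wme"),
                            bootstrap_B = 200L, run_sisvive = TRUE,
                            cluster_k = 3L, alpha = 0.05,
                            significance_method = "wme",
                            seed = 1L, output_dir = tempfile("mr_run_")) {
  methods <- match.arg(methods, c("egger", "wme"), several.ok = TRUE)
  if (bootstrap_B < 100L) stop("bootstrap_B must be at least 100")
  if (cluster_k < 1L) stop("cluster_k must be at least 1")
  stopifnot(significance_method %in% methods)
  structure(list(genotypes = genotypes, cohort = cohort, outcomes = outcomes,
                 thresholds = thresholds, methods = methods,
                 bootstrap_B = as.integer(bootstrap_B),
                 run_sisvive = isTRUE(run_sisvive),
                 cluster_k = as.integer(cluster_k), alpha = alpha,
                 significance_method = significance_method,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "analysis_config")
}

.write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full Mendelian-randomisation analysis
#'
#' Stages, in order: load inputs; log-transform exposure and outcomes;
#' orient/QC/select instruments against the exposure (once, reused for every
#' outcome); per outcome compute per-instrument summary statistics, IVW and
#' Egger estimates, the weighted median with bootstrap SE, and optionally
#' the invalid-instrument count; Ward-cluster the log outcomes; build the
#' signed-significance table; test cluster enrichment. Every stage writes a
#' tab-delimited table into the output directory, plus a JSON run manifest.
#' Aborts (after writing the QC audit trail) when fewer than 3 instruments
#' survive selection.
#'
#' @param config an `analysis_config`.
#' @return invisibly, a list with all in-memory results (`instruments`,
#'   `mr_results`, `summary_stats`, `invalid`, `clusters`, `significance`,
#'   `enrichment`, `output_dir`).
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "analysis_config")) {
    stop("config must be built by analysis_config()")
  }
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  G <- if (is.character(config$genotypes)) read_genotypes(config$genotypes)
       else config$genotypes
  cohort <- if (is.character(config$cohort)) read_cohort_tsv(config$cohort)
            else config$cohort
  outcomes <- config$outcomes
  if (is.null(outcomes)) {
    outcomes <- setdiff(names(cohort), c("subject_id", "bmi", "age", "sex"))
  }
  missing_cols <- setdiff(outcomes, names(cohort))
  if (length(missing_cols)) {
    stop("outcome column(s) not in cohort: ", paste(missing_cols, collapse = ", "))
  }

  inst <- select_instruments(G, cohort, config$thresholds)
  .write_tsv(inst$exclusions, config$output_dir, "qc_exclusions.tsv")
  .write_tsv(inst$qc, config$output_dir, "qc_snps.tsv")
  if (inst$n_unphenotyped > 0) {
    note(sprintf("%d genotyped subject(s) without phenotypes dropped",
                 inst$n_unphenotyped))
  }
  if (length(inst$snp_ids) < 3L) {
    stop("fewer than 3 instruments survive selection (",
         length(inst$snp_ids), "); audit trail written to ",
         config$output_dir)
  }
  .write_tsv(data.frame(snp_id = inst$snp_ids,
                        inst$exposure_stats[match(inst$snp_ids,
                                                  inst$exposure_stats$snp_id),
                                            c("beta", "se", "p", "n_used")],
                        row.names = NULL),
             config$output_dir, "instruments.tsv")

  ph <- cohort[match(inst$subjects, cohort$subject_id), ]
  Gk <- inst$genotypes
  x <- log(ph$bmi)
  exposure_stats <- snp_summary_stats(Gk, x, ph$age, ph$sex,
                                      trait_id = "log_bmi")

  per_outcome <- list()
  sumstats <- list()
  invalid_rows <- list()
  for (i in seq_along(outcomes)) {
    m <- outcomes[i]
    y <- suppressWarnings(log(ph[[m]]))
    oy <- snp_summary_stats(Gk, y, ph$age, ph$sex, trait_id = m)
    sumstats[[m]] <- data.frame(outcome_id = m,
                                snp_id = oy$snp_id,
                                beta_exposure = exposure_stats$beta,
                                se_exposure = exposure_stats$se,
                                beta_outcome = oy$beta,
                                se_outcome = oy$se,
                                stringsAsFactors = FALSE)
    rows <- list()
    ivw <- ivw_estimate(exposure_stats, oy)
    rows$ivw <- as.data.frame(ivw)
    if ("egger" %in% config$methods) {
      rows$egger <- as.data.frame(egger_estimate(exposure_stats, oy))
    }
    if ("wme" %in% config$methods) {
      wme <- suppressWarnings(
        bootstrap_wme(Gk, cohort, inst, m, B = config$bootstrap_B,
                      seed = config$seed + i))
      rows$wme <- as.data.frame(wme)
    }
    res <- do.call(rbind, rows)
    res <- cbind(outcome_id = m, res)
    per_outcome[[m]] <- res
    if (config$run_sisvive) {
      rep <- count_invalid_sisvive(Gk, cohort, inst, m,
                                   seed = config$seed + 100000L + i)
      invalid_rows[[m]] <- data.frame(
        outcome_id = m, n_invalid = rep$n_invalid,
        invalid_snp_ids = paste(rep$invalid_snp_ids, collapse = ","),
        lambda = rep$lambda_selected,
        weight_fraction_invalid = rep$weight_fraction_invalid,
        stringsAsFactors = FALSE)
    }
  }
  mr_results <- do.call(rbind, per_outcome)
  rownames(mr_results) <- NULL
  .write_tsv(mr_results, config$output_dir, "mr_results.tsv")
  sumstats <- do.call(rbind, sumstats)
  rownames(sumstats) <- NULL
  .write_tsv(sumstats, config$output_dir, "summary_stats.tsv")
  jsonlite::write_json(mr_results,
                       file.path(config$output_dir, "mr_results.json"),
                       digits = NA, dataframe = "rows")
  invalid <- NULL
  if (config$run_sisvive) {
    invalid <- do.call(rbind, invalid_rows)
    rownames(invalid) <- NULL
    .write_tsv(invalid, config$output_dir, "invalid_instruments.tsv")
  }

  # outcome clustering on log concentrations
  logY <- as.matrix(log(ph[, outcomes, drop = FALSE]))
  clusters <- NULL
  if (length(outcomes) >= 2L && config$cluster_k <= length(outcomes)) {
    D <- correlation_distance(logY)
    clusters <- ward_cluster(D, config$cluster_k)
    .write_tsv(data.frame(outcome_id = names(clusters$labels),
                          cluster = unname(clusters$labels)),
               config$output_dir, "clusters.tsv")
    .write_tsv(data.frame(merge1 = clusters$tree$merge[, 1],
                          merge2 = clusters$tree$merge[, 2],
                          height = clusters$tree$height),
               config$output_dir, "linkage.tsv")
    writeLines(names(clusters$labels)[clusters$order],
               file.path(config$output_dir, "leaf_order.txt"))
  }

  sig_rows <- mr_results[mr_results$method == config$significance_method, ]
  significance <- signed_significance(
    data.frame(outcome_id = sig_rows$outcome_id, estimate = sig_rows$estimate,
               p = sig_rows$p, stringsAsFactors = FALSE),
    alpha = config$alpha)
  enrichment <- NULL
  if (!is.null(clusters)) {
    sig_out <- merge(significance,
                     data.frame(outcome_id = names(clusters$labels),
                                cluster = unname(clusters$labels)),
                     by = "outcome_id")
    sig_out <- sig_out[order(sig_out$cluster, sig_out$outcome_id), ]
    .write_tsv(sig_out, config$output_dir, "signed_scores.tsv")
    enrichment <- cluster_enrichment(significance, clusters)
    .write_tsv(enrichment, config$output_dir, "enrichment.tsv")
  } else {
    .write_tsv(significance, config$output_dir, "signed_scores.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mrmetab")),
    seed = config$seed,
    methods = config$methods,
    bootstrap_B = config$bootstrap_B,
    cluster_k = config$cluster_k,
    alpha = config$alpha,
    thresholds = config$thresholds,
    n_subjects_analysed = length(inst$subjects),
    n_instruments = length(inst$snp_ids),
    n_outcomes = length(outcomes),
    warnings = warnings_log,
    elapsed_seconds = proc.time()[["elapsed"]] - t0
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(instruments = inst, exposure_stats = exposure_stats,
                 mr_results = mr_results, summary_stats = sumstats,
                 invalid = invalid, clusters = clusters,
                 significance = significance, enrichment = enrichment,
                 output_dir = config$output_dir))
}

#' Simulate a cohort and write it to disk
#'
#' Runs [simulate_cohort()] and writes the genotype matrix (as both a
#' minimal VCF and a dosage TSV), the cohort table, and a ground-truth JSON
#' (simulation parameters, invalid-instrument set, block labels) into a
#' directory. The files round-trip directly into [run_analysis()].
#'
#' @param config a `sim_config` (e.g. from [mr_scenario()] or
#'   [read_sim_config()]).
#' @param dir output directory, created if needed.
#' @return invisibly, the list of file paths written.
#' @export
write_simulation <- function(config, dir) {
  sim <- simulate_cohort(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    dosage = file.path(dir, "genotypes.tsv"),
    cohort = file.path(dir, "cohort.tsv"),
    truth = file.path(dir, "truth.json"))
  write_genotypes_vcf(sim$genotypes, paths$vcf)
  write_dosage_tsv(sim$genotypes, paths$dosage)
  write_cohort_tsv(sim$cohort, paths$cohort)
  truth <- list(
    seed = config$seed,
    snp_ids = config$snp_specs$snp_id,
    mafs = config$snp_specs$maf,
    gamma = config$gamma,
    beta = config$beta,
    invalid_instruments = sim$truth$invalid_instruments,
    outcome_blocks = as.list(sim$truth$outcome_blocks))
  jsonlite::write_json(truth, paths$truth, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
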