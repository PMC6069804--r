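#' Write a dosage matrix as a minimal VCF
#'
#' One biallelic record per SNP (chromosome 1, consecutive positions,
#' REF=A/ALT=B placeholders), GT-only FORMAT, unphased genotypes: dosage 0
#' -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, missing -> `./.`. The ALT allele is the
#' counted (minor) allele.
#'
#' @param genotypes subjects x SNPs dosage matrix.
#' @param path output file.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  .check_genotypes(genotypes)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t"))
  rows <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    calls <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c("1", j, colnames(genotypes)[j], "A", "B", ".", ".", ".", "GT",
            calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a dosage matrix as tab-delimited text
#'
#' Rows are subjects (first column `subject_id`), columns are SNPs, missing
#' calls are written as `NA`.
#'
#' @inheritParams write_genotypes_vcf
#' @export
write_dosage_tsv <- function(genotypes, path) {
  .check_genotypes(genotypes)
  df <- data.frame(subject_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype dosages from VCF or TSV
#'
#' VCF files (recognised by a `.vcf` / `.vcf.gz` extension) are parsed with
#' vcfR; GT fields are converted to minor-allele dosage counts of the ALT
#' allele, with multi-allelic records skipped with a warning. Any other
#' extension is read as a tab-delimited dosage matrix written by
#' [write_dosage_tsv()].
#'
#' @param path input file.
#' @return subjects x SNPs dosage matrix.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    multi <- grepl(",", vcfR::getALT(v), fixed = TRUE)
    if (any(multi)) {
      warning(sum(multi), " multi-allelic record(s) skipped")
      v <- v[!multi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(x) {
      ifelse(is.na(x) | x %in% c("./.", ".|.", "."), NA_real_,
             vapply(strsplit(gsub("\\|", "/", x), "/", fixed = FALSE),
                    function(al) sum(al == "1"), numeric(1)))
    }
    D <- matrix(count_alt(as.vector(gt)), nrow = nrow(gt),
                dimnames = dimnames(gt))
    t(D)  # subjects x SNPs
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    G <- as.matrix(df[, -1, drop = FALSE])
    rownames(G) <- df[[1]]
    storage.mode(G) <- "double"
    G
  }
}

#' Write / read the cohort phenotype-and-outcome table
#'
#' Tab-delimited with header `subject_id`, `bmi`, `age`, `sex`, then one
#' column per metabolite concentration. BMI and concentrations are on the
#' natural scale; the analysis takes logs.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("subject_id", "bmi", "age", "sex")
  if (!all(req %in% names(df))) {
    stop("cohort table must have columns ", paste(req, collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Read a simulation config from a YAML/JSON key-value file
#'
#' Recognised keys mirror the arguments of [sim_config()] /
#' [mr_scenario()]: either `scenario: <name>` plus overrides
#' (`n_subjects`, `n_outcomes`, `beta`, `block_cor`), or the full set of
#' [sim_config()] fields (`snp_ids`, `mafs`, `missing_rates`, `gamma`, ...).
#' `seed` is mandatory.
#'
#' @param path YAML (or JSON, a YAML subset) file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  if (!is.null(cfg$scenario)) {
    args <- cfg[intersect(names(cfg),
                          c("n_subjects", "n_outcomes", "beta", "block_cor"))]
    return(do.call(mr_scenario,
                   c(list(name = cfg$scenario, seed = cfg$seed), args)))
  }
  specs <- snp_spec(cfg$snp_ids, cfg$mafs,
                    if (is.null(cfg$missing_rates)) 0 else cfg$missing_rates)
  keep <- setdiff(names(cfg), c("snp_ids", "mafs", "missing_rates", "scenario"))
  args <- cfg[keep]
  args$snp_specs <- specs
  if (!is.null(args$alpha)) args$alpha <- do.call(rbind, args$alpha)
  do.call(sim_config, args)
}

#' Read two-sample-style per-instrument summary statistics
#'
#' Tab-delimited with columns `snp_id`, `beta_exposure`, `se_exposure`,
#' `beta_outcome`, `se_outcome`; returns the pair of data.frames the
#' summary-level estimators ([ivw_estimate()], [egger_estimate()],
#' [ratio_estimates()]) accept, so published association results can be
#' analysed without individual-level data (the bootstrap and
#' invalid-instrument paths still need the cohort itself).
#'
#' @param path input file.
#' @return list with data.frames `exposure` and `outcome` (columns
#'   `snp_id`, `beta`, `se`).
#' @export
read_summary_stats_tsv <- function(path) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("snp_id", "beta_exposure", "se_exposure", "beta_outcome",
           "se_outcome")
  if (!all(req %in% names(df))) {
    stop("summary-statistics table must have columns ",
         paste(req, collapse = ", "))
  }
  list(exposure = data.frame(snp_id = as.character(df$snp_id),
                             beta = df$beta_exposure, se = df$se_exposure,
                             stringsAsFactors = FALSE),
       outcome = data.frame(snp_id = as.character(df$snp_id),
                            beta = df$beta_outcome, se = df$se_outcome,
                            stringsAsFactors = FALSE))
}
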