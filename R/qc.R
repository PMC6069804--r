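#' Orient dosage columns to count the minor allele
#'
#' Recode any SNP whose counted allele has frequency above 0.5 as
#' `dosage -> 2 - dosage`, so dosage 2 is always the rarer homozygote.
#' Columns with allele frequency exactly 0.5 are left as-is.
#'
#' @param genotypes subjects x SNPs dosage matrix (entries 0/1/2/`NA`).
#' @return the recoded matrix, with attribute `recoded` listing the SNP ids
#'   that were flipped.
#' @export
orient_to_minor_allele <- function(genotypes) {
  .check_genotypes(genotypes)
  freq <- apply(genotypes, 2, function(d) {
    d <- d[!is.na(d)]
    if (!length(d)) return(NA_real_)
    sum(d) / (2 * length(d))
  })
  flip <- which(!is.na(freq) & freq > 0.5)
  if (length(flip)) genotypes[, flip] <- 2 - genotypes[, flip]
  attr(genotypes, "recoded") <- colnames(genotypes)[flip]
  genotypes
}

.check_genotypes <- function(G) {
  if (!is.matrix(G) || !is.numeric(G)) {
    stop("genotypes must be a numeric matrix (subjects x SNPs)")
  }
  if (nrow(G) < 1L || ncol(G) < 1L) stop("genotype matrix is empty")
  vals <- G[!is.na(G)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("non-missing dosages must be 0, 1 or 2")
  }
  invisible(G)
}

#' Per-SNP and per-subject call rates
#'
#' @param genotypes dosage matrix.
#' @return list with numeric vectors `snp` (non-missing fraction per SNP) and
#'   `subject` (non-missing fraction per subject), both named.
#' @export
call_rates <- function(genotypes) {
  .check_genotypes(genotypes)
  ok <- !is.na(genotypes)
  list(snp = colMeans(ok), subject = rowMeans(ok))
}

#' Minor allele frequency of a dosage column
#'
#' Computed on non-missing calls as
#' (n_het + 2 n_hom_minor) / (2 n_called), assuming the column is already
#' oriented so that dosage counts the minor allele.
#'
#' @param dosage numeric vector of 0/1/2/`NA`.
#' @return the allele frequency, or `NA` when the column has no calls.
#' @export
minor_allele_frequency <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  if (!length(d)) return(NA_real_)
  sum(d) / (2 * length(d))
}

#' Signed Hardy-Weinberg equilibrium statistic
#'
#' The signed square root of the 1-df chi-square goodness-of-fit statistic
#' comparing observed genotype counts with the counts expected under HWE at
#' the estimated allele frequency. The sign is positive for heterozygote
#' excess, negative for heterozygote deficit. Monomorphic columns return 0
#' (they are screened out by the MAF filter instead).
#'
#' @param dosage numeric vector of 0/1/2/`NA`; needs at least 2 calls.
#' @return signed z-like statistic.
#' @export
hwe_statistic <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  if (length(d) < 2L) stop("hwe_statistic needs at least 2 genotype calls")
  n <- length(d)
  obs <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  q <- (obs[2] + 2 * obs[3]) / (2 * n)
  if (q == 0 || q == 1) return(0)
  expd <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((obs - expd)^2 / expd)
  sign_het <- if (obs[2] >= expd[2]) 1 else -1
  sign_het * sqrt(chi2)
}

#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' Composite LD: the squared Pearson correlation of the two dosage columns
#' over pairwise-complete subjects.
#'
#' @param a,b dosage vectors of equal length.
#' @return r^2 in \[0, 1\], or `NA` (with a warning) when either column has
#'   zero variance on the shared subjects.
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("dosage columns differ in length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("ld_r2 needs at least 3 paired non-missing entries")
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero dosage variance; LD undefined, pair treated as not in LD")
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Age- and sex-adjusted association of a trait with one SNP
#'
#' Ordinary least squares of the trait on (intercept, dosage, age, sex) over
#' complete cases; reports the dosage coefficient with its standard error and
#' two-sided Wald p-value (normal reference). When the fit is exact
#' (zero residual variance) the standard error is 0 and the result is
#' flagged `exact_fit`.
#'
#' @param trait numeric response (already on the analysis scale, e.g. log BMI
#'   or log concentration).
#' @param dosage SNP dosages 0/1/2/`NA`.
#' @param age,sex covariates.
#' @param snp_id,trait_id identifiers copied into the result.
#' @return one-row data.frame: `snp_id`, `trait_id`, `beta`, `se`, `p`,
#'   `n_used`, `exact_fit`.
#' @export
adjusted_regression <- function(trait, dosage, age, sex,
                                snp_id = NA_character_,
                                trait_id = NA_character_) {
  ok <- stats::complete.cases(trait, dosage, age, sex)
  n <- sum(ok)
  if (n < 5L) stop("adjusted_regression needs at least 5 complete cases")
  X <- cbind(`(Intercept)` = 1, dosage = dosage[ok], age = age[ok], sex = sex[ok])
  y <- trait[ok]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  df <- n - ncol(X)
  scale2 <- mean(y^2) + 1
  exact <- rss < 1e-12 * n * scale2
  sigma2 <- if (exact) 0 else rss / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  beta <- unname(coefs["dosage"])
  p <- if (se == 0) {
    if (beta == 0) 1 else .Machine$double.xmin
  } else {
    2 * stats::pnorm(-abs(beta / se))
  }
  data.frame(snp_id = snp_id, trait_id = trait_id, beta = beta, se = se,
             p = p, n_used = n, exact_fit = exact, stringsAsFactors = FALSE)
}

#' Adjusted association of one trait with every SNP in a matrix
#'
#' Vectorised equivalent of calling [adjusted_regression()] per SNP.
#' Subjects with missing trait/age/sex are dropped globally; SNP columns
#' with missing dosages are handled complete-case within their own
#' regression (Frisch-Waugh-Lovell residualisation is used for the fully
#' observed columns, which is algebraically identical to the per-SNP OLS).
#'
#' @inheritParams adjusted_regression
#' @param genotypes dosage matrix restricted to the SNPs of interest.
#' @return data.frame with one row per SNP: `snp_id`, `trait_id`, `beta`,
#'   `se`, `p`, `n_used`.
#' @export
snp_summary_stats <- function(genotypes, trait, age, sex,
                              trait_id = NA_character_) {
  .check_genotypes(genotypes)
  ok <- stats::complete.cases(trait, age, sex)
  G <- genotypes[ok, , drop = FALSE]
  y <- trait[ok]; a <- age[ok]; s <- sex[ok]
  n <- length(y)
  out <- data.frame(snp_id = colnames(G), trait_id = trait_id,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    n_used = NA_integer_, stringsAsFactors = FALSE)
  has_na <- colSums(is.na(G)) > 0L
  if (any(!has_na)) {
    C <- cbind(1, a, s)
    qc <- qr(C)
    Zr <- qr.resid(qc, G[, !has_na, drop = FALSE])
    yr <- qr.resid(qc, y)
    sz2 <- colSums(Zr^2)
    b <- colSums(Zr * yr) / sz2
    rss <- sum(yr^2) - b^2 * sz2
    rss[rss < 0] <- 0
    sigma2 <- rss / (n - 4L)
    se <- sqrt(sigma2 / sz2)
    z <- b / se
    out$beta[!has_na] <- b
    out$se[!has_na] <- se
    out$p[!has_na] <- 2 * stats::pnorm(-abs(z))
    out$n_used[!has_na] <- n
  }
  for (j in which(has_na)) {
    fit <- adjusted_regression(y, G[, j], a, s, snp_id = colnames(G)[j],
                               trait_id = trait_id)
    out[j, c("beta", "se", "p", "n_used")] <-
      fit[, c("beta", "se", "p", "n_used")]
  }
  out
}

#' Default instrument-selection thresholds
#'
#' Call rate at least 0.95 (per SNP and per subject), minor allele frequency
#' above 0.01, |HWE statistic| below 4, exposure-association p at most 1e-5,
#' pairwise LD r^2 at most 0.05.
#'
#' @param call_rate,maf,hwe,p,ld_r2 individual thresholds.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(call_rate = 0.95, maf = 0.01, hwe = 4,
                          p = 1e-5, ld_r2 = 0.05) {
  list(call_rate = call_rate, maf = maf, hwe = hwe, p = p, ld_r2 = ld_r2)
}

#' Select instrumental SNPs for the exposure
#'
#' Applies the QC and association filters in a fixed, audited order:
#' drop SNPs with call rate below threshold; drop subjects with call rate
#' (over the surviving SNPs) below threshold; orient dosages to the minor
#' allele; drop SNPs with MAF <= threshold, then
#' |HWE statistic| >= threshold; regress log BMI (age- and sex-adjusted) on
#' each surviving SNP and keep those with p <= threshold; finally greedy LD
#' pruning — survivors are sorted by ascending association p (ties broken by
#' SNP id) and a SNP is kept only if its r^2 with every already-kept SNP is
#' at most the threshold. Pairs with undefined LD (zero variance) are
#' treated as not in LD.
#'
#' @param genotypes dosage matrix; oriented internally.
#' @param cohort data.frame with `subject_id`, `bmi` (natural scale), `age`,
#'   `sex`; the exposure analysed is `log(bmi)`.
#' @param thresholds list from [qc_thresholds()].
#' @return an object of class `instrument_set`: list with `snp_ids` (kept),
#'   `qc` (per-SNP call rate / MAF / HWE for all SNPs considered),
#'   `exposure_stats` (per kept SNP), `exclusions` (data.frame snp_id,
#'   filter, value), `subjects` (ids used), `subjects_dropped`, `recoded`,
#'   `thresholds`.
#' @export
select_instruments <- function(genotypes, cohort, thresholds = qc_thresholds()) {
  .check_genotypes(genotypes)
  stopifnot(is.data.frame(cohort),
            all(c("subject_id", "bmi", "age", "sex") %in% names(cohort)))
  common <- intersect(rownames(genotypes), cohort$subject_id)
  if (!length(common)) stop("no subjects shared between genotypes and cohort")
  n_unphenotyped <- nrow(genotypes) - length(common)
  G <- genotypes[common, , drop = FALSE]
  ph <- cohort[match(common, cohort$subject_id), ]

  excl <- data.frame(snp_id = character(), filter = character(),
                     value = numeric(), stringsAsFactors = FALSE)
  drop_snps <- function(ids, filter, values) {
    if (!length(ids)) return(excl)
    rbind(excl, data.frame(snp_id = ids, filter = filter,
                           value = unname(values), stringsAsFactors = FALSE))
  }

  # SNP call-rate filter first (computed over all shared subjects), then the
  # subject call-rate filter over the surviving SNPs
  snp_cr_all <- call_rates(G)$snp
  cr_fail <- names(snp_cr_all)[snp_cr_all < thresholds$call_rate]
  excl <- drop_snps(cr_fail, "call_rate", snp_cr_all[cr_fail])
  G <- G[, setdiff(colnames(G), cr_fail), drop = FALSE]
  if (!ncol(G)) stop("no SNPs survive the call-rate filter")

  subj_cr <- call_rates(G)$subject
  keep_subj <- subj_cr >= thresholds$call_rate
  subjects_dropped <- rownames(G)[!keep_subj]
  G <- G[keep_subj, , drop = FALSE]
  ph <- ph[keep_subj, , drop = FALSE]
  if (nrow(G) < 5L) stop("fewer than 5 subjects survive the call-rate filter")

  G <- orient_to_minor_allele(G)
  recoded <- attr(G, "recoded")

  snp_cr <- call_rates(G)$snp
  maf <- apply(G, 2, minor_allele_frequency)
  hwe <- vapply(colnames(G), function(j) {
    d <- G[, j]
    if (sum(!is.na(d)) < 2L) return(NA_real_)
    hwe_statistic(d)
  }, numeric(1))
  qc_tab <- data.frame(snp_id = colnames(G), call_rate = snp_cr, maf = maf,
                       hwe = hwe, row.names = NULL, stringsAsFactors = FALSE)

  alive <- colnames(G)
  no_calls <- alive[is.na(maf[alive])]
  excl <- drop_snps(no_calls, "no calls", NA_real_)
  alive <- setdiff(alive, no_calls)

  bad <- alive[maf[alive] <= thresholds$maf]
  excl <- drop_snps(bad, "maf", maf[bad])
  alive <- setdiff(alive, bad)

  bad <- alive[!is.na(hwe[alive]) & abs(hwe[alive]) >= thresholds$hwe]
  excl <- drop_snps(bad, "hwe", hwe[bad])
  alive <- setdiff(alive, bad)

  stats_tab <- NULL
  if (length(alive)) {
    stats_tab <- snp_summary_stats(G[, alive, drop = FALSE], log(ph$bmi),
                                   ph$age, ph$sex, trait_id = "log_bmi")
    pvals <- stats::setNames(stats_tab$p, stats_tab$snp_id)
    bad <- alive[!(pvals[alive] <= thresholds$p)]
    excl <- drop_snps(bad, "association_p", pvals[bad])
    alive <- setdiff(alive, bad)
  }

  if (length(alive) > 1L) {
    ord <- alive[order(pvals[alive], alive)]
    kept <- character()
    for (s in ord) {
      r2 <- vapply(kept, function(k) {
        suppressWarnings(ld_r2(G[, s], G[, k]))
      }, numeric(1))
      if (any(!is.na(r2) & r2 > thresholds$ld_r2)) {
        worst <- max(r2, na.rm = TRUE)
        excl <- drop_snps(s, "ld_prune", worst)
      } else {
        kept <- c(kept, s)
      }
    }
    alive <- ord[ord %in% kept]
  }

  if (!length(alive)) {
    warning("no SNPs survive instrument selection")
  }
  res <- list(
    snp_ids = alive,
    qc = qc_tab,
    exposure_stats = if (is.null(stats_tab)) NULL else
      stats_tab[stats_tab$snp_id %in% alive, , drop = FALSE],
    exclusions = excl,
    subjects = rownames(G),
    subjects_dropped = subjects_dropped,
    n_unphenotyped = n_unphenotyped,
    recoded = recoded,
    thresholds = thresholds,
    genotypes = G[, alive, drop = FALSE]
  )
  class(res) <- "instrument_set"
  res
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set:", length(x$snp_ids), "SNPs retained,",
      nrow(x$exclusions), "excluded,",
      length(x$subjects), "subjects\n")
  invisible(x)
}
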