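#' @keywords internal
.mr_result <- function(method, estimate, se, p, n_instruments,
                       egger_intercept = NULL, egger_intercept_se = NULL,
                       egger_intercept_p = NULL, bootstrap_B = NULL,
                       extra = list()) {
  res <- c(list(method = method, estimate = estimate, se = se, p = p,
                n_instruments = n_instruments), extra)
  if (identical(method, "egger")) {
    res$egger_intercept <- egger_intercept
    res$egger_intercept_se <- egger_intercept_se
    res$egger_intercept_p <- egger_intercept_p
  }
  if (identical(method, "wme") && !is.null(bootstrap_B)) {
    res$bootstrap_B <- bootstrap_B
  }
  class(res) <- "mr_result"
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR %s estimate: %.4g (se %.4g, p %.3g) from %d instruments\n",
              x$method, x$estimate, x$se, x$p, x$n_instruments))
  if (identical(x$method, "egger")) {
    cat(sprintf("  intercept: %.4g (se %.4g, p %.3g)\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(
    method = x$method, estimate = x$estimate, se = x$se, p = x$p,
    n_instruments = x$n_instruments,
    egger_intercept = if (identical(x$method, "egger")) x$egger_intercept else NA_real_,
    egger_intercept_se = if (identical(x$method, "egger")) x$egger_intercept_se else NA_real_,
    egger_intercept_p = if (identical(x$method, "egger")) x$egger_intercept_p else NA_real_,
    stringsAsFactors = FALSE)
}

.align_stats <- function(exposure_stats, outcome_stats) {
  ex <- exposure_stats; oy <- outcome_stats
  stopifnot(all(c("snp_id", "beta", "se") %in% names(ex)),
            all(c("snp_id", "beta", "se") %in% names(oy)))
  if (!setequal(ex$snp_id, oy$snp_id)) {
    d1 <- setdiff(ex$snp_id, oy$snp_id)
    d2 <- setdiff(oy$snp_id, ex$snp_id)
    stop("instrument ids differ between exposure and outcome statistics: ",
         paste(c(d1, d2), collapse = ", "))
  }
  oy <- oy[match(ex$snp_id, oy$snp_id), ]
  list(snp_id = ex$snp_id, bx = ex$beta, sx = ex$se, by = oy$beta, sy = oy$se)
}

#' Per-instrument ratio estimates of the causal effect
#'
#' For instrument j the ratio estimate is beta_Yj / beta_Xj; its first-order
#' inverse-variance weight is beta_Xj^2 / se(beta_Yj)^2. Instruments with
#' beta_Xj exactly 0 have no defined ratio and are dropped with a warning.
#'
#' @param exposure_stats,outcome_stats data.frames with columns `snp_id`,
#'   `beta`, `se` (one row per instrument, matching ids).
#' @return data.frame `snp_id`, `ratio`, `weight`.
#' @export
ratio_estimates <- function(exposure_stats, outcome_stats) {
  s <- .align_stats(exposure_stats, outcome_stats)
  if (length(s$snp_id) < 1L) stop("at least one instrument is required")
  zero <- s$bx == 0
  if (any(zero)) {
    warning("dropping instrument(s) with zero exposure association: ",
            paste(s$snp_id[zero], collapse = ", "))
  }
  data.frame(snp_id = s$snp_id[!zero],
             ratio = s$by[!zero] / s$bx[!zero],
             weight = s$bx[!zero]^2 / s$sy[!zero]^2,
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted causal-effect estimate
#'
#' Weighted least squares of the per-instrument outcome associations on the
#' exposure associations through the origin, with weights 1/se(beta_Yj)^2.
#' Algebraically identical to the weight-weighted mean of the ratio
#' estimates, and to Egger regression with the intercept constrained to
#' zero. The standard error uses a multiplicative random-effects residual
#' variance floored at 1 (no under-dispersion); p is two-sided normal.
#'
#' @inheritParams ratio_estimates
#' @return an `mr_result` with method `"ivw"`.
#' @export
ivw_estimate <- function(exposure_stats, outcome_stats) {
  s <- .align_stats(exposure_stats, outcome_stats)
  J <- length(s$snp_id)
  if (J < 2L) stop("IVW needs at least 2 instruments")
  w <- 1 / s$sy^2
  swx2 <- sum(w * s$bx^2)
  b <- sum(w * s$bx * s$by) / swx2
  resid <- s$by - b * s$bx
  phi <- max(1, sum(w * resid^2) / (J - 1))
  se <- sqrt(phi / swx2)
  p <- 2 * stats::pnorm(-abs(b / se))
  .mr_result("ivw", b, se, p, J)
}

#' Egger regression causal-effect and mean-pleiotropy estimates
#'
#' Each instrument is first oriented so that its exposure association is
#' non-negative (both associations are negated together, which leaves the
#' ratio unchanged); then the outcome associations are regressed on the
#' exposure associations by weighted least squares with an intercept and
#' weights 1/se(beta_Yj)^2. The slope estimates the causal effect; the
#' intercept estimates the average directional pleiotropic effect, and its
#' test is the standard check for directional pleiotropy. Standard errors
#' use a residual variance floored at 1.
#'
#' @inheritParams ratio_estimates
#' @param reference `"t"` (default, J-2 df) or `"normal"` reference for the
#'   two-sided p-values.
#' @return an `mr_result` with method `"egger"` and an intercept block.
#' @export
egger_estimate <- function(exposure_stats, outcome_stats,
                           reference = c("t", "normal")) {
  reference <- match.arg(reference)
  s <- .align_stats(exposure_stats, outcome_stats)
  J <- length(s$snp_id)
  if (J < 3L) stop("Egger regression needs at least 3 instruments")
  flip <- ifelse(s$bx < 0, -1, 1)
  bx <- s$bx * flip
  by <- s$by * flip
  w <- 1 / s$sy^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * by)
  coefs <- solve(XtWX, XtWy)
  resid <- by - drop(X %*% coefs)
  phi <- max(1, sum(w * resid^2) / (J - 2))
  covb <- phi * solve(XtWX)
  est <- unname(coefs[2, 1]); se <- unname(sqrt(covb[2, 2]))
  a <- unname(coefs[1, 1]); a_se <- unname(sqrt(covb[1, 1]))
  pfun <- if (reference == "t") {
    function(z) 2 * stats::pt(-abs(z), df = J - 2)
  } else {
    function(z) 2 * stats::pnorm(-abs(z))
  }
  .mr_result("egger", est, se, pfun(est / se), J,
             egger_intercept = a, egger_intercept_se = a_se,
             egger_intercept_p = pfun(a / a_se),
             extra = list(reference = reference))
}

#' Weighted median of per-instrument ratio estimates
#'
#' Sort the ratio estimates; with normalised cumulative weights
#' p_j = (S_j - w_j/2) / S_total (S_j the running weight sum), the estimate
#' is the linear interpolation of the sorted ratios at p = 0.5. Consistent
#' when instruments carrying at least half of the total weight are valid.
#'
#' @param ratios data.frame from [ratio_estimates()] (columns `ratio`,
#'   `weight`), or a numeric vector of ratios.
#' @param weights weights when `ratios` is a plain vector.
#' @return the weighted-median point estimate.
#' @export
weighted_median_estimate <- function(ratios, weights = NULL) {
  if (is.data.frame(ratios)) {
    r <- ratios$ratio; w <- ratios$weight
  } else {
    r <- as.numeric(ratios); w <- weights
  }
  if (length(r) < 3L) stop("weighted median needs at least 3 instruments")
  if (is.null(w) || length(w) != length(r) || any(w < 0)) {
    stop("weights must be non-negative and match the ratios")
  }
  if (sum(w) == 0) stop("all weights are zero")
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  pj <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= pj[1]) return(r[1])
  if (0.5 >= pj[length(pj)]) return(r[length(r)])
  stats::approx(pj, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate with an individual-level bootstrap
#'
#' The point estimate is the weighted median computed from the original
#' data (age- and sex-adjusted per-instrument regressions of log BMI and of
#' the log outcome concentration on each instrument). Its standard error is
#' the standard deviation of the estimate over B bootstrap replicates in
#' which subjects are resampled with replacement and all per-instrument
#' regressions and the weighted median are recomputed. Replicates in which
#' some instrument has zero dosage variance are redrawn (up to 10 times,
#' then skipped and counted). The p-value is two-sided normal on
#' estimate/se.
#'
#' @param genotypes dosage matrix (subjects x SNPs).
#' @param cohort cohort data.frame (`subject_id`, `bmi`, `age`, `sex`,
#'   outcome columns; natural scale, logs are taken here).
#' @param instrument_set an `instrument_set` from [select_instruments()], or
#'   a character vector of instrument SNP ids.
#' @param outcome_id name of the outcome column in `cohort`.
#' @param B number of bootstrap replicates (>= 100; a warning is issued
#'   below 1000).
#' @param seed integer seed making the procedure deterministic.
#' @return an `mr_result` with method `"wme"`, `bootstrap_B`, and the number
#'   of skipped replicates in `$skipped`.
#' @export
bootstrap_wme <- function(genotypes, cohort, instrument_set, outcome_id,
                          B = 1000, seed = 1L) {
  snps <- if (inherits(instrument_set, "instrument_set")) {
    instrument_set$snp_ids
  } else {
    as.character(instrument_set)
  }
  if (B < 100) stop("B must be at least 100")
  if (B < 1000) warning("B < 1000 bootstrap replicates; SE may be unstable")
  common <- intersect(rownames(genotypes), cohort$subject_id)
  G <- genotypes[common, snps, drop = FALSE]
  ph <- cohort[match(common, cohort$subject_id), ]
  x <- log(ph$bmi)
  y <- log(ph[[outcome_id]])
  age <- ph$age; sex <- ph$sex
  point <- .wme_from_individual(G, x, y, age, sex)

  set.seed(seed)
  n <- nrow(G)
  p <- ncol(G)
  ests <- rep(NA_real_, B)
  skipped <- 0L
  fast <- !anyNA(G) && !anyNA(x) && !anyNA(y) && !anyNA(age) && !anyNA(sex)
  if (fast) A <- cbind(1, age, sex, x, y, G)
  ks <- 5L + seq_len(p)
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try in seq_len(10L)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (fast) {
        S <- crossprod(A[idx, , drop = FALSE])
        vars <- diag(S)[ks] - S[1, ks]^2 / n
      } else {
        Gi <- G[idx, , drop = FALSE]
        vars <- apply(Gi, 2, function(d) stats::var(d[!is.na(d)]))
        vars[is.na(vars)] <- 0
      }
      if (all(vars > 0)) { ok <- TRUE; break }
    }
    if (!ok) { skipped <- skipped + 1L; next }
    ests[b] <- if (fast) {
      .wme_from_crossprod(S, n, p)
    } else {
      .wme_from_individual(Gi, x[idx], y[idx], age[idx], sex[idx])
    }
  }
  ests <- ests[!is.na(ests)]
  se <- stats::sd(ests)
  p <- if (se == 0) {
    if (point == 0) 1 else .Machine$double.xmin
  } else {
    2 * stats::pnorm(-abs(point / se))
  }
  res <- .mr_result("wme", point, se, p, ncol(G), bootstrap_B = B,
                    extra = list(skipped = skipped))
  res
}

.wme_from_individual <- function(G, x, y, age, sex) {
  if (anyNA(G) || anyNA(x) || anyNA(y)) {
    ex <- snp_summary_stats(G, x, age, sex, trait_id = "exposure")
    oy <- snp_summary_stats(G, y, age, sex, trait_id = "outcome")
    rt <- suppressWarnings(ratio_estimates(ex, oy))
    return(weighted_median_estimate(rt))
  }
  A <- cbind(1, age, sex, x, y, G)
  .wme_from_crossprod(crossprod(A), nrow(G), ncol(G))
}

# All per-instrument adjusted regressions for both traits, computed from the
# Gram matrix of (1, age, sex, x, y, Z) by Frisch-Waugh-Lovell partialling;
# algebraically identical to the per-SNP OLS fits.
.wme_from_crossprod <- function(S, n, p) {
  cc <- 1:3
  Bc <- solve(S[cc, cc], S[cc, , drop = FALSE])
  Tm <- S - crossprod(S[cc, , drop = FALSE], Bc)
  ks <- 5L + seq_len(p)
  dkk <- diag(Tm)[ks]
  bx <- Tm[ks, 4] / dkk
  by <- Tm[ks, 5] / dkk
  rss_y <- Tm[5, 5] - by^2 * dkk
  rss_y[rss_y < 0] <- 0
  sey2 <- rss_y / ((n - 4L) * dkk)
  keep <- bx != 0
  weighted_median_estimate(by[keep] / bx[keep], bx[keep]^2 / sey2[keep])
}

#' Count invalid instruments by L1-penalised direct-effect selection
#'
#' Implements the "some invalid, some valid IV estimator" idea: after
#' residualising exposure, outcome and dosages on (intercept, age, sex), the
#' model Y = Z alpha + X beta + error is fitted on the projection onto the
#' column space of Z, with an L1 penalty on the direct effects alpha and no
#' penalty on beta. The penalty is chosen by 10-fold cross-validation on the
#' projected residual (the conservative "1se" rule); instruments with
#' nonzero alpha at the selected penalty are reported invalid. The fraction
#' of weighted-median weight they carry is reported alongside, since the
#' weighted median is consistent only while that fraction stays below 1/2.
#'
#' @inheritParams bootstrap_wme
#' @param lambda_grid optional decreasing penalty sequence; defaults to the
#'   glmnet path.
#' @param seed seed for the cross-validation fold assignment.
#' @return list of class `invalid_report`: `n_invalid`, `invalid_snp_ids`,
#'   `lambda_selected`, `weight_fraction_invalid`, `beta` (the causal-effect
#'   coefficient at the selected penalty).
#' @export
count_invalid_sisvive <- function(genotypes, cohort, instrument_set, outcome_id,
                                  lambda_grid = NULL, seed = 1L) {
  snps <- if (inherits(instrument_set, "instrument_set")) {
    instrument_set$snp_ids
  } else {
    as.character(instrument_set)
  }
  if (length(snps) < 3L) stop("invalid-instrument counting needs >= 3 instruments")
  common <- intersect(rownames(genotypes), cohort$subject_id)
  G <- genotypes[common, snps, drop = FALSE]
  ph <- cohort[match(common, cohort$subject_id), ]
  x <- log(ph$bmi)
  y <- log(ph[[outcome_id]])
  ok <- stats::complete.cases(x, y, ph$age, ph$sex)
  G <- G[ok, , drop = FALSE]
  for (j in seq_len(ncol(G))) {  # mean-impute residual missing dosages
    nas <- is.na(G[, j])
    if (any(nas)) G[nas, j] <- mean(G[, j], na.rm = TRUE)
  }
  x <- x[ok]; y <- y[ok]
  n <- nrow(G)
  if (n <= ncol(G) + 3L) stop("too few subjects for invalid-instrument counting")
  C <- cbind(1, ph$age[ok], ph$sex[ok])
  qc <- qr(C)
  Zr <- qr.resid(qc, G)
  xr <- qr.resid(qc, x)
  yr <- qr.resid(qc, y)
  qz <- qr(Zr)
  if (qz$rank < ncol(Zr)) stop("projected instrument design is singular")
  PZy <- qr.fitted(qz, yr)
  PZx <- qr.fitted(qz, xr)

  ex <- snp_summary_stats(genotypes[common, snps, drop = FALSE][ok, , drop = FALSE],
                          x, ph$age[ok], ph$sex[ok])
  oy <- snp_summary_stats(genotypes[common, snps, drop = FALSE][ok, , drop = FALSE],
                          y, ph$age[ok], ph$sex[ok])
  wme_w <- stats::setNames(ex$beta^2 / oy$se^2, ex$snp_id)

  if (stats::var(PZy) == 0) {
    return(structure(list(n_invalid = 0L, invalid_snp_ids = character(),
                          lambda_selected = NA_real_,
                          weight_fraction_invalid = 0, beta = 0),
                     class = "invalid_report"))
  }
  # Profile out the causal effect: with xt = P_Z x, minimising over beta
  # leaves the lasso of (P_Z - P_xt) y on (P_Z - P_xt) Z in alpha alone.
  proj <- function(Zrows, xrows, M) {
    qz <- qr(Zrows)
    xt <- qr.fitted(qz, xrows)
    sx2 <- sum(xt^2)
    P <- qr.fitted(qz, M)
    P - xt %*% (crossprod(xt, P) / sx2)
  }
  sx2 <- sum(PZx^2)
  ytil <- PZy - PZx * sum(PZx * PZy) / sx2
  Ztil <- Zr - PZx %*% (crossprod(PZx, Zr) / sx2)
  fit0 <- glmnet::glmnet(Ztil, ytil, family = "gaussian",
                         lambda = lambda_grid,
                         intercept = FALSE, standardize = TRUE)
  lams <- fit0$lambda

  # 10-fold CV on the projected residual: alpha is fitted on the training
  # fold's projected system; each lambda is scored by the test fold's own
  # projection of y - Z alpha (the causal effect profiled out per fold).
  set.seed(seed)
  nfolds <- 10L
  foldid <- sample(rep_len(seq_len(nfolds), n))
  errs <- matrix(NA_real_, nfolds, length(lams))
  for (f in seq_len(nfolds)) {
    tr <- foldid != f
    qz_tr <- qr(Zr[tr, , drop = FALSE])
    xt_tr <- qr.fitted(qz_tr, xr[tr])
    sx2_tr <- sum(xt_tr^2)
    ytil_tr <- qr.fitted(qz_tr, yr[tr])
    ytil_tr <- ytil_tr - xt_tr * sum(xt_tr * ytil_tr) / sx2_tr
    Ztil_tr <- Zr[tr, , drop = FALSE] -
      xt_tr %*% (crossprod(xt_tr, Zr[tr, , drop = FALSE]) / sx2_tr)
    fit <- glmnet::glmnet(Ztil_tr, drop(ytil_tr), family = "gaussian",
                          lambda = lams, intercept = FALSE,
                          standardize = TRUE)
    A <- as.matrix(fit$beta)
    Rres <- yr[!tr] - Zr[!tr, , drop = FALSE] %*% A
    PR <- proj(Zr[!tr, , drop = FALSE], xr[!tr], Rres)
    errs[f, seq_len(ncol(A))] <- colSums(PR^2) / sum(!tr)
  }
  keep <- colSums(is.na(errs)) == 0
  lams <- lams[keep]; errs <- errs[, keep, drop = FALSE]
  cvm <- colMeans(errs)
  cvse <- apply(errs, 2, stats::sd) / sqrt(nfolds)
  i_min <- which.min(cvm)
  i_1se <- min(which(cvm <= cvm[i_min] + cvse[i_min]))
  lambda_sel <- lams[i_1se]
  alpha_hat <- as.numeric(fit0$beta[, match(lambda_sel, fit0$lambda)])
  beta_hat <- sum(PZx * (yr - drop(Zr %*% alpha_hat))) / sx2
  invalid <- snps[alpha_hat != 0]
  wfrac <- if (sum(wme_w) > 0) sum(wme_w[invalid]) / sum(wme_w) else 0
  structure(list(n_invalid = length(invalid), invalid_snp_ids = invalid,
                 lambda_selected = lambda_sel,
                 weight_fraction_invalid = unname(wfrac),
                 beta = beta_hat),
            class = "invalid_report")
}

#' @export
print.invalid_report <- function(x, ...) {
  cat(sprintf(
    "Invalid instruments: %d (%s); weight fraction %.3f; lambda %.4g\n",
    x$n_invalid,
    if (x$n_invalid) paste(x$invalid_snp_ids, collapse = ", ") else "none",
    x$weight_fraction_invalid, x$lambda_selected))
  invisible(x)
}
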