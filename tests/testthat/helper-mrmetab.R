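# Shared fixtures and small independent oracles, built in code at test time.

# Dosage vectors with realistic genotype class frequencies, as reported in
# genotyping summaries: percentages of 688 subjects in the 0/1/2 dosage
# classes, remainder uncalled. Used as inputs for MAF/orientation checks.
freq_row_counts <- function(pct0, pct1, pct2, n_total = 688) {
  n0 <- round(n_total * pct0 / 100)
  n1 <- round(n_total * pct1 / 100)
  n2 <- round(n_total * pct2 / 100)
  c(rep(0, n0), rep(1, n1), rep(2, n2),
    rep(NA_real_, n_total - n0 - n1 - n2))
}

# Brute-force allele-count oracle for the minor allele frequency.
maf_oracle <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  minor <- sum(d)           # allele-2 count
  total <- 2 * length(d)
  minor / total
}

# Explicit normal-equations OLS oracle (matrix solve, no shortcuts).
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  sigma2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(diag(sigma2 * solve(XtX)))
  list(beta = unname(drop(b)), se = unname(se))
}

# Explicit weighted normal-equations oracle for a (possibly through-origin)
# weighted regression, with the same residual-variance floor convention.
wls_oracle <- function(y, X, w, floor_phi = TRUE) {
  W <- diag(w)
  XtWX <- t(X) %*% W %*% X
  b <- solve(XtWX, t(X) %*% W %*% y)
  res <- y - X %*% b
  phi <- sum(w * res^2) / (length(y) - ncol(X))
  if (floor_phi) phi <- max(1, phi)
  covb <- phi * solve(XtWX)
  list(beta = unname(drop(b)), se = unname(sqrt(diag(covb))), phi = phi)
}

# Grid oracle for the weighted-median interpolant: evaluate the
# piecewise-linear weighted empirical CDF on a fine grid of candidate
# estimates and return the first grid point whose CDF value reaches 1/2.
wme_grid_oracle <- function(ratio, weight, n_grid = 200000L) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- weight[ord]
  pj <- (cumsum(w) - w / 2) / sum(w)
  grid <- seq(min(r), max(r), length.out = n_grid)
  cdf <- numeric(length(grid))
  for (i in seq_along(grid)) {
    g <- grid[i]
    if (g <= r[1]) { cdf[i] <- pj[1]; next }
    if (g >= r[length(r)]) { cdf[i] <- pj[length(pj)]; next }
    k <- max(which(r <= g))
    if (r[k + 1] == r[k]) { cdf[i] <- pj[k + 1]; next }
    cdf[i] <- pj[k] + (pj[k + 1] - pj[k]) * (g - r[k]) / (r[k + 1] - r[k])
  }
  grid[min(which(cdf >= 0.5))]
}

# Exhaustive hypergeometric tail oracle from binomial coefficients.
hyper_tail_oracle <- function(a, K, N, nc, upper = TRUE) {
  ks <- max(0, K + nc - N):min(K, nc)
  pk <- choose(K, ks) * choose(N - K, nc - ks) / choose(N, nc)
  if (upper) sum(pk[ks >= a]) else sum(pk[ks <= a])
}

# Adjusted Rand index between two partitions (label-permutation invariant).
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Small utility: per-outcome summary stats + all estimators on one simulated
# cohort, for the sampling-property tests.
fit_all <- function(sim, outcome = "M001") {
  ph <- sim$cohort
  ex <- snp_summary_stats(sim$genotypes, log(ph$bmi), ph$age, ph$sex,
                          trait_id = "log_bmi")
  oy <- snp_summary_stats(sim$genotypes, log(ph[[outcome]]), ph$age, ph$sex,
                          trait_id = outcome)
  list(ex = ex, oy = oy,
       ivw = ivw_estimate(ex, oy),
       egger = egger_estimate(ex, oy),
       wme = weighted_median_estimate(ratio_estimates(ex, oy)))
}

# A toy panel with exactly one planted failure per filter plus one clean SNP.
build_qc_toy <- function() {
  set.seed(29)
  n <- 400
  clean <- rbinom(n, 2, 0.3)
  lowcall <- rbinom(n, 2, 0.3); lowcall[seq_len(0.1 * n)] <- NA  # call rate 0.9
  raremaf <- c(rep(1, 4), rep(0, n - 4))                          # MAF 0.005
  badhwe <- c(rep(0, n / 2), rep(2, n / 2))                       # |z| >> 4
  weak <- rbinom(n, 2, 0.3)                                       # no association
  dup <- clean                                                    # r^2 = 1 twin
  G <- cbind(s1_clean = clean, s2_lowcall = lowcall, s3_rare = raremaf,
             s4_hwe = badhwe, s5_weak = weak, s6_dup = dup)
  rownames(G) <- sprintf("P%04d", seq_len(n))
  age <- runif(n, 25, 74); sex <- rbinom(n, 1, 0.5)
  # exposure driven hard by the clean SNP so that s1 (and its twin) pass p<=1e-5
  x <- 3.2 + 0.08 * clean + rnorm(n, 0, 0.05)
  cohort <- data.frame(subject_id = rownames(G), bmi = exp(x),
                       age = age, sex = sex)
  list(G = G, cohort = cohort)
}
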