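test_that("orientation flips major-allele-coded columns and is idempotent", {
  # frequency row (-, 3.3, 94): dosage 2 is the common class and must flip
  inverted <- freq_row_counts(0, 3.3, 94)
  ok <- freq_row_counts(49.7, 39.2, 6.5)
  G <- cbind(inv = inverted, fine = ok)
  rownames(G) <- sprintf("S%03d", seq_len(nrow(G)))
  O <- orient_to_minor_allele(G)
  expect_identical(attr(O, "recoded"), "inv")
  expect_equal(O[, "inv"], 2 - inverted, ignore_attr = TRUE)
  expect_equal(O[, "fine"], ok, ignore_attr = TRUE)
  # dosage 2 is now the rare class
  expect_lt(minor_allele_frequency(O[, "inv"]), 0.5)
  # idempotence
  O2 <- orient_to_minor_allele(O)
  expect_equal(unclass(O2), unclass(O), ignore_attr = TRUE)

  # exactly 0.5: keep as-is
  half <- c(rep(0, 10), rep(2, 10))
  Gh <- matrix(half, ncol = 1, dimnames = list(NULL, "h"))
  expect_equal(orient_to_minor_allele(Gh)[, 1], half, ignore_attr = TRUE)
})

test_that("call rates follow their definitions and the MCAR binomial law", {
  G <- matrix(c(0, 1, 2, NA, 1, 1), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  cr <- call_rates(G)
  expect_equal(unname(cr$snp), c(1, 2 / 3))
  expect_equal(unname(cr$subject), c(0.5, 1, 1))

  col20 <- c(rep(1, 19), NA)
  expect_equal(unname(call_rates(cbind(x = col20))$snp), 0.95)

  G <- simulate_genotypes(snp_spec(sprintf("s%d", 1:50), 0.3,
                                   missing_rate = 0.1), 10000, seed = 21)
  expect_true(all(abs(call_rates(G)$snp - 0.9) < 0.01))
  expect_gt(mean(call_rates(G)$snp), 0.89)
  expect_lt(mean(call_rates(G)$snp), 0.91)
  expect_error(call_rates(matrix(numeric(0), 0, 0)), "empty")
})

test_that("minor allele frequency equals the allele-count oracle", {
  row <- freq_row_counts(49.7, 39.2, 6.5)
  expect_equal(minor_allele_frequency(row), maf_oracle(row), tolerance = 1e-15)
  # (n_het + 2 n_hom) / (2 n_called) spelled out
  called <- sum(!is.na(row))
  expect_equal(minor_allele_frequency(row),
               (sum(row == 1, na.rm = TRUE) + 2 * sum(row == 2, na.rm = TRUE)) /
                 (2 * called))
  expect_equal(minor_allele_frequency(rep(0, 10)), 0)
  expect_equal(minor_allele_frequency(rep(1, 10)), 0.5)
  expect_true(is.na(minor_allele_frequency(rep(NA_real_, 5))))
})

test_that("the HWE statistic is the signed root chi-square", {
  # exact HWE at q = 1/3: expected counts are the observed counts
  d <- c(rep(0, 400), rep(1, 400), rep(2, 100))
  expect_equal(hwe_statistic(d), 0, tolerance = 1e-12)

  # total heterozygote deficit: chi-square computed by hand
  d <- c(rep(0, 500), rep(2, 500))
  # q = 0.5 -> expected (250, 500, 250); chi2 = 250 + 500 + 250 = 1000
  expect_equal(hwe_statistic(d), -sqrt(1000), tolerance = 1e-12)

  # heterozygote excess has positive sign
  d <- c(rep(0, 100), rep(1, 800), rep(2, 100))
  expect_gt(hwe_statistic(d), 0)

  expect_error(hwe_statistic(c(1, NA)), "at least 2")
  expect_equal(hwe_statistic(rep(0, 50)), 0)

  # under HWE the statistic is (nearly always) inside the +-4 screen
  G <- simulate_genotypes(snp_spec(sprintf("s%d", 1:1000),
                                   rep(c(0.05, 0.2, 0.4), length.out = 1000)),
                          5000, seed = 22)
  z <- apply(G, 2, hwe_statistic)
  expect_gte(mean(abs(z) < 4), 0.999)
})

test_that("LD r2 is squared dosage correlation, sign-blind, null-calibrated", {
  set.seed(23)
  a <- rbinom(500, 2, 0.3)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 2 - a), 1)
  expect_warning(r <- ld_r2(a, rep(1, 500)), "zero dosage variance")
  expect_true(is.na(r))
  expect_error(ld_r2(a, a[-1]), "length")

  G <- simulate_genotypes(snp_spec(sprintf("s%d", 1:40), 0.3), 10000, seed = 24)
  pairs <- utils::combn(40, 2)
  r2 <- apply(pairs, 2, function(ij) ld_r2(G[, ij[1]], G[, ij[2]]))
  expect_gte(mean(r2 < 0.01), 0.99)
})

test_that("adjusted regression equals the explicit normal-equations oracle", {
  set.seed(25)
  for (i in 1:200) {
    n <- sample(30:120, 1)
    dos <- rbinom(n, 2, runif(1, 0.1, 0.5))
    if (var(dos) == 0) next
    age <- runif(n, 25, 74)
    sex <- rbinom(n, 1, 0.5)
    y <- rnorm(n, 1 + 0.2 * dos + 0.01 * age - 0.1 * sex, 0.7)
    fit <- adjusted_regression(y, dos, age, sex)
    orc <- ols_oracle(y, cbind(1, dos, age, sex))
    expect_equal(fit$beta, orc$beta[2], tolerance = 1e-10)
    expect_equal(fit$se, orc$se[2], tolerance = 1e-10)
  }
})

test_that("an exact linear trait is flagged exact-fit with zero SE", {
  set.seed(26)
  dos <- rbinom(60, 2, 0.4)
  age <- runif(60, 25, 74); sex <- rbinom(60, 1, 0.5)
  fit <- adjusted_regression(3 + 2 * dos, dos, age, sex)
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_equal(fit$se, 0)
  expect_true(fit$exact_fit)
  expect_error(adjusted_regression(rnorm(60), dos, age, rep(1, 60) * 0 + sex * 0),
               "collinear")
})

test_that("vectorised summary stats agree with per-SNP regressions", {
  cfg <- mr_scenario("valid", n_subjects = 400, n_outcomes = 1, seed = 27)
  cfg$snp_specs$missing_rate <- rep(c(0, 0.05), 9)  # exercise both code paths
  sim <- simulate_cohort(cfg)
  y <- log(sim$cohort$bmi)
  st <- snp_summary_stats(sim$genotypes, y, sim$cohort$age, sim$cohort$sex)
  for (j in seq_len(ncol(sim$genotypes))) {
    fit <- adjusted_regression(y, sim$genotypes[, j], sim$cohort$age,
                               sim$cohort$sex)
    expect_equal(st$beta[j], fit$beta, tolerance = 1e-10)
    expect_equal(st$se[j], fit$se, tolerance = 1e-10)
    expect_equal(st$n_used[j], fit$n_used)
  }
})

test_that("exposure association recovers a small planted effect at scale", {
  specs <- snp_spec("s1", 0.3)
  cfg <- sim_config(n_subjects = 50000, snp_specs = specs, gamma = 0.02,
                    beta = 0, n_outcomes = 1, kappa_x = 0,
                    noise_sd_x = 0.15, noise_sd_y = 0.3,
                    age_effect_x = 4e-4, sex_effect_x = 0.01, seed = 28)
  sim <- simulate_cohort(cfg)
  fit <- adjusted_regression(log(sim$cohort$bmi), sim$genotypes[, 1],
                             sim$cohort$age, sim$cohort$sex)
  expect_lt(abs(fit$beta - 0.02), 3 * fit$se)
})


test_that("instrument selection applies each filter once, with audited reasons", {
  toy <- build_qc_toy()
  inst <- select_instruments(toy$G, toy$cohort)
  expect_identical(inst$snp_ids, "s1_clean")
  expect_equal(nrow(inst$exclusions), 5)
  reasons <- setNames(inst$exclusions$filter, inst$exclusions$snp_id)
  expect_identical(unname(reasons["s2_lowcall"]), "call_rate")
  expect_identical(unname(reasons["s3_rare"]), "maf")
  expect_identical(unname(reasons["s4_hwe"]), "hwe")
  expect_identical(unname(reasons["s5_weak"]), "association_p")
  expect_identical(unname(reasons["s6_dup"]), "ld_prune")
})

test_that("impossible thresholds give an empty, warned-about instrument set", {
  toy <- build_qc_toy()
  expect_warning(
    inst <- select_instruments(toy$G, toy$cohort,
                               qc_thresholds(p = 0)),
    "no SNPs survive")
  expect_length(inst$snp_ids, 0)
})

test_that("greedy LD pruning keeps the smaller association p-value", {
  set.seed(30)
  n <- 2000
  z <- rbinom(n, 2, 0.3)
  twin <- z
  flip <- sample(n, 40)  # mildly degraded copy: r^2 near 1, weaker assoc
  twin[flip] <- rbinom(40, 2, 0.3)
  G <- cbind(b_strong = z, a_twin = twin)
  rownames(G) <- sprintf("P%04d", 1:n)
  x <- 3.2 + 0.05 * z + rnorm(n, 0, 0.1)
  cohort <- data.frame(subject_id = rownames(G), bmi = exp(x),
                       age = runif(n, 25, 74), sex = rbinom(n, 1, 0.5))
  inst <- select_instruments(G, cohort)
  # both pass the association filter; the smaller-p SNP wins the LD prune
  # even though its id sorts later
  expect_gt(ld_r2(z, twin), 0.05)
  expect_identical(inst$snp_ids, "b_strong")
  expect_identical(inst$exclusions$filter, "ld_prune")

  # exact duplicates tie on p and fall back to the lexicographic rule
  G2 <- cbind(a_dup = z, b_dup = z)
  rownames(G2) <- rownames(G)
  inst2 <- select_instruments(G2, cohort)
  expect_identical(inst2$snp_ids, "a_dup")
})

test_that("selection is invariant to SNP column order", {
  toy <- build_qc_toy()
  perm <- c(4, 1, 6, 3, 2, 5)
  inst1 <- select_instruments(toy$G, toy$cohort)
  inst2 <- select_instruments(toy$G[, perm], toy$cohort)
  expect_setequal(inst1$snp_ids, inst2$snp_ids)
  expect_setequal(inst1$exclusions$snp_id, inst2$exclusions$snp_id)
})

test_that("selection retains a power-calibrated panel at the reference size", {
  kept <- vapply(1:30, function(s) {
    cfg <- mr_scenario("valid", n_subjects = 688, n_outcomes = 1,
                       power_n = 688, seed = 4000 + s)
    sim <- simulate_cohort(cfg)
    suppressWarnings(
      length(select_instruments(sim$genotypes, sim$cohort)$snp_ids))
  }, numeric(1))
  expect_gte(mean(kept) / 18, 0.8)
})
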