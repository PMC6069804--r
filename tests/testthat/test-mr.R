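rand_stats <- function(J, seed) {
  set.seed(seed)
  list(ex = data.frame(snp_id = sprintf("s%02d", 1:J),
                       beta = rnorm(J, 0.05, 0.04),
                       se = runif(J, 0.005, 0.02)),
       oy = data.frame(snp_id = sprintf("s%02d", 1:J),
                       beta = rnorm(J, 0.02, 0.05),
                       se = runif(J, 0.01, 0.05)))
}

test_that("ratio estimates and weights follow their definitions", {
  ex <- data.frame(snp_id = "a", beta = 0.1, se = 0.01)
  oy <- data.frame(snp_id = "a", beta = 0.2, se = 0.05)
  r <- ratio_estimates(ex, oy)
  expect_equal(r$ratio, 2)
  expect_equal(r$weight, 0.01 / 0.0025)

  ex2 <- rbind(ex, data.frame(snp_id = "b", beta = 0, se = 0.01))
  oy2 <- rbind(oy, data.frame(snp_id = "b", beta = 0.1, se = 0.02))
  expect_warning(r2 <- ratio_estimates(ex2, oy2), "zero exposure")
  expect_identical(r2$snp_id, "a")

  oy3 <- oy; oy3$snp_id <- "c"
  expect_error(ratio_estimates(ex, oy3), "differ.*c|c.*differ")
})

test_that("a noiseless single-instrument cohort returns the structural effect", {
  specs <- snp_spec("z", 0.4)
  cfg <- sim_config(n_subjects = 500, snp_specs = specs, gamma = 0.2,
                    beta = 0.7, n_outcomes = 1, kappa_x = 0, kappa_y = 0,
                    noise_sd_x = 0, noise_sd_y = 0, seed = 31)
  sim <- simulate_cohort(cfg)
  ex <- adjusted_regression(log(sim$cohort$bmi), sim$genotypes[, 1],
                            sim$cohort$age, sim$cohort$sex, snp_id = "z")
  oy <- adjusted_regression(log(sim$cohort$M001), sim$genotypes[, 1],
                            sim$cohort$age, sim$cohort$sex, snp_id = "z")
  expect_equal(oy$beta / ex$beta, 0.7, tolerance = 1e-8)
})

test_that("IVW, Egger-through-origin and the weighted ratio mean coincide", {
  for (i in 1:100) {
    st <- rand_stats(sample(3:25, 1), 4000 + i)
    ivw <- ivw_estimate(st$ex, st$oy)
    # constrained-WLS oracle: through-origin weighted regression
    w <- 1 / st$oy$se^2
    orc <- wls_oracle(st$oy$beta, cbind(st$ex$beta), w)
    expect_equal(ivw$estimate, orc$beta[1], tolerance = 1e-10)
    expect_equal(ivw$se, orc$se[1], tolerance = 1e-10)
    # weighted mean of ratios with first-order weights
    rt <- suppressWarnings(ratio_estimates(st$ex, st$oy))
    expect_equal(ivw$estimate,
                 sum(rt$weight * rt$ratio) / sum(rt$weight),
                 tolerance = 1e-10)
  }
})

test_that("points exactly on a line are fitted exactly", {
  ex <- data.frame(snp_id = letters[1:4], beta = c(1, 2, 3, 4),
                   se = rep(0.1, 4))
  oy <- data.frame(snp_id = letters[1:4], beta = 2.5 * c(1, 2, 3, 4),
                   se = rep(0.1, 4))
  expect_equal(ivw_estimate(ex, oy)$estimate, 2.5, tolerance = 1e-12)
  oy$beta <- 0.3 + 1.7 * ex$beta
  eg <- egger_estimate(ex, oy)
  expect_equal(eg$estimate, 1.7, tolerance = 1e-12)
  expect_equal(eg$egger_intercept, 0.3, tolerance = 1e-12)
})

test_that("Egger regression equals the weighted normal-equations oracle", {
  for (i in 1:200) {
    st <- rand_stats(sample(3:25, 1), 5000 + i)
    eg <- egger_estimate(st$ex, st$oy)
    flip <- ifelse(st$ex$beta < 0, -1, 1)
    w <- 1 / st$oy$se^2
    orc <- wls_oracle(st$oy$beta * flip, cbind(1, st$ex$beta * flip), w)
    expect_equal(eg$estimate, orc$beta[2], tolerance = 1e-10)
    expect_equal(eg$se, orc$se[2], tolerance = 1e-10)
    expect_equal(eg$egger_intercept, orc$beta[1], tolerance = 1e-10)
    expect_equal(eg$egger_intercept_se, orc$se[1], tolerance = 1e-10)
  }
})

test_that("Egger output is invariant under re-coding any instrument", {
  st <- rand_stats(12, 6000)
  base <- egger_estimate(st$ex, st$oy)
  for (j in c(1, 5, 12)) {
    ex <- st$ex; oy <- st$oy
    ex$beta[j] <- -ex$beta[j]; oy$beta[j] <- -oy$beta[j]
    flipped <- egger_estimate(ex, oy)
    expect_equal(flipped$estimate, base$estimate, tolerance = 1e-12)
    expect_equal(flipped$egger_intercept, base$egger_intercept,
                 tolerance = 1e-12)
  }
  expect_error(egger_estimate(st$ex[1:2, ], st$oy[1:2, ]), "at least 3")
  expect_error(ivw_estimate(st$ex[1, , drop = FALSE],
                            st$oy[1, , drop = FALSE]), "at least 2")
})

test_that("the weighted median interpolant behaves at the reference points", {
  # equal weights: plain median
  expect_equal(weighted_median_estimate(c(1, 2, 9), rep(1, 3)), 2)
  # dominant interior instrument: cumulative weight hits 1/2 exactly there
  expect_equal(weighted_median_estimate(c(1, 5, 9), c(0.2, 0.6, 0.2)), 5)
  expect_error(weighted_median_estimate(c(1, 2, 3), c(0, 0, 0)), "zero")
  expect_error(weighted_median_estimate(c(1, 2), c(1, 1)), "at least 3")
})

test_that("the weighted median matches a fine-grid CDF oracle", {
  set.seed(32)
  for (i in 1:100) {
    J <- sample(3:20, 1)
    r <- rnorm(J, 0.5, 1)
    w <- runif(J, 0.1, 2)
    est <- weighted_median_estimate(r, w)
    orc <- wme_grid_oracle(r, w)
    step <- (max(r) - min(r)) / 199999
    expect_lt(abs(est - orc), 2 * step)
  }
})

test_that("bootstrap SE vanishes on a noiseless cohort and is seed-stable", {
  specs <- snp_spec(c("z1", "z2", "z3"), c(0.2, 0.3, 0.4))
  cfg <- sim_config(n_subjects = 300, snp_specs = specs,
                    gamma = c(0.1, 0.15, 0.2), beta = 0.5, n_outcomes = 1,
                    kappa_x = 0, kappa_y = 0, noise_sd_x = 0,
                    noise_sd_y = 0, seed = 33)
  sim <- simulate_cohort(cfg)
  w <- suppressWarnings(
    bootstrap_wme(sim$genotypes, sim$cohort, c("z1", "z2", "z3"), "M001",
                  B = 100, seed = 1))
  expect_equal(w$estimate, 0.5, tolerance = 1e-8)
  expect_lt(w$se, 1e-8)

  sim2 <- simulate_cohort(mr_scenario("valid", n_subjects = 500,
                                      n_outcomes = 1, seed = 34))
  b1 <- suppressWarnings(bootstrap_wme(sim2$genotypes, sim2$cohort,
                                       colnames(sim2$genotypes), "M001",
                                       B = 150, seed = 9))
  b2 <- suppressWarnings(bootstrap_wme(sim2$genotypes, sim2$cohort,
                                       colnames(sim2$genotypes), "M001",
                                       B = 150, seed = 9))
  expect_identical(b1$se, b2$se)
  expect_error(suppressWarnings(
    bootstrap_wme(sim2$genotypes, sim2$cohort, colnames(sim2$genotypes),
                  "M001", B = 50, seed = 1)), "at least 100")
})

test_that("invalid-instrument counting is empty without pleiotropy and on a null outcome", {
  sim <- simulate_cohort(mr_scenario("valid", n_subjects = 5000,
                                     n_outcomes = 1, seed = 35))
  rep <- count_invalid_sisvive(sim$genotypes, sim$cohort,
                               colnames(sim$genotypes), "M001", seed = 2)
  expect_equal(rep$n_invalid, 0)
  expect_equal(rep$weight_fraction_invalid, 0)

  # outcome with zero variance: everything zero by construction
  cohort0 <- sim$cohort
  cohort0$M001 <- 1  # log(1) = 0 identically
  rep0 <- count_invalid_sisvive(sim$genotypes, cohort0,
                                colnames(sim$genotypes), "M001", seed = 2)
  expect_equal(rep0$n_invalid, 0L)
  expect_equal(rep0$beta, 0)
  expect_error(count_invalid_sisvive(sim$genotypes, sim$cohort,
                                     colnames(sim$genotypes)[1:2], "M001"),
               ">= 3")
})

test_that("planted strong direct effects are recovered by the L1 count", {
  cfg <- mr_scenario("valid", n_subjects = 5000, n_outcomes = 1, seed = 36)
  cfg$alpha[c(3, 9, 15), ] <- 0.1
  sim <- simulate_cohort(cfg)
  rep <- count_invalid_sisvive(sim$genotypes, sim$cohort,
                               colnames(sim$genotypes), "M001", seed = 5)
  expect_true(all(c("SNP03", "SNP09", "SNP15") %in% rep$invalid_snp_ids))
  expect_lt(rep$weight_fraction_invalid, 0.5)
})
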