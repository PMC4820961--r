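test_that("moderator construction matches the z-transform and 0/1 coding", {
  m <- moderator_from_age(c(25, 50), mean = 37.2, sd = 13.3)
  expect_equal(m$values, c((25 - 37.2) / 13.3, (50 - 37.2) / 13.3))
  expect_equal(m$values[1], -0.917293, tolerance = 1e-6)
  expect_equal(m$values[2], 0.962406, tolerance = 1e-6)
  ages <- c(20, 30, 40, 50)
  m2 <- moderator_from_age(ages)
  expect_equal(mean(m2$values), 0, tolerance = 1e-12)
  expect_equal(sd(m2$values), 1, tolerance = 1e-12)
  expect_error(moderator_from_age(ages, sd = 0), "positive")
  expect_error(moderator_from_sex(c(0, 1, 2)), "0/1")
})

test_that("Wald chi-square equals (beta/se)^2 with chi2(1) p-values", {
  w0 <- wald_chi2(0, 1)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 1)
  w <- wald_chi2(1.959964, 1)
  expect_equal(w$statistic, 3.8416, tolerance = 1e-4)
  expect_equal(w$p, 0.05, tolerance = 1e-4)
  expect_error(wald_chi2(1, 0), "positive")
})

test_that("Bonferroni thresholds reproduce the genome-wide alphas", {
  expect_equal(multiple_testing_threshold(0.05, 117), 0.05 / 117)
  expect_equal(multiple_testing_threshold(0.05, 117), 4.2735e-4,
               tolerance = 1e-4)
  expect_equal(multiple_testing_threshold(0.05, 411169), 1.2e-7,
               tolerance = 0.02)
  expect_equal(multiple_testing_threshold(0.05, 391227), 1.3e-7,
               tolerance = 0.02)
  expect_equal(multiple_testing_threshold(0.05, 1), 0.05)
  expect_error(multiple_testing_threshold(1.5, 10), "alpha")
  expect_error(multiple_testing_threshold(0.05, 0), "n_tests")
})

test_that("heritability trajectories follow the moderated-variance formulas", {
  fit <- list(sigma_a = 0.6325, beta_g = 0, sigma_e = 0.7746, beta_e = 0.2,
              moderator = list(kind = "age_z", source_mean = 37.2,
                               source_sd = 13.3))
  expect_equal((fit$sigma_a + fit$beta_g * 1)^2, 0.4001, tolerance = 1e-3)
  expect_equal(h2_at(fit, 1), 0.4001 / (0.4001 + 0.9498), tolerance = 1e-3)
  expect_equal(h2_at(fit, 1), 0.2964, tolerance = 1e-3)
  # constant when both slopes are zero
  fit0 <- list(sigma_a = 0.5, beta_g = 0, sigma_e = 0.7, beta_e = 0)
  expect_equal(h2_at(fit0, c(-2, 0, 2)), rep(h2_at(fit0, 0), 3))
  # environmental variance vanishing drives h2 to 1
  fitv <- list(sigma_a = 0.5, beta_g = 0, sigma_e = 0.4, beta_e = 0.2)
  expect_equal(h2_at(fitv, -2), 1)
  vp <- variance_profile(fit, ages = c(25, 50))
  expect_equal(vp$age, c(25, 50))
  expect_equal(vp$vtot, vp$va + vp$ve)
  expect_s3_class(autoplot(vp), "ggplot")
})

test_that("moderation fit recovers environmental-variance-by-age effects", {
  co <- fixture_cohort()
  m_age <- moderator_from_age(co$covars$age)
  est <- t(sapply(1:15, function(i) {
    y <- fixture_site(site_params(var_ped = 0.4, var_e = 0.6,
                                  beta_e_age = 0.25), seed = 600 + i)
    f <- fit_moderation(y, co$A_ped, m_age)
    c(f$beta_g, f$beta_e, f$sigma_e)
  }))
  expect_lt(abs(mean(est[, 1]) - 0), 0.05)
  expect_lt(abs(mean(est[, 2]) - 0.25), 0.05)
  expect_lt(abs(mean(est[, 3]) - sqrt(0.6)), 0.06)
})

test_that("Wald statistics are reproducible from the stored fields", {
  co <- fixture_cohort()
  m_age <- moderator_from_age(co$covars$age)
  y <- fixture_site(site_params(var_ped = 0.4, var_e = 0.6,
                                beta_e_age = 0.2), seed = 61)
  f <- fit_moderation(y, co$A_ped, m_age)
  expect_equal(f$chi2_g, (f$beta_g / f$se_beta_g)^2, tolerance = 1e-10)
  expect_equal(f$chi2_e, (f$beta_e / f$se_beta_e)^2, tolerance = 1e-10)
  expect_true(f$sigma_a >= 0 && f$sigma_e >= 0)
  expect_error(fit_moderation(y, co$A_ped, rep(1, length(y))), "constant")
  td <- tidy(f)
  expect_equal(td$term, c("sigma_a", "beta_g", "sigma_e", "beta_e"))
})

test_that("moderation likelihood is invariant to joint sign flips", {
  co <- fixture_cohort()
  m_age <- moderator_from_age(co$covars$age)
  y <- fixture_site(site_params(var_ped = 0.4, var_e = 0.6,
                                beta_g_age = 0.15), seed = 62)
  nll <- methvc:::make_mod_lik(y, co$A_ped$matrix, m_age$values)
  par <- c(0.6, 0.1, 0.75, -0.05)
  expect_equal(nll(par), nll(c(-par[1:2], par[3:4])), tolerance = 1e-10)
  expect_equal(nll(par), nll(c(par[1:2], -par[3:4])), tolerance = 1e-10)
})

test_that("genetic covariance term stays positive semidefinite under moderation", {
  co <- fixture_cohort()
  A <- co$A_ped$matrix[1:40, 1:40]
  set.seed(63)
  for (i in 1:5) {
    g <- 0.5 + rnorm(1, 0, 0.3) * runif(40, -1, 1)
    DAD <- A * tcrossprod(g)
    ev <- eigen(DAD, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("sex-moderated heritability matches sex-stratified AE twin fits", {
  cfg <- sim_config(n_mz_pairs = 800, n_dz_pairs = 800, n_snps = 50,
                    prop_female = 0.5,
                    site_params = sample_site_params(1, 1), seed = 64)
  ped <- simulate_pedigree(cfg)
  covars <- simulate_covariates(ped, cfg)
  geno <- simulate_genotypes(ped, cfg)
  p <- site_params(var_ped = 0.35, var_e = 0.65, beta_g_sex = 0.15,
                   beta_e_sex = -0.1)
  y <- simulate_site(ped, geno, covars, p, seed = 65)
  y <- (y - mean(y)) / sd(y)
  A_ped <- pedigree_kinship(ped)
  f <- fit_moderation(y, A_ped, moderator_from_sex(covars$sex))

  # same-sex pairs only, stratified classical AE fits
  strat <- function(sexcode) {
    sel <- ped$sample_id[covars$sex == sexcode]
    pd <- ped[ped$sample_id %in% sel, ]
    keep <- names(table(pd$family_id))[table(pd$family_id) == 2]
    pd <- pd[pd$family_id %in% keep, ]
    fit_twin_model(twin_pairs(pd, y[pd$sample_id]), "AE")$a2
  }
  expect_lt(abs(h2_at(f, 0) - strat(0)), 0.05)
  expect_lt(abs(h2_at(f, 1) - strat(1)), 0.05)
})
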