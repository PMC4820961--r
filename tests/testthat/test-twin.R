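make_pairs <- function(n_mz, n_dz, r_mz, r_dz, seed = 1) {
  set.seed(seed)
  draw <- function(n, r) {
    z <- matrix(rnorm(2 * n), n, 2)
    z[, 2] <- r * z[, 1] + sqrt(1 - r^2) * z[, 2]
    z
  }
  mz <- draw(n_mz, r_mz); dz <- draw(n_dz, r_dz)
  tibble::tibble(
    family_id = paste0("f", seq_len(n_mz + n_dz)),
    zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)),
    value1 = c(mz[, 1], dz[, 1]), value2 = c(mz[, 2], dz[, 2]))
}

test_that("twin correlations and the Falconer estimate are exact on toys", {
  p <- tibble::tibble(family_id = paste0("f", 1:3), zygosity = "MZ",
                      value1 = c(1, 2, 3), value2 = c(2, 4, 6))
  rc <- twin_correlations(p)
  expect_equal(rc$rmz, 1.0)
  expect_true(is.na(rc$rdz))

  expect_equal(falconer_h2(0.20, 0.09)$h2, 0.22)
  expect_false(falconer_h2(0.20, 0.09)$out_of_range)
  expect_equal(falconer_h2(0.5, 0.25)$h2, 0.5)
  neg <- falconer_h2(0.1, 0.2)
  expect_equal(neg$h2, -0.2)
  expect_true(neg$out_of_range)

  degen <- tibble::tibble(family_id = paste0("f", 1:3), zygosity = "MZ",
                          value1 = c(1, 1, 1), value2 = c(2, 4, 6))
  expect_error(twin_correlations(degen), "zero variance")
})

test_that("simulated twin correlations match the generative values", {
  co <- fixture_cohort()
  y <- fixture_site(site_params(var_ped = 0.4, var_e = 0.6), seed = 31)
  rc <- twin_correlations(twin_pairs(co$ped, y))
  fisher_se <- 1 / sqrt(150 - 3)
  expect_lt(abs(atanh(rc$rmz) - atanh(0.4)), 3 * fisher_se)
  expect_lt(abs(atanh(rc$rdz) - atanh(0.2)), 3 * fisher_se)
})

test_that("ML twin fits land on the moment solution where it is interior", {
  # rMZ = rDZ forces a2 to 0 and c2 to the common correlation
  p1 <- make_pairs(1000, 1000, 0.4, 0.4, seed = 32)
  f1 <- fit_twin_model(p1, "ACE")
  expect_lt(f1$a2, 0.07)
  expect_lt(abs(f1$c2 - 0.4), 0.05)

  # rMZ = 2 rDZ forces c2 to 0 and a2 to rMZ
  p2 <- make_pairs(2000, 2000, 0.6, 0.3, seed = 33)
  f2 <- fit_twin_model(p2, "ACE")
  expect_lt(abs(f2$a2 - 0.6), 0.05)
  expect_lt(f2$c2, 0.05)

  # proportions always sum to one exactly
  expect_equal(f1$a2 + f1$c2 + f1$d2 + f1$e2, 1, tolerance = 1e-8)
  expect_equal(f2$a2 + f2$c2 + f2$d2 + f2$e2, 1, tolerance = 1e-8)
})

test_that("ML ACE estimates agree with closed-form moments on balanced data", {
  p <- make_pairs(5000, 5000, 0.55, 0.35, seed = 34)
  rc <- twin_correlations(p)
  f <- fit_twin_model(p, "ACE")
  expect_lt(abs(f$a2 - 2 * (rc$rmz - rc$rdz)), 0.02)
  expect_lt(abs(f$c2 - (2 * rc$rdz - rc$rmz)), 0.02)
  expect_lt(abs(f$e2 - (1 - rc$rmz)), 0.02)
})

test_that("ADE parameters are recovered from simulated dominance data", {
  cfg <- sim_config(n_mz_pairs = 2500, n_dz_pairs = 2500, n_snps = 10,
                    site_params = sample_site_params(1, 1), seed = 35)
  ped <- simulate_pedigree(cfg)
  covars <- simulate_covariates(ped, cfg)
  geno <- simulate_genotypes(ped, cfg)
  y <- simulate_site(ped, geno, covars,
                     site_params(var_ped = 0.3, var_d = 0.3, var_e = 0.4),
                     seed = 36)
  f <- fit_twin_model(twin_pairs(ped, y), "ADE")
  expect_lt(abs(f$a2 - 0.3), 0.05)
  expect_lt(abs(f$d2 - 0.3), 0.05)
  expect_lt(abs(f$e2 - 0.4), 0.05)
})

test_that("likelihood ratio tests follow the chi-square reference", {
  p <- make_pairs(400, 400, 0.5, 0.25, seed = 37)
  ae <- fit_twin_model(p, "AE")
  e <- fit_twin_model(p, "E")
  ace <- fit_twin_model(p, "ACE")
  lrt <- likelihood_ratio_test(ae, e)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p, pchisq(lrt$statistic, 1, lower.tail = FALSE))
  expect_lt(lrt$p, 1e-6)                 # strong additive signal

  # identical logliks give statistic 0 and p = 1
  full0 <- structure(list(model = "ACE", loglik = -100,
                          n_mz = 10, n_dz = 10), class = "twin_fit")
  red0 <- structure(list(model = "AE", loglik = -100,
                         n_mz = 10, n_dz = 10), class = "twin_fit")
  lrt0 <- likelihood_ratio_test(full0, red0)
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p, 1)

  # chi-square quantile sanity at the conventional cutoff
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)

  ade <- fit_twin_model(p, "ADE")
  expect_error(likelihood_ratio_test(ace, ade), "not nested")
  expect_error(likelihood_ratio_test(e, ae), "not nested")
})

test_that("LRT for C under a true AE model rejects at or below nominal rate", {
  set.seed(38)
  n_reps <- 400
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    p <- make_pairs(120, 120, 0.5, 0.25, seed = 1000 + r)
    ace <- fit_twin_model(p, "ACE", n_restarts = 0)
    ae <- fit_twin_model(p, "AE", n_restarts = 0)
    rej[r] <- likelihood_ratio_test(ace, ae)$p < 0.05
  }
  # boundary truncation makes the test conservative
  expect_lte(mean(rej), 0.06 + 2 * sqrt(0.05 * 0.95 / n_reps))
})

test_that("per-site twin table carries estimates, tests and status", {
  co <- fixture_cohort()
  m <- rbind(a = fixture_site(site_params(var_ped = 0.5, var_e = 0.5), 41),
             b = fixture_site(site_params(var_ped = 0, var_e = 1), 42))
  colnames(m) <- co$ped$sample_id
  tbl <- fit_twin_models_sites(m, co$ped)
  expect_equal(tbl$site_id, c("a", "b"))
  expect_true(all(tbl$status == "ok"))
  expect_gt(tbl$a2[1], 0.3)
  expect_lt(tbl$p_a[1], 1e-4)
  expect_gt(tbl$p_a[2], 1e-4)
  expect_equal(tbl$h2_twins, 2 * (tbl$rmz - tbl$rdz))
})

test_that("tidy and glance expose twin fit results in broom form", {
  p <- make_pairs(200, 200, 0.5, 0.25, seed = 43)
  f <- fit_twin_model(p, "ACE")
  td <- tidy(f)
  expect_equal(td$term, c("a2", "c2", "e2"))
  expect_equal(sum(td$estimate), 1, tolerance = 1e-8)
  gl <- glance(f)
  expect_equal(gl$model, "ACE")
  expect_equal(gl$n_mz, 200)
})
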