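test_that("pedigree structure respects twin definitions and counts", {
  cfg <- sim_config(n_mz_pairs = 1, n_dz_pairs = 0,
                    site_params = sample_site_params(1, 1), seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 2)
  expect_equal(length(unique(ped$family_id)), 1)
  expect_true(all(ped$zygosity == "MZ"))
  expect_equal(ped$sex[1], ped$sex[2])
  expect_equal(ped$age[1], ped$age[2])

  cfg2 <- sim_config(n_mz_pairs = 769, n_dz_pairs = 424,
                     site_params = sample_site_params(1, 1), seed = 2)
  ped2 <- simulate_pedigree(cfg2)
  expect_equal(nrow(ped2), 2386)   # twin individuals in the emulated cohort

  # determinism: identical config and seed give identical tables
  expect_identical(simulate_pedigree(cfg2), ped2)

  expect_error(sim_config(n_mz_pairs = 0, n_dz_pairs = 0), "at least one")
})

test_that("gene dropping realises the expected relatedness structure", {
  co <- fixture_cohort()
  ped <- co$ped; G <- co$geno$dosage
  expect_true(all(G %in% 0:2))

  mz <- ped[ped$zygosity %in% "MZ", ]
  fam1 <- mz$sample_id[mz$family_id == mz$family_id[1]]
  expect_identical(G[fam1[1], ], G[fam1[2], ])

  # brute-force allele-sharing: mean realized additive relatedness of DZ
  # pairs approximately 0.5 (3 s.e. over SNPs and pairs)
  A <- co$A_ibs$matrix
  dz <- ped[ped$zygosity %in% "DZ", ]
  dzfam <- split(dz$sample_id, dz$family_id)
  r_dz <- vapply(dzfam, function(ids) A[ids[1], ids[2]], numeric(1))
  se <- sd(r_dz) / sqrt(length(r_dz))
  expect_lt(abs(mean(r_dz) - 0.5), 3 * se)

  # founders from different families are unrelated on average
  par_ids <- ped$sample_id[ped$role == "parent"]
  Ap <- A[par_ids, par_ids]
  off <- Ap[upper.tri(Ap)]
  fam_of <- ped$family_id[match(par_ids, ped$sample_id)]
  cross <- outer(fam_of, fam_of, `!=`)[upper.tri(Ap)]
  expect_lt(abs(mean(off[cross])), 3 * sd(off[cross]) / sqrt(sum(cross)))
})

test_that("site generator reproduces the requested variance partition", {
  cfg <- sim_config(n_mz_pairs = 500, n_dz_pairs = 500, n_snps = 100,
                    site_params = sample_site_params(1, 1), seed = 3)
  ped <- simulate_pedigree(cfg)
  covars <- simulate_covariates(ped, cfg)
  geno <- simulate_genotypes(ped, cfg)

  # fully heritable site: MZ within-pair correlation exactly 1
  y <- simulate_site(ped, geno, covars,
                     site_params(var_ped = 1, var_e = 0), seed = 4)
  rc <- twin_correlations(twin_pairs(ped, y))
  expect_equal(rc$rmz, 1.0, tolerance = 1e-12)
  expect_equal(rc$rdz, 0.5, tolerance = 0.1)

  # pure noise site: both correlations near zero
  y0 <- simulate_site(ped, geno, covars,
                      site_params(var_ped = 0, var_e = 1), seed = 5)
  rc0 <- twin_correlations(twin_pairs(ped, y0))
  expect_lt(abs(rc0$rmz), 3 / sqrt(500))
  expect_lt(abs(rc0$rdz), 3 / sqrt(500))

  # variance normalised to about 1
  y2 <- simulate_site(ped, geno, covars,
                      site_params(var_snp = 0.4, var_ped = 0, var_e = 0.6,
                                  n_causal = 10), seed = 6)
  expect_equal(var(y2), 1, tolerance = 0.05)

  # twin correlations match the theoretical mixture at moderate n
  p <- site_params(var_snp = 0.2, var_ped = 0.2, var_c = 0.1, var_d = 0.1,
                   var_e = 0.4, n_causal = 10)
  y3 <- simulate_site(ped, geno, covars, p, seed = 7)
  rc3 <- twin_correlations(twin_pairs(ped, y3))
  fisher_se <- 1 / sqrt(500 - 3)
  expect_lt(abs(atanh(rc3$rmz) - atanh(0.6)), 3 * fisher_se)
  expect_lt(abs(atanh(rc3$rdz) - atanh(0.5 * 0.4 + 0.1 + 0.025)), 3 * fisher_se)

  # non-positive moderated variance is a configuration error
  expect_error(
    simulate_site(ped, geno, covars,
                  site_params(var_ped = 0.9, var_e = 0.1, beta_e_age = 1),
                  seed = 8),
    "non-positive")
})

test_that("dataset generation writes consistent files with beta in (0,1)", {
  cfg <- sim_config(n_mz_pairs = 30, n_dz_pairs = 30, n_snps = 50,
                    site_params = sample_site_params(8, 2), seed = 9)
  dir <- withr::local_tempdir()
  ds <- generate_dataset(cfg, dir)
  expect_true(all(file.exists(unlist(ds$paths))))
  expect_true(all(ds$methylation_beta >= 0 & ds$methylation_beta <= 1,
                  na.rm = TRUE))
  # missingness mirrored across scales and near the configured rate
  expect_identical(is.na(ds$methylation_m), is.na(ds$methylation_beta))
  n_cells <- length(ds$methylation_m)
  rate <- mean(is.na(ds$methylation_m))
  se <- sqrt(0.001 * 0.999 / n_cells)
  expect_lt(abs(rate - 0.001), 3 * se)

  # round trip through TSV
  m2 <- read_meth_matrix(ds$paths$methylation_m)
  expect_equal(m2, ds$methylation_m, tolerance = 1e-9)

  # no missingness when the rate is zero
  cfg0 <- sim_config(n_mz_pairs = 5, n_dz_pairs = 5, n_snps = 20,
                     site_params = sample_site_params(2, 3),
                     missing_rate = 0, seed = 10)
  ds0 <- generate_dataset(cfg0, withr::local_tempdir())
  expect_false(anyNA(ds0$methylation_m))

  # byte-level determinism of the generator
  dirA <- withr::local_tempdir(); dirB <- withr::local_tempdir()
  generate_dataset(cfg0, dirA); generate_dataset(cfg0, dirB)
  for (f in c("pedigree.tsv", "methylation_m.tsv", "genotypes.tsv")) {
    expect_identical(readLines(file.path(dirA, f)),
                     readLines(file.path(dirB, f)))
  }
})
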