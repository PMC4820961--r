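# shared synthetic fixtures, built once per test run
.fixtures <- new.env()

# small twin-family cohort used across modules: 150 MZ + 150 DZ pairs,
# 400 SNPs
fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    cfg <- sim_config(n_mz_pairs = 150, n_dz_pairs = 150, n_parents = 20,
                      n_snps = 400, site_params = sample_site_params(5, 1),
                      seed = 20240101)
    ped <- simulate_pedigree(cfg)
    covars <- simulate_covariates(ped, cfg)
    geno <- simulate_genotypes(ped, cfg)
    .fixtures$cohort <- list(cfg = cfg, ped = ped, covars = covars,
                             geno = geno,
                             A_ibs = compute_grm(geno),
                             A_ped = pedigree_kinship(ped))
  }
  .fixtures$cohort
}

# one simulated standardized site on the fixture cohort
fixture_site <- function(params, seed) {
  co <- fixture_cohort()
  y <- simulate_site(co$ped, co$geno, co$covars, params, seed = seed)
  (y - mean(y)) / sd(y)
}
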