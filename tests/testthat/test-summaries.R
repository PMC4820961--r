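mk_mat <- function(values, sites, samples) {
  matrix(values, length(sites), length(samples),
         dimnames = list(sites, samples))
}

test_that("paired correlations handle identity, nulls and summaries", {
  set.seed(81)
  sites <- paste0("cg", 1:50); samples <- paste0("s", 1:30)
  x <- mk_mat(rnorm(1500), sites, samples)
  # identical matrices give r = 1 everywhere
  r1 <- paired_site_correlations(x, x)
  expect_equal(r1$r, rep(1, 50), tolerance = 1e-12)
  expect_equal(attr(r1, "mean_r"), 1, tolerance = 1e-12)
  # independent re-draw gives mean r near 0
  y <- mk_mat(rnorm(1500), sites, samples)
  r0 <- paired_site_correlations(x, y)
  expect_lt(abs(attr(r0, "mean_r")), 3 / sqrt(30 * 50) * 10)
  # mixture of stable and unstable sites hits the analytic mean
  rho <- 0.8; n_stable <- 25
  y2 <- y
  for (i in 1:n_stable) {
    y2[i, ] <- rho * x[i, ] + sqrt(1 - rho^2) * rnorm(30)
  }
  rmix <- paired_site_correlations(x, y2)
  expected <- (n_stable * rho + 25 * 0) / 50
  expect_equal(attr(rmix, "mean_r"), expected, tolerance = 0.1)
})

test_that("stability-heritability coupling is detected by correlation", {
  r_tbl <- tibble::tibble(site_id = paste0("cg", 1:30),
                          r = seq(0.1, 0.9, length.out = 30))
  h_tbl <- tibble::tibble(site_id = paste0("cg", 1:30),
                          h2_twins = seq(0.1, 0.9, length.out = 30))
  expect_equal(correlate_with_h2(r_tbl, h_tbl), 1)
  set.seed(82)
  h_perm <- h_tbl
  h_perm$h2_twins <- sample(h_perm$h2_twins)
  expect_lt(abs(correlate_with_h2(r_tbl, h_perm)), 0.5)
  expect_error(correlate_with_h2(r_tbl[1:2, ], h_tbl[1:2, ]), "3 shared")
})

test_that("EWAS-list overlap counts interaction flags by set arithmetic", {
  cat_tbl <- tibble::tibble(
    site_id = paste0("cg", 1:10),
    h2_ibd = seq(0.05, 0.5, by = 0.05),
    sig_age_g = c(rep(TRUE, 1), rep(FALSE, 9)),
    sig_age_e = c(rep(TRUE, 4), rep(FALSE, 6)))
  ov <- ewas_overlap(cat_tbl, paste0("cg", 1:10))
  expect_equal(ov$counts$n[ov$counts$flag == "sig_age_g"], 1)
  expect_equal(ov$counts$n[ov$counts$flag == "sig_age_e"], 4)
  expect_equal(ov$mean_h2, mean(cat_tbl$h2_ibd))

  # disjoint list: all counts zero, missing ids reported
  ov0 <- ewas_overlap(cat_tbl, c("cg11", "cg12"))
  expect_true(all(ov0$counts$n == 0))
  expect_equal(ov0$missing_ids, c("cg11", "cg12"))

  # 5-site toy mean h2 by hand
  ov5 <- ewas_overlap(cat_tbl, paste0("cg", 1:5))
  expect_equal(ov5$mean_h2, mean(c(0.05, 0.1, 0.15, 0.2, 0.25)))
  expect_error(ewas_overlap(cat_tbl, character()), "empty")
})

test_that("discordant MZ contrast separates exposure-affected sites", {
  set.seed(83)
  n_pairs <- 60
  ped <- tibble::tibble(
    family_id = rep(paste0("f", 1:n_pairs), each = 2),
    sample_id = paste0("s", 1:(2 * n_pairs)),
    father_id = "0", mother_id = "0", sex = "F",
    role = "mz_twin", zygosity = "MZ",
    age = rep(30, 2 * n_pairs))
  g <- rep(rnorm(n_pairs), each = 2)       # shared genetic value
  base <- outer(rep(1, 5), g) +
    matrix(rnorm(5 * 2 * n_pairs, 0, 0.5), 5)
  dimnames(base) <- list(paste0("cg", 1:5), ped$sample_id)
  # exposure: 20 concordant-exposed pairs, 20 unexposed, 20 discordant
  exposure <- setNames(rep(0L, 2 * n_pairs), ped$sample_id)
  exposure[1:40] <- 1L
  exposure[seq(81, 120, by = 2)] <- 1L

  # no exposure effect: group means agree
  r_null <- discordant_mz_contrast(base, ped, exposure)
  mr <- r_null$group_means$mean_r
  expect_lt(max(mr) - min(mr), 0.35)

  # exposure shifting one twin decorrelates discordant pairs
  affected <- base
  affected <- affected + 2 * matrix(rep(exposure, each = 5), 5) *
    matrix(rnorm(5 * 2 * n_pairs), 5)
  r_eff <- discordant_mz_contrast(affected, ped, exposure)
  gm <- r_eff$group_means
  expect_lt(gm$mean_r[gm$group == "discordant"],
            gm$mean_r[gm$group == "concordant_unexposed"])

  # all-concordant input omits the discordant group (with warnings for
  # every empty group)
  suppressWarnings(
    r2 <- discordant_mz_contrast(base, ped,
                                 setNames(rep(1L, 2 * n_pairs),
                                          ped$sample_id)))
  expect_false("discordant" %in% r2$group_means$group)
  expect_true("concordant_exposed" %in% r2$group_means$group)
})

test_that("catalogue assembly enforces a common site universe and round-trips", {
  a <- tibble::tibble(site_id = c("cg1", "cg2"), h2_ibd = c(0.3, 0.5))
  b <- tibble::tibble(site_id = c("cg1", "cg2"), rmz = c(0.2, 0.4))
  cat_tbl <- build_catalogue(a, b)
  expect_equal(names(cat_tbl), c("site_id", "h2_ibd", "rmz"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalogue(cat_tbl, path)
  expect_equal(as.data.frame(read_catalogue(path)), as.data.frame(cat_tbl))
  bad <- tibble::tibble(site_id = c("cg1", "cg3"), x = 1:2)
  expect_error(build_catalogue(a, bad), "conflicting")
})

test_that("CpG lists read from both supported text layouts", {
  p1 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("cg1", "cg2", "cg3"), p1)
  l1 <- read_cpg_list(p1, source = "smoking")
  expect_equal(l1$site_id, c("cg1", "cg2", "cg3"))
  expect_true(all(l1$source == "smoking"))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(site_id = c("cg9", "cg8"),
                                  source = c("bmi", "bmi")), p2)
  l2 <- read_cpg_list(p2)
  expect_equal(l2$site_id, c("cg9", "cg8"))
  expect_equal(l2$source, c("bmi", "bmi"))
})
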