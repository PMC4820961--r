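toy_genes <- tibble::tibble(
  gene_id = c("g1", "g2"), chrom = c("1", "1"), strand = c("+", "-"),
  tss = c(100000, 300000), end = c(120000, 280000))

toy_sites <- function(pos, chrom = "1") {
  tibble::tibble(site_id = paste0("cg", seq_along(pos)),
                 chrom = chrom, pos = pos)
}

test_that("gene-centric windows follow the TSS-anchored definitions", {
  # 2 kb upstream of the nearest TSS: distal promoter
  expect_equal(assign_gene_region(toy_sites(98000), toy_genes),
               "distal_promoter")
  # 100 bp downstream of the TSS: proximal promoter
  expect_equal(assign_gene_region(toy_sites(100100), toy_genes),
               "proximal_promoter")
  # inside the gene beyond +500: gene body
  expect_equal(assign_gene_region(toy_sites(110000), toy_genes),
               "gene_body")
  # past the 3' end within 5 kb: downstream
  expect_equal(assign_gene_region(toy_sites(123000), toy_genes),
               "downstream")
  # far from every TSS and outside all windows: intergenic
  expect_equal(assign_gene_region(toy_sites(200000), toy_genes),
               "intergenic")
  # boundary positions belong to the promoter-proximal class
  expect_equal(assign_gene_region(toy_sites(100000 - 1500), toy_genes),
               "proximal_promoter")
  expect_equal(assign_gene_region(toy_sites(100000 + 500), toy_genes),
               "proximal_promoter")
  expect_equal(assign_gene_region(toy_sites(100000 - 10000), toy_genes),
               "distal_promoter")
  # a site 2 kb upstream of the minus-strand gene's TSS (i.e., at larger
  # coordinate) is in its distal promoter
  expect_equal(assign_gene_region(toy_sites(302000), toy_genes),
               "distal_promoter")
  # unknown chromosome warns and labels intergenic
  expect_warning(
    lbl <- assign_gene_region(toy_sites(5000, chrom = "9"), toy_genes),
    "absent")
  expect_equal(lbl, "intergenic")
})

test_that("CGI-centric classes use exact 2-kb shore and shelf widths", {
  cgis <- tibble::tibble(chrom = "1", start = 50000, end = 51000)
  lab <- function(pos) assign_cgi_region(toy_sites(pos), cgis)
  expect_equal(lab(50500), "island")
  expect_equal(lab(50000), "island")
  expect_equal(lab(49999 - 1499), "shore")   # 1,500 bp from the edge
  expect_equal(lab(51000 + 2000), "shore")
  expect_equal(lab(51000 + 3000), "shelf")
  expect_equal(lab(51000 + 4000), "shelf")
  expect_equal(lab(51000 + 4001), "non_cgi")
  expect_equal(lab(50000 - 4000), "shelf")
  expect_equal(assign_cgi_region(toy_sites(100, chrom = "2"), cgis),
               "non_cgi")
})

test_that("CGI sequence criteria count CG dinucleotides correctly", {
  seq_cgi <- strrep("CG", 125)
  r <- check_cgi_criteria(seq_cgi)
  expect_true(r$is_cgi)
  expect_equal(r$gc_fraction, 1)
  expect_equal(r$length, 250)
  expect_equal(r$obs_exp_cpg, 125 / (125 * 125 / 250))  # 2.0
  expect_equal(r$obs_exp_cpg, 2)

  expect_false(check_cgi_criteria(strrep("A", 300))$is_cgi)
  expect_false(check_cgi_criteria(strrep("CG", 75))$is_cgi)   # 150 bp: too short
  expect_error(check_cgi_criteria("ACGTN"), "ambiguous")
})

test_that("site categorisation applies strict and inclusive thresholds", {
  cat_in <- tibble::tibble(site_id = paste0("cg", 1:4),
                           h2_ibd = c(0.5, 0.49, 0.19, 0.2),
                           h2_snps = c(0.5, 0.1, 0.6, 0.19))
  sd_beta <- setNames(c(0.03, 0.031, 0.2, 0.001), cat_in$site_id)
  lr <- setNames(c(0.5, 0.2, 0.19, 0.9), cat_in$site_id)
  cats <- categorize_sites(cat_in, sd_beta = sd_beta, longitudinal_r = lr)
  expect_equal(cats$high_h2, c(TRUE, FALSE, FALSE, FALSE))   # h2 >= 0.5
  expect_equal(cats$low_h2, c(FALSE, FALSE, TRUE, FALSE))    # h2 < 0.2
  expect_equal(cats$high_h2snp, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cats$low_h2snp, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(cats$variable, c(FALSE, TRUE, TRUE, FALSE))   # sd > 0.03 strict
  expect_equal(cats$longitudinally_stable, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(cats$longitudinally_unstable, c(FALSE, FALSE, TRUE, FALSE))
  # high/low flags are mutually exclusive
  expect_false(any(cats$high_h2 & cats$low_h2))
})

test_that("enrichment chi-square matches the hand-computed Pearson statistic", {
  # contingency [[20,10],[10,20]]: chi2 = 6.667, p = 0.00983
  bg <- paste0("cg", 1:60)
  ann <- setNames(rep(c("island", "non_cgi"), each = 30), bg)
  cat_sites <- c(paste0("cg", 1:20), paste0("cg", 31:40))
  res <- enrichment_test(cat_sites, bg, ann, family_size = 117)
  isl <- res[res$class == "island", ]
  # brute-force Pearson chi-square from the explicit table
  tab <- matrix(c(20, 10, 10, 20), 2, 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2_brute <- sum((tab - E)^2 / E)
  expect_equal(isl$chi2, chi2_brute, tolerance = 1e-10)
  expect_equal(isl$chi2, 20 / 3, tolerance = 1e-10)
  expect_equal(isl$p, 0.009823, tolerance = 1e-4)
  expect_equal(isl$direction, "enriched")
  # at family size 117 neither 0.00983 nor 1e-3 pass; 1e-5 does
  expect_false(isl$significant)
  thr <- multiple_testing_threshold(0.05, 117)
  expect_true(1e-5 < thr && 1e-3 > thr)

  # identical composition gives a null statistic
  same <- enrichment_test(bg[seq(1, 60, 2)], bg, ann)
  expect_lt(max(same$chi2), 1e-10)
  expect_equal(min(same$p), 1, tolerance = 1e-9)

  expect_error(enrichment_test(character(), bg, ann), "empty")
  expect_error(enrichment_test("cgX", bg, ann), "subset")
})

test_that("region assignment is exhaustive and exclusive over random sites", {
  set.seed(71)
  sites <- toy_sites(sort(sample.int(4e5, 200)))
  g_lab <- assign_gene_region(sites, toy_genes)
  cgis <- tibble::tibble(chrom = "1", start = c(50000, 150000),
                         end = c(51000, 152000))
  c_lab <- assign_cgi_region(sites, cgis)
  expect_true(all(g_lab %in% c("proximal_promoter", "distal_promoter",
                               "gene_body", "downstream", "intergenic")))
  expect_true(all(c_lab %in% c("island", "shore", "shelf", "non_cgi")))
  expect_equal(length(g_lab), nrow(sites))
  expect_equal(length(c_lab), nrow(sites))
})
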