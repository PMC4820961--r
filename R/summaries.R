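#' Per-site correlations between repeated measures
#'
#' Correlates, for each site, the values of the same individuals at two
#' time points (or in two tissues), and summarises the genome-wide mean and
#' median.
#'
#' @param x,y Two sites x samples matrices with identical dimnames (time 1
#'   and time 2, or blood and buccal).
#' @param min_pairs Minimum complete pairs per site (default 3); sites
#'   below it get `NA`.
#' @return Tibble with `site_id`, `r`, `n`; the genome-wide `mean_r` and
#'   `median_r` (over non-degenerate sites) are attached as attributes and
#'   via `summary()`.
#' @export
paired_site_correlations <- function(x, y, min_pairs = 3) {
  check_meth_matrix(x); check_meth_matrix(y)
  assert_that(identical(dimnames(x), dimnames(y)),
              "the two matrices must share sites and samples")
  out <- purrr::map_dfr(rownames(x), function(sid) {
    ok <- !is.na(x[sid, ]) & !is.na(y[sid, ])
    if (sum(ok) < min_pairs || sd(x[sid, ok]) == 0 || sd(y[sid, ok]) == 0) {
      return(tibble(site_id = sid, r = NA_real_, n = sum(ok)))
    }
    tibble(site_id = sid, r = cor(x[sid, ok], y[sid, ok]), n = sum(ok))
  })
  assert_that(any(!is.na(out$r)), "all sites degenerate; no correlations")
  attr(out, "mean_r") <- mean(out$r, na.rm = TRUE)
  attr(out, "median_r") <- median(out$r, na.rm = TRUE)
  out
}

#' Correlate per-site stability with heritability
#'
#' Pearson correlation, over the shared site set, between a per-site
#' correlation (longitudinal or cross-tissue) and the per-site twin
#' heritability.
#'
#' @param r_sites Tibble with `site_id` and `r` (e.g., from
#'   [paired_site_correlations()]).
#' @param h2_sites Tibble with `site_id` and a heritability column
#'   (`h2_twins`, `h2_ibd`, or pass `h2_col`).
#' @param h2_col Name of the heritability column.
#' @return Pearson correlation (scalar).
#' @export
correlate_with_h2 <- function(r_sites, h2_sites, h2_col = "h2_twins") {
  d <- dplyr::inner_join(r_sites, h2_sites, by = "site_id")
  d <- d[!is.na(d$r) & !is.na(d[[h2_col]]), ]
  assert_that(nrow(d) >= 3, "fewer than 3 shared sites with estimates")
  cor(d$r, d[[h2_col]])
}

#' Overlap of a published CpG list with the catalogue
#'
#' Counts how many sites of a trait-associated CpG list carry each type of
#' significant interaction flag, and summarises the list's heritability.
#'
#' @param catalogue Catalogue tibble with `site_id`, heritability columns,
#'   and logical interaction flag columns (e.g. `sig_age_g`, `sig_age_e`,
#'   `sig_sex_g`, `sig_sex_e`).
#' @param cpg_list Character vector of site ids, or a tibble with a
#'   `site_id` column and optional `source` tag.
#' @param flag_cols Names of the logical flag columns to count; defaults to
#'   every column starting with `sig_`.
#' @param h2_col Heritability column to summarise.
#' @return List with `n_list`, `n_in_catalogue`, `missing_ids`, `counts`
#'   (tibble flag/count), `mean_h2`, `sd_h2`.
#' @export
ewas_overlap <- function(catalogue, cpg_list, flag_cols = NULL,
                         h2_col = "h2_ibd") {
  ids <- if (is.data.frame(cpg_list)) cpg_list$site_id else cpg_list
  assert_that(length(ids) > 0, "CpG list is empty")
  assert_that(!anyDuplicated(ids), "CpG list ids must be unique")
  flag_cols <- flag_cols %||% grep("^sig_", names(catalogue), value = TRUE)
  hit <- catalogue[catalogue$site_id %in% ids, ]
  missing_ids <- setdiff(ids, catalogue$site_id)
  counts <- tibble(flag = flag_cols,
                   n = vapply(flag_cols,
                              function(f) sum(hit[[f]], na.rm = TRUE),
                              numeric(1), USE.NAMES = FALSE))
  h2 <- hit[[h2_col]]
  list(n_list = length(ids), n_in_catalogue = nrow(hit),
       missing_ids = missing_ids, counts = counts,
       mean_h2 = mean(h2, na.rm = TRUE), sd_h2 = sd(h2, na.rm = TRUE))
}

#' Within-pair correlations in exposure-concordant and -discordant MZ twins
#'
#' Splits MZ pairs by exposure pattern (both exposed, both unexposed,
#' discordant) and computes per-site within-pair correlations and the
#' group-level mean correlation over sites, the comparison used to show
#' that a discordant exposure weakens co-twin resemblance at
#' exposure-sensitive sites.
#'
#' @param meth Sites x samples matrix.
#' @param ped Pedigree tibble.
#' @param exposure Named 0/1 vector (per sample id) of exposure status.
#' @param sites Site ids to analyse (default: all rows of `meth`).
#' @param min_pairs Minimum pairs per group (default 3); smaller groups are
#'   omitted with a warning.
#' @return List with `per_site` (tibble: group, site_id, r) and
#'   `group_means` (tibble: group, n_pairs, mean_r).
#' @export
discordant_mz_contrast <- function(meth, ped, exposure, sites = NULL,
                                   min_pairs = 3) {
  check_meth_matrix(meth)
  sites <- sites %||% rownames(meth)
  mz <- ped[ped$zygosity %in% "MZ", ]
  mz <- mz[order(mz$family_id, mz$sample_id), ]
  fams <- split(mz$sample_id, mz$family_id)
  fams <- fams[lengths(fams) == 2]
  grp <- vapply(fams, function(ids) {
    e <- exposure[ids]
    if (anyNA(e)) NA_character_
    else if (sum(e) == 2) "concordant_exposed"
    else if (sum(e) == 0) "concordant_unexposed"
    else "discordant"
  }, character(1))
  per_site <- purrr::map_dfr(
    c("concordant_exposed", "concordant_unexposed", "discordant"),
    function(g) {
      f <- fams[which(grp == g)]
      if (length(f) < min_pairs) {
        rlang::warn(paste0("group ", g, " has fewer than ", min_pairs,
                           " pairs; omitted"))
        return(tibble())
      }
      id1 <- vapply(f, `[`, character(1), 1)
      id2 <- vapply(f, `[`, character(1), 2)
      purrr::map_dfr(sites, function(sid) {
        v1 <- meth[sid, id1]; v2 <- meth[sid, id2]
        ok <- !is.na(v1) & !is.na(v2)
        r <- if (sum(ok) >= 3 && sd(v1[ok]) > 0 && sd(v2[ok]) > 0) {
          cor(v1[ok], v2[ok])
        } else NA_real_
        tibble(group = g, site_id = sid, r = r, n_pairs = sum(ok))
      })
    })
  group_means <- per_site |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_pairs = max(.data$n_pairs),
                     mean_r = mean(.data$r, na.rm = TRUE), .groups = "drop")
  list(per_site = per_site, group_means = group_means)
}

#' Assemble and write the per-site catalogue
#'
#' Joins per-site outputs (descriptives, twin estimates, two-GRM estimates,
#' moderation estimates, category flags, annotations) on `site_id` into the
#' catalogue table, one row per site; sites present in one input but not
#' another raise an error listing the discrepancies.
#'
#' @param ... Tibbles each containing a `site_id` column.
#' @return Catalogue tibble.
#' @export
build_catalogue <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  assert_that(length(parts) > 0, "no inputs")
  universe <- parts[[1]]$site_id
  for (p in parts[-1]) {
    extra <- setdiff(p$site_id, universe)
    miss <- setdiff(universe, p$site_id)
    assert_that(length(extra) == 0 && length(miss) == 0,
                paste0("conflicting site universes; e.g. ",
                       paste(head(c(extra, miss), 5), collapse = ", ")))
  }
  Reduce(function(a, b) dplyr::left_join(a, b, by = "site_id"), parts)
}

#' @rdname build_catalogue
#' @param catalogue Catalogue tibble.
#' @param path Output TSV path.
#' @export
write_catalogue <- function(catalogue, path) {
  readr::write_tsv(catalogue, path)
  invisible(path)
}

#' @rdname build_catalogue
#' @export
read_catalogue <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a CpG list from disk
#'
#' Accepts one-id-per-line text or a two-column TSV (`site_id`, `source`).
#'
#' @param path File path.
#' @param source Optional source tag overriding the file's.
#' @return Tibble with `site_id` and `source`.
#' @export
read_cpg_list <- function(path, source = NA_character_) {
  first <- readr::read_lines(path, n_max = 1)
  if (grepl("\t", first)) {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    names(df)[1] <- "site_id"
    if (ncol(df) == 1) df$source <- source else names(df)[2] <- "source"
    if (!is.na(source)) df$source <- source
    df[, c("site_id", "source")]
  } else {
    tibble(site_id = readr::read_lines(path), source = source)
  }
}
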