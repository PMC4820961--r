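#' Genetic relationship matrices
#'
#' A `grm` object is a symmetric samples x samples relatedness matrix with a
#' `kind` tag: `ibs` for the standardized-genotype estimator, a thresholded
#' variant (`ibd_thresholded`) in which distant relationships are zeroed so
#' entries approximate genome shared identity-by-descent, or
#' `pedigree_expected` for expected additive relatedness derived from the
#' pedigree.
#'
#' @param matrix Symmetric numeric matrix with sample ids as dimnames.
#' @param kind One of `"ibs"`, `"ibd_thresholded"`, `"pedigree_expected"`.
#' @param n_snps Number of SNPs the estimate is based on (NA for pedigree).
#' @return An object of class `grm`.
#' @export
grm <- function(matrix, kind = c("ibs", "ibd_thresholded", "pedigree_expected"),
                n_snps = NA_integer_) {
  kind <- match.arg(kind)
  assert_that(is.matrix(matrix) && nrow(matrix) == ncol(matrix),
              "GRM must be a square matrix")
  assert_that(max(abs(matrix - t(matrix))) < 1e-10, "GRM must be symmetric")
  assert_that(!is.null(rownames(matrix)), "GRM needs sample ids as dimnames")
  structure(list(matrix = matrix, kind = kind, n_snps = n_snps,
                 sample_ids = rownames(matrix)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm: %s, %d samples%s>\n", x$kind, nrow(x$matrix),
              if (is.na(x$n_snps)) "" else sprintf(", %d SNPs", x$n_snps)))
  invisible(x)
}

as_grm_matrix <- function(A) {
  if (inherits(A, "grm")) A$matrix else A
}

#' Compute the IBS genetic relationship matrix
#'
#' Standard standardized-genotype estimator over SNPs passing the MAF
#' filter: \deqn{A_{jk} = \frac{1}{N}\sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
#' {2 p_i (1 - p_i)}} with allele frequencies `p_i` estimated from the
#' sample. Missing dosages are handled by pairwise-complete averaging: each
#' pair's mean runs over the SNPs observed in both samples.
#'
#' @param genotypes Samples x SNPs matrix of dosages (0/1/2, NA allowed),
#'   or the list returned by [simulate_genotypes()].
#' @param maf_min Minimum minor allele frequency for a SNP to contribute.
#' @param founders_only Optional character vector of sample ids to estimate
#'   allele frequencies from (default: all samples, relatives included).
#' @return A [grm()] of kind `ibs`.
#' @export
compute_grm <- function(genotypes, maf_min = 0.01, founders_only = NULL) {
  X <- if (is.list(genotypes) && !is.data.frame(genotypes)) genotypes$dosage else genotypes
  assert_that(is.matrix(X), "genotypes must be a samples x SNPs matrix")
  assert_that(all(X %in% c(0, 1, 2) | is.na(X)),
              "dosages must be 0, 1, 2 or missing")
  freq_rows <- if (is.null(founders_only)) X else X[founders_only, , drop = FALSE]
  p <- colMeans(freq_rows, na.rm = TRUE) / 2
  v <- apply(X, 2, var, na.rm = TRUE)            # monomorphic in-sample
  keep <- pmin(p, 1 - p) > maf_min & !is.na(p) & !is.na(v) & v > 0
  assert_that(sum(keep) >= 1,
              "no polymorphic SNP passes the MAF filter")
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  W <- sweep(X, 2, 2 * p, `-`)
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), `/`)
  obs <- !is.na(W)
  W[!obs] <- 0
  num <- tcrossprod(W)
  den <- tcrossprod(obs * 1)          # SNPs observed in both samples
  assert_that(all(den > 0), "some sample pair shares no observed SNPs")
  A <- num / den
  A <- (A + t(A)) / 2
  grm(A, "ibs", n_snps = sum(keep))
}

#' Zero out distant relationships in an IBS GRM
#'
#' Off-diagonal entries strictly below `cutoff` are set to zero; entries at
#' or above the cutoff and the diagonal are unchanged. The result
#' approximates relatedness as the proportion of the genome shared
#' identity-by-descent.
#'
#' @param A A [grm()] of kind `ibs`.
#' @param cutoff Threshold (default 0.05); must be non-negative.
#' @return A [grm()] of kind `ibd_thresholded`.
#' @export
threshold_grm <- function(A, cutoff = 0.05) {
  assert_that(inherits(A, "grm") && A$kind == "ibs",
              "`A` must be an ibs GRM")
  assert_that(cutoff >= 0, "`cutoff` must be non-negative")
  M <- A$matrix
  off <- row(M) != col(M)
  M[off & M < cutoff] <- 0
  grm(M, "ibd_thresholded", n_snps = A$n_snps)
}

#' Expected additive relatedness from a pedigree
#'
#' Computes twice the kinship coefficient by the standard recursive
#' algorithm (founders unrelated and non-inbred), then sets MZ co-twin
#' relatedness to 1 since they carry the same genome. Diagonal is 1.
#'
#' @param ped Pedigree tibble (see [simulate_pedigree()] for the schema);
#'   `father_id`/`mother_id` of `"0"` or `NA` mean unknown. DZ twins and
#'   full siblings with unknown parents are still assigned relatedness 0.5
#'   through latent within-family parents.
#' @return A [grm()] of kind `pedigree_expected`.
#' @export
pedigree_kinship <- function(ped) {
  check_pedigree(ped)
  ids <- ped$sample_id
  n <- length(ids)

  # materialise latent parents so sibs/DZ pairs with unsampled parents link up
  fa <- ifelse(ped$father_id %in% c("0", NA), paste0(ped$family_id, "_.fa"),
               ped$father_id)
  mo <- ifelse(ped$mother_id %in% c("0", NA), paste0(ped$family_id, "_.mo"),
               ped$mother_id)
  # sampled parents are founders in their own right
  fa[ped$role == "parent"] <- paste0("founder_fa_", ids[ped$role == "parent"])
  mo[ped$role == "parent"] <- paste0("founder_mo_", ids[ped$role == "parent"])

  latent <- setdiff(unique(c(fa, mo)), ids)
  ord <- order(ped$role != "parent")              # sampled parents before offspring
  all_ids <- c(latent, ids[ord])                  # founders first
  fa_full <- c(setNames(rep(NA_character_, length(latent)), latent),
               setNames(fa, ids)[ids[ord]])
  mo_full <- c(setNames(rep(NA_character_, length(latent)), latent),
               setNames(mo, ids)[ids[ord]])

  assert_that(!any(all_ids == fa_full | all_ids == mo_full, na.rm = TRUE),
              "a sample is listed as its own ancestor")

  N <- length(all_ids)
  phi <- matrix(0, N, N, dimnames = list(all_ids, all_ids))
  for (i in seq_len(N)) {
    f <- fa_full[[i]]; m <- mo_full[[i]]
    if (is.na(f)) {
      phi[i, i] <- 0.5
    } else {
      fi <- match(f, all_ids); mi <- match(m, all_ids)
      assert_that(fi < i && mi < i, "pedigree is not sorted founders-first (cycle?)")
      phi[i, i] <- 0.5 * (1 + phi[fi, mi])
      for (j in seq_len(i - 1)) {
        phi[i, j] <- phi[j, i] <- 0.5 * (phi[fi, j] + phi[mi, j])
      }
    }
  }
  A <- 2 * phi[ids, ids, drop = FALSE]

  # MZ co-twins share their full genome
  mz <- ped[ped$zygosity %in% "MZ", ]
  for (fam in unique(mz$family_id)) {
    tw <- mz$sample_id[mz$family_id == fam]
    A[tw, tw] <- 1
  }
  diag(A) <- 1
  grm(A, "pedigree_expected")
}

#' Read and write GRMs as lower-triangle TSV
#'
#' The text format has one row per sample pair (including the diagonal):
#' `id1`, `id2`, `n_snps`, `value`, mirroring the conventional text export
#' of binary GRM files.
#'
#' @param A A [grm()].
#' @param path File path.
#' @param kind `kind` tag to restore on read.
#' @return `read_grm()` returns a [grm()]; `write_grm()` returns `path`
#'   invisibly.
#' @export
write_grm <- function(A, path) {
  assert_that(inherits(A, "grm"), "`A` must be a grm")
  M <- A$matrix
  idx <- which(lower.tri(M, diag = TRUE), arr.ind = TRUE)
  df <- tibble(id1 = rownames(M)[idx[, 1]], id2 = colnames(M)[idx[, 2]],
               n_snps = A$n_snps, value = M[idx])
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path, kind = "ibs") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- unique(c(df$id1, df$id2))
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  M[cbind(df$id1, df$id2)] <- df$value
  M[cbind(df$id2, df$id1)] <- df$value
  grm(M, kind, n_snps = df$n_snps[1])
}

#' Genotype principal components
#'
#' Top eigenvectors of an IBS GRM, the usual ancestry covariates.
#'
#' @param A A [grm()].
#' @param k Number of components (default 10).
#' @return Samples x k matrix of eigenvectors, columns `PC1..PCk`.
#' @export
genotype_pcs <- function(A, k = 10) {
  M <- as_grm_matrix(A)
  k <- min(k, nrow(M) - 1)
  ev <- eigen(M, symmetric = TRUE)
  pcs <- ev$vectors[, seq_len(k), drop = FALSE]
  dimnames(pcs) <- list(rownames(M), paste0("PC", seq_len(k)))
  pcs
}
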