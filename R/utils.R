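# internal helpers shared across modules

`%||%` <- rlang::`%||%`

# stopifnot() with a readable message
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}

# a methylation value container is a sites x samples numeric matrix with
# rownames = site ids and colnames = sample ids; validate it once at entry
check_meth_matrix <- function(meth) {
  assert_that(is.matrix(meth) && is.numeric(meth),
              "`meth` must be a numeric sites x samples matrix")
  assert_that(!is.null(rownames(meth)) && !is.null(colnames(meth)),
              "`meth` must carry site ids as rownames and sample ids as colnames")
  assert_that(!anyDuplicated(rownames(meth)), "duplicated site ids")
  assert_that(!anyDuplicated(colnames(meth)), "duplicated sample ids")
  invisible(meth)
}

check_pedigree <- function(ped) {
  need <- c("family_id", "sample_id", "father_id", "mother_id",
            "sex", "role", "zygosity", "age")
  missing_cols <- setdiff(need, names(ped))
  assert_that(length(missing_cols) == 0,
              paste0("pedigree is missing columns: ",
                     paste(missing_cols, collapse = ", ")))
  assert_that(!anyDuplicated(ped$sample_id), "duplicated sample ids in pedigree")
  invisible(ped)
}

# draw a child seed deterministically from a parent seed; keeps values
# within the 32-bit integer range R requires
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103515245 + 12345 * stream) %% 2147483647
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))
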