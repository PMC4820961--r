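# Internal engine: profiled-mean multivariate-normal likelihood for a
# linear covariance model V = sum_k exp(l_k) K_k.
#
# The likelihood factorises over connected components of the combined
# kernel sparsity pattern (families, for pedigree-structured kernels), so
# evaluation is done blockwise whenever blocks are small; otherwise one
# dense Cholesky per evaluation.

# connected components of a symmetric nonzero pattern via union-find
nonzero_components <- function(M) {
  n <- nrow(M)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  idx <- which(M != 0 & row(M) < col(M), arr.ind = TRUE)
  if (nrow(idx)) {
    for (r in seq_len(nrow(idx))) {
      a <- find(idx[r, 1]); b <- find(idx[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

# kernels: list of n x n matrices (the last need not be identity)
make_vc_lik <- function(y, kernels, reml = FALSE, max_block = 20) {
  n <- length(y)
  for (K in kernels) assert_that(all(dim(K) == n), "kernel dimension mismatch")
  pat <- Reduce(`+`, lapply(kernels, function(K) abs(K) > 1e-12))
  blocks <- nonzero_components(pat)
  if (max(lengths(blocks)) > max_block) blocks <- list(seq_len(n))
  kb <- lapply(blocks, function(b) lapply(kernels, function(K) K[b, b, drop = FALSE]))
  yb <- lapply(blocks, function(b) y[b])
  p <- length(kernels)

  env <- new.env()
  env$par <- NULL

  evaluate <- function(l) {
    if (!is.null(env$par) && identical(env$par, l)) return(env$val)
    th <- exp(l)
    logdet <- 0; a_num <- 0; a_den <- 0
    Vi_list <- vector("list", length(blocks))
    ok <- TRUE
    for (i in seq_along(blocks)) {
      Vb <- kb[[i]][[1]] * th[1]
      if (p > 1) for (k in 2:p) Vb <- Vb + kb[[i]][[k]] * th[k]
      ch <- tryCatch(chol(Vb), error = function(e) NULL)
      if (is.null(ch)) { ok <- FALSE; break }
      logdet <- logdet + 2 * sum(log(diag(ch)))
      Vi <- chol2inv(ch)
      Vi_list[[i]] <- Vi
      a_num <- a_num + sum(Vi %*% yb[[i]])
      a_den <- a_den + sum(Vi)
    }
    if (!ok || a_den <= 0) {
      env$par <- l
      env$val <- list(nll = 1e10, grad = rep(0, p), mu = NA_real_)
      return(env$val)
    }
    mu <- a_num / a_den
    quad <- 0
    tr_k <- numeric(p); quad_k <- numeric(p); prof_k <- numeric(p)
    for (i in seq_along(blocks)) {
      r <- yb[[i]] - mu
      Vi <- Vi_list[[i]]
      u <- Vi %*% r
      quad <- quad + sum(r * u)
      w <- rowSums(Vi)                 # Vi %*% 1
      for (k in seq_len(p)) {
        Kk <- kb[[i]][[k]]
        tr_k[k] <- tr_k[k] + sum(Vi * Kk)
        quad_k[k] <- quad_k[k] + sum(u * (Kk %*% u))
        prof_k[k] <- prof_k[k] + sum(w * (Kk %*% w))
      }
    }
    nll <- 0.5 * (logdet + quad + n * log(2 * pi))
    grad <- 0.5 * (tr_k - quad_k) * th
    if (reml) {
      nll <- nll + 0.5 * log(a_den) - 0.5 * log(2 * pi)
      grad <- grad - 0.5 * (prof_k / a_den) * th
    }
    env$par <- l
    env$val <- list(nll = nll, grad = grad, mu = mu)
    env$val
  }

  list(nll = function(l) evaluate(l)$nll,
       grad = function(l) evaluate(l)$grad,
       mu = function(l) evaluate(l)$mu,
       n_blocks = length(blocks))
}

# central-difference Hessian of f at x
num_hessian <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- pmax(1e-5, 1e-4 * (1 + abs(x)))
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xm <- x
        xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpm <- x; xmp <- x; xmm <- x
        xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}
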