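# Independent oracles used across tests: dense Kronecker assembly, dense SVD
# comparisons, closed-form Tikhonov, and brute-force active-set enumeration
# for tiny non-negative least-squares problems.

dense_kron <- function(kern) kronecker(kern$K2, kern$K1)

# Random small separable kernel with well-separated singular values.
random_kernel <- function(M1, N1, M2, N2, seed = 1) {
  set.seed(seed)
  separable_kernel(matrix(rnorm(M1 * N1), M1, N1),
                   matrix(rnorm(M2 * N2), M2, N2))
}

# A small physical IR-CPMG kernel (distinct singular values, realistic decay).
small_ircpmg <- function(M1 = 8, M2 = 7, N1 = 5, N2 = 4) {
  g <- make_grids(M1, M2, c(1e-3, 3), c(1e-3, 1), N1, N2, c(1e-3, 3), c(1e-3, 1))
  build_kernels(g$time, g$relax)
}

# Unconstrained Tikhonov solution of min ||A x - b||^2 + alpha ||x||^2.
tikhonov_closed_form <- function(A, b, alpha) {
  solve(crossprod(A) + alpha * diag(ncol(A)), crossprod(A, b))
}

# Global minimizer of min_{x >= 0} ||A x - b||^2 + alpha ||x||^2 by
# enumerating all 2^n zero patterns (n <= 12).
nnls_bruteforce <- function(A, b, alpha = 0) {
  n <- ncol(A)
  stopifnot(n <= 12)
  best <- NULL; best_val <- Inf
  for (mask in 0:(2^n - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    x <- numeric(n)
    if (length(free) > 0) {
      Af <- A[, free, drop = FALSE]
      xf <- tryCatch(
        solve(crossprod(Af) + alpha * diag(length(free)), crossprod(Af, b)),
        error = function(e) NULL)
      if (is.null(xf) || any(xf < 0)) next
      x[free] <- xf
    }
    val <- sum((A %*% x - b)^2) + alpha * sum(x^2)
    if (val < best_val) { best_val <- val; best <- x }
  }
  list(x = best, value = best_val)
}

# NP solve of the dense problem min_{x>=0} ||A x - b||^2 + alpha ||x||^2.
np_dense <- function(A, b, alpha, cfg = np_config(), x0 = rep(1, ncol(A))) {
  AtA <- crossprod(A); Atb <- crossprod(A, b); bb <- sum(b * b)
  np_solve(
    objective = function(x) sum(x * (AtA %*% x)) - 2 * sum(x * Atb) + bb + alpha * sum(x * x),
    gradient  = function(x) as.numeric(2 * (AtA %*% x - Atb + alpha * x)),
    hess_mul  = function(v) as.numeric(2 * (AtA %*% v + alpha * v)),
    f0 = x0, cfg = cfg)
}
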