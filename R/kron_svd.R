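#' Thin SVDs of the kernel factors
#'
#' Computes the thin singular value decompositions of `K1` and `K2`.  Singular
#' vectors are sign-normalized (largest-magnitude entry of each left singular
#' vector positive) so downstream quantities are reproducible across linear
#' algebra backends.
#'
#' @param kern a [separable_kernel].
#' @return object of class `factor_svds`: lists `f1`, `f2` each with `u`, `d`,
#'   `v` (descending singular values).
#' @export
factor_svds <- function(kern) {
  stopifnot(inherits(kern, "separable_kernel"))
  fix_signs <- function(s) {
    sgn <- apply(s$u, 2, function(col) {
      j <- which.max(abs(col)); if (col[j] < 0) -1 else 1
    })
    s$u <- sweep(s$u, 2, sgn, "*")
    s$v <- sweep(s$v, 2, sgn, "*")
    s
  }
  s1 <- tryCatch(fix_signs(svd(kern$K1)), error = function(e)
    stop("SVD of K1 failed: ", conditionMessage(e), call. = FALSE))
  s2 <- tryCatch(fix_signs(svd(kern$K2)), error = function(e)
    stop("SVD of K2 failed: ", conditionMessage(e), call. = FALSE))
  structure(list(f1 = s1, f2 = s2, kern = kern), class = "factor_svds")
}

#' Descending ordering of the Kronecker spectrum
#'
#' The singular values of the full operator `K2 %x% K1` are all pairwise
#' products of the factor singular values.  This computes them, sorts them in
#' non-increasing order with a stable tie-break (smaller composite
#' column-major index first), and records the permutation between composite
#' (Kronecker) ordering and spectral ordering.
#'
#' @param fs a [factor_svds].
#' @return object of class `spectral_ordering`: `sv` (sorted descending),
#'   `perm` (composite column-major index of each sorted entry, i.e.
#'   `i1 + r1*(i2-1)`), `pairs` (two-column matrix of factor indices
#'   `(i1, i2)`), `r1`, `r2`.
#' @export
spectral_ordering <- function(fs) {
  stopifnot(inherits(fs, "factor_svds"))
  r1 <- length(fs$f1$d); r2 <- length(fs$f2$d)
  prod <- outer(fs$f1$d, fs$f2$d)          # r1 x r2, composite index i1 + r1*(i2-1)
  perm <- order(prod, seq_along(prod), decreasing = c(TRUE, FALSE), method = "radix")
  sv <- as.vector(prod)[perm]
  pairs <- cbind(i1 = ((perm - 1L) %% r1) + 1L, i2 = ((perm - 1L) %/% r1) + 1L)
  structure(list(sv = sv, perm = perm, pairs = pairs, r1 = r1, r2 = r2),
            class = "spectral_ordering")
}

#' @export
print.spectral_ordering <- function(x, ...) {
  cat(sprintf("<spectral_ordering> %d Kronecker singular values in [%.4g, %.4g]\n",
              length(x$sv), min(x$sv), max(x$sv)))
  invisible(x)
}

#' Zero the tail of a vector
#'
#' Keeps the first `k` entries of `x` and sets the rest to zero, the basic
#' truncation primitive of the compressed representation.
#'
#' @param x numeric vector.
#' @param k number of leading entries to keep, `0 <= k <= length(x)`.
#' @return vector of the same length as `x`.
#' @examples
#' zero_tail(c(5, 4, 3), 2)  # 5 4 0
#' @export
zero_tail <- function(x, k) {
  L <- length(x)
  if (!is.finite(k) || k < 0 || k > L) {
    stop(sprintf("k must be in [0, %d], got %s", L, format(k)), call. = FALSE)
  }
  if (k < L) x[(k + 1L):L] <- 0
  x
}

#' Truncated Kronecker-SVD operator
#'
#' Bundles the factor SVDs and the spectral ordering with a truncation index
#' `k`, defining the rank-`k` TSVD of the full operator.  `k` may be given
#' directly or derived from a singular-value threshold `tau`
#' (`k = # { sigma_i >= tau }`).
#'
#' @param kern a [separable_kernel], or a [factor_svds] (to reuse a
#'   factorization).
#' @param k truncation index (count of retained singular values).
#' @param tau alternatively, a positive singular-value threshold.
#' @return object of class `kron_tsvd` with elements `fs`, `so`, `k`.
#' @export
kron_tsvd <- function(kern, k = NULL, tau = NULL) {
  fs <- if (inherits(kern, "factor_svds")) kern else factor_svds(kern)
  so <- spectral_ordering(fs)
  if (is.null(k)) {
    if (is.null(tau)) stop("supply either `k` or `tau`", call. = FALSE)
    k <- select_k_threshold(so, tau)
  }
  k <- as.integer(k)
  if (k < 1L || k > length(so$sv)) {
    stop(sprintf("k must be in [1, %d]", length(so$sv)), call. = FALSE)
  }
  if (so$sv[k] <= 0) stop("retained spectrum must be strictly positive", call. = FALSE)
  structure(list(fs = fs, so = so, k = k), class = "kron_tsvd")
}

#' @export
print.kron_tsvd <- function(x, ...) {
  cat(sprintf("<kron_tsvd> rank %d of %d, sigma_1 = %.4g, sigma_k = %.4g\n",
              x$k, length(x$so$sv), x$so$sv[1], x$so$sv[x$k]))
  invisible(x)
}

#' Compress a data surface into the dominant left singular basis
#'
#' Computes the first `k` spectral coefficients `t(Uk) %*% vec(S)` of the data
#' without forming `Uk`: evaluates `vec(t(U1bar) S U2bar)`, reorders by the
#' descending-spectrum permutation and keeps the leading `k` entries.
#'
#' @param op a [kron_tsvd].
#' @param S a [data_surface] or plain `M1 x M2` matrix.
#' @param k optional override of the operator's truncation index.
#' @return numeric vector of length `k`.
#' @export
compress_data <- function(op, S, k = op$k) {
  stopifnot(inherits(op, "kron_tsvd"))
  Sm <- if (inherits(S, "data_surface")) S$S else S
  fs <- op$fs
  if (!is.matrix(Sm) || nrow(Sm) != nrow(fs$f1$u) || ncol(Sm) != nrow(fs$f2$u)) {
    stop("data surface shape does not match the kernel", call. = FALSE)
  }
  if (k < 0 || k > length(op$so$sv)) stop("k out of range", call. = FALSE)
  coef <- as.vector(crossprod(fs$f1$u, Sm) %*% fs$f2$u)  # r1 x r2, vec'd
  coef[op$so$perm[seq_len(k)]]
}

#' Truncated right-singular-basis products
#'
#' `apply_VkT` computes the first `k` coefficients `t(Vk) %*% vec(F)` of a
#' distribution-shaped matrix; `apply_Vk` is its adjoint, scattering `k`
#' coefficients back to an `N1 x N2` matrix through the inverse permutation.
#'
#' @param op a [kron_tsvd].
#' @param F `N1 x N2` matrix (or [t1t2_dist]).
#' @param coef numeric vector of length at most `k`.
#' @return `apply_VkT`: length-`k` vector; `apply_Vk`: `N1 x N2` matrix.
#' @export
apply_VkT <- function(op, F) {
  stopifnot(inherits(op, "kron_tsvd"))
  Fm <- if (inherits(F, "t1t2_dist")) F$F else F
  fs <- op$fs
  if (!is.matrix(Fm) || nrow(Fm) != nrow(fs$f1$v) || ncol(Fm) != nrow(fs$f2$v)) {
    stop("distribution shape does not match the kernel", call. = FALSE)
  }
  coef <- as.vector(crossprod(fs$f1$v, Fm) %*% fs$f2$v)
  coef[op$so$perm[seq_len(op$k)]]
}

#' @rdname apply_VkT
#' @export
apply_Vk <- function(op, coef) {
  stopifnot(inherits(op, "kron_tsvd"))
  if (length(coef) > op$k) stop("coefficient vector longer than truncation index", call. = FALSE)
  fs <- op$fs
  z <- numeric(op$so$r1 * op$so$r2)
  z[op$so$perm[seq_along(coef)]] <- coef
  C <- matrix(z, op$so$r1, op$so$r2)
  fs$f1$v %*% C %*% t(fs$f2$v)
}
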