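#' Active-set indicator of a non-negative solution
#'
#' Coordinates at zero (within `tol`) form the active set of the
#' non-negativity constraint; the complementary indicator is the diagonal
#' matrix `D*` entering the filtered representation of constrained
#' solutions.  Returned as the indicator values themselves (the diagonal),
#' shaped like the input.
#'
#' @param F a [t1t2_dist] or non-negative matrix/vector.
#' @param tol absolute threshold below which a coordinate counts as active;
#'   default `1e-8 * max(F)`.
#' @return numeric 0/1 object of the same shape as the input, class
#'   `active_set`.
#' @export
active_set <- function(F, tol = NULL) {
  Fm <- if (inherits(F, "t1t2_dist")) F$F else F
  if (any(Fm < 0)) stop("solution must be non-negative", call. = FALSE)
  if (is.null(tol)) tol <- 1e-8 * max(Fm, 0)
  D <- (Fm > tol) * 1
  class(D) <- c("active_set", class(D))
  D
}

#' Spectral filter factors of the inversion methods
#'
#' Each regularized solution can be written as
#' `sum_i phi_i (u_i' s / sigma_i) D* v_i` with method-specific factors
#' `phi_i` over the sorted composite spectrum:
#' TSVD keeps `phi = 1` up to `k`; Tikhonov applies
#' `sigma^2 / (sigma^2 + alpha)` everywhere; the hybrid applies the Tikhonov
#' factor up to `k` and zero beyond, combining the sharp cut-off with the
#' smooth roll-off.  (For the VSH factors, which live on a non-contiguous
#' index set, see [vsh_filter_factors()].)
#'
#' @param method one of `"tsvd"`, `"tikhonov"`, `"hybrid"`.
#' @param so a [spectral_ordering] (or [kron_tsvd]).
#' @param k truncation index (tsvd, hybrid).
#' @param alpha positive regularization parameter (tikhonov, hybrid).
#' @return tibble of class `filter_spec` with columns `i`, `sigma`, `phi`
#'   and attributes `method`, `k`, `alpha`.
#' @export
filter_factors <- function(method = c("tsvd", "tikhonov", "hybrid"), so,
                           k = NULL, alpha = NULL) {
  method <- match.arg(method)
  if (inherits(so, "kron_tsvd")) { if (is.null(k)) k <- so$k; so <- so$so }
  stopifnot(inherits(so, "spectral_ordering"))
  n <- length(so$sv)
  if (method %in% c("tsvd", "hybrid")) {
    if (is.null(k) || k < 1 || k > n) stop("valid `k` required", call. = FALSE)
  }
  if (method %in% c("tikhonov", "hybrid")) {
    if (is.null(alpha) || !is.finite(alpha) || alpha <= 0) {
      stop("positive `alpha` required", call. = FALSE)
    }
  }
  phi <- switch(method,
    tsvd     = as.numeric(seq_len(n) <= k),
    tikhonov = so$sv^2 / (so$sv^2 + alpha),
    hybrid   = ifelse(seq_len(n) <= k, so$sv^2 / (so$sv^2 + alpha), 0)
  )
  out <- tibble::tibble(i = seq_len(n), sigma = so$sv, phi = phi)
  attr(out, "method") <- method
  attr(out, "k") <- k
  attr(out, "alpha") <- alpha
  class(out) <- c("filter_spec", class(out))
  out
}

#' Filtered spectral representation of a constrained solution
#'
#' Assembles `sum_i phi_i (u_i' s / sigma_i) D* v_i` with fast Kronecker
#' products: the spectral data coefficients are filtered, mapped back
#' through the right singular basis, and masked by the active-set diagonal.
#' This is a post-hoc diagnostic — `D*` is only known after a solver has
#' produced the solution it characterizes — never the production solve path.
#'
#' @param fspec a `filter_spec` from [filter_factors()] (or a tibble with
#'   columns `i`, `phi`).
#' @param D an [active_set()] indicator (`N1 x N2`), or `NULL` for the
#'   unconstrained representation.
#' @param op a [kron_tsvd] of the same kernel (provides the bases; its own
#'   `k` is ignored).
#' @param S a [data_surface] or matrix.
#' @param F_ref optional solver output ([t1t2_dist] or matrix) to compare
#'   against; adds the relative discrepancy as attribute `"rel_discrepancy"`.
#' @return `N1 x N2` matrix (may contain negative entries only where `D`
#'   masks none and the filtered sum does).
#' @export
filtered_representation <- function(fspec, D, op, S, F_ref = NULL) {
  stopifnot(inherits(op, "kron_tsvd"))
  n <- length(op$so$sv)
  phi <- numeric(n)
  phi[fspec$i] <- fspec$phi
  keep <- which(phi != 0)
  if (length(keep) > 0 && any(op$so$sv[keep] <= 0)) {
    stop("filter retains components with zero singular value", call. = FALSE)
  }
  coef_all <- compress_data(op, S, k = n)
  w <- numeric(n)
  w[keep] <- phi[keep] * coef_all[keep] / op$so$sv[keep]
  z <- numeric(op$so$r1 * op$so$r2)
  z[op$so$perm] <- w
  Fm <- op$fs$f1$v %*% matrix(z, op$so$r1, op$so$r2) %*% t(op$fs$f2$v)
  if (!is.null(D)) {
    Dm <- unclass(D)
    if (!all(dim(Dm) == dim(Fm))) stop("active-set indicator shape mismatch", call. = FALSE)
    Fm <- Fm * Dm
  }
  if (!is.null(F_ref)) {
    Rm <- if (inherits(F_ref, "t1t2_dist")) F_ref$F else F_ref
    attr(Fm, "rel_discrepancy") <- norm(Fm - Rm, "F") / max(norm(Rm, "F"), .Machine$double.xmin)
  }
  Fm
}

#' Numerical check of the masked pseudo-inverse identity
#'
#' For `K = U S V'` and a 0/1 diagonal `D`, compares the Moore-Penrose
#' pseudo-inverse of `K %*% D` with `D %*% V %*% S^+ %*% U'` on a dense
#' instance and reports the relative discrepancy.  The identity underlies
#' the filtered representation of constrained solutions; it holds in the
#' active-set context but not for arbitrary masks, so this is exposed as a
#' diagnostic rather than asserted.
#'
#' @param K dense matrix.
#' @param d 0/1 vector, the diagonal of `D` (length `ncol(K)`).
#' @param tol rank tolerance passed to the pseudo-inverse.
#' @return relative Frobenius discrepancy (scalar).
#' @export
pinv_identity_check <- function(K, d, tol = 1e-10) {
  stopifnot(is.matrix(K), length(d) == ncol(K), all(d %in% c(0, 1)))
  pinv <- function(A) {
    s <- svd(A)
    pos <- s$d > tol * max(s$d, tol)
    if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
    s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
  lhs <- pinv(K %*% diag(d))
  rhs <- diag(d) %*% pinv(K)
  norm(lhs - rhs, "F") / max(norm(rhs, "F"), .Machine$double.xmin)
}
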