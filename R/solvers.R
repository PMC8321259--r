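new_solve_result <- function(F, rg, method, alpha, k, np, residual,
                             extra = list()) {
  structure(c(list(F = t1t2_dist(F, rg), method = method, alpha = alpha,
                   k = k, objective = np$objective, np_iters = np$np_iters,
                   cg_iters = np$cg_iters, converged = np$converged,
                   residual = residual), extra),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("<solve_result> method %s, alpha = %.4g%s\n", x$method, x$alpha,
              if (!is.null(x$k)) sprintf(", k = %d", x$k) else ""))
  cat(sprintf("  %d NP iterations (%d CG), %sconverged, |Kf - s| = %.4g\n",
              x$np_iters, x$cg_iters, if (x$converged) "" else "NOT ", x$residual))
  invisible(x)
}

#' Hybrid TSVD-Tikhonov inversion
#'
#' Solves the compressed non-negative Tikhonov problem
#' \deqn{\min_{f \ge 0} \|\Sigma_k V_k^T f - U_k^T s\|^2 + \alpha \|f\|^2}
#' by the Newton Projection method.  The data is first projected onto the
#' `k` dominant left singular vectors of the composite operator, so all inner
#' work is `O(N)` per product and independent of the (large) data size.
#' The initial iterate is the constant all-ones distribution.
#'
#' @param op a [kron_tsvd] defining the truncation.
#' @param S a [data_surface] or matrix.
#' @param alpha positive Tikhonov parameter.  The default ties it to the
#'   truncation as `sigma_k^2` (see [alpha_from_k()]).
#' @param cfg an [np_config].
#' @param f0 optional starting distribution (matrix), default all ones.
#' @return a `solve_result`: the recovered [t1t2_dist] plus solver
#'   diagnostics (objective trace, iteration counts, residual norm,
#'   convergence flag, `alpha`, `k`).
#' @export
solve_hybrid <- function(op, S, alpha = alpha_from_k(op, op$k),
                         cfg = np_config(), f0 = NULL) {
  stopifnot(inherits(op, "kron_tsvd"))
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive", call. = FALSE)
  b <- compress_data(op, S)
  sig <- op$so$sv[seq_len(op$k)]
  N1 <- nrow(op$fs$f1$v); N2 <- nrow(op$fs$f2$v)
  dm <- c(N1, N2)
  vkT <- function(fv) {
    co <- as.vector(crossprod(op$fs$f1$v, matrix(fv, dm[1], dm[2])) %*% op$fs$f2$v)
    co[op$so$perm[seq_len(op$k)]]
  }
  vk <- function(coef) {
    z <- numeric(op$so$r1 * op$so$r2)
    z[op$so$perm[seq_len(op$k)]] <- coef
    as.vector(op$fs$f1$v %*% matrix(z, op$so$r1, op$so$r2) %*% t(op$fs$f2$v))
  }
  objective <- function(fv) { r <- sig * vkT(fv) - b; sum(r * r) + alpha * sum(fv * fv) }
  gradient  <- function(fv) 2 * (vk(sig * (sig * vkT(fv) - b)) + alpha * fv)
  hess_mul  <- function(v)  2 * (vk(sig^2 * vkT(v)) + alpha * v)
  start <- if (is.null(f0)) rep(1, N1 * N2) else as.numeric(f0)
  np <- np_solve(objective, gradient, hess_mul, start, cfg)
  Fm <- matrix(np$f, N1, N2)
  res <- norm(forward(op$fs$kern, Fm) - (if (inherits(S, "data_surface")) S$S else S), "F")
  rg <- op$fs$kern$rg
  new_solve_result(Fm, rg, "hybrid", alpha, op$k, np, res)
}

#' Full-space non-negative Tikhonov inversion
#'
#' Solves \deqn{\min_{f \ge 0} \|K f - s\|^2 + \alpha \|f\|^2} on the
#' untruncated operator.  The Kronecker structure is exploited throughout:
#' the normal-equations matrices `t(K1) K1` and `t(K2) K2` (each only
#' `N x N`) are formed once, after which every objective, gradient and
#' Hessian evaluation is independent of the data size.
#'
#' @param kern a [separable_kernel].
#' @inheritParams solve_hybrid
#' @return a `solve_result` (with `k = NULL`).
#' @export
solve_tikhonov <- function(kern, S, alpha, cfg = np_config(), f0 = NULL) {
  stopifnot(inherits(kern, "separable_kernel"))
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive", call. = FALSE)
  Sm <- if (inherits(S, "data_surface")) S$S else S
  if (nrow(Sm) != nrow(kern$K1) || ncol(Sm) != nrow(kern$K2)) {
    stop("data surface shape does not match the kernel", call. = FALSE)
  }
  G1 <- crossprod(kern$K1); G2 <- crossprod(kern$K2)
  Kts <- crossprod(kern$K1, Sm) %*% kern$K2
  s2 <- sum(Sm * Sm)
  N1 <- ncol(kern$K1); N2 <- ncol(kern$K2)
  objective <- function(fv) {
    Fm <- matrix(fv, N1, N2)
    sum(Fm * (G1 %*% Fm %*% G2)) - 2 * sum(Fm * Kts) + s2 + alpha * sum(fv * fv)
  }
  gradient <- function(fv) {
    Fm <- matrix(fv, N1, N2)
    as.vector(2 * (G1 %*% Fm %*% G2 - Kts + alpha * Fm))
  }
  hess_mul <- function(v) {
    Vm <- matrix(v, N1, N2)
    as.vector(2 * (G1 %*% Vm %*% G2 + alpha * Vm))
  }
  start <- if (is.null(f0)) rep(1, N1 * N2) else as.numeric(f0)
  np <- np_solve(objective, gradient, hess_mul, start, cfg)
  Fm <- matrix(np$f, N1, N2)
  res <- norm(forward(kern, Fm) - Sm, "F")
  new_solve_result(Fm, kern$rg, "tikhonov", alpha, NULL, np, res)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a solve result into per-node rows
#'
#' @param x a `solve_result`.
#' @param ... unused.
#' @return tibble with columns `T1`, `T2` (seconds; `NA` if the kernel grids
#'   are unknown) and `amplitude`.
#' @export
tidy.solve_result <- function(x, ...) {
  Fm <- x$F$F
  rg <- x$F$rg
  T1 <- if (!is.null(rg)) rg$T1 else rep(NA_real_, nrow(Fm))
  T2 <- if (!is.null(rg)) rg$T2 else rep(NA_real_, ncol(Fm))
  tibble::tibble(T1 = rep(T1, times = ncol(Fm)),
                 T2 = rep(T2, each = nrow(Fm)),
                 amplitude = as.vector(Fm))
}

#' One-row summary of a solve result
#'
#' @param x a `solve_result`.
#' @param ... unused.
#' @return one-row tibble with method, parameters, iteration counts,
#'   final objective and residual norm.
#' @export
glance.solve_result <- function(x, ...) {
  tibble::tibble(method = x$method, alpha = x$alpha,
                 k = if (is.null(x$k)) NA_integer_ else x$k,
                 np_iters = x$np_iters, cg_iters = x$cg_iters,
                 converged = x$converged,
                 objective = x$objective[length(x$objective)],
                 residual = x$residual)
}
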