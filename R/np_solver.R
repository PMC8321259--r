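#' Newton Projection solver configuration
#'
#' Tolerances and caps for the bound-constrained Newton Projection (NP)
#' method with conjugate-gradient (CG) inner solves.
#'
#' @param tol_np stop when the relative objective decrease between accepted
#'   iterates falls below this value (default `1e-3`).
#' @param tol_cg CG relative residual tolerance (default `1e-7`).
#' @param kmax_np maximum NP iterations (default 500).
#' @param kmax_cg maximum CG iterations per Newton system (default `1e4`).
#' @param eps_active active-set threshold; coordinates with
#'   `f_i <= eps_active` and positive gradient are treated as active.  The
#'   default `NULL` uses the machine-scaled rule
#'   `min(1e-9 * max(f), sqrt(.Machine$double.eps))`.
#' @param armijo_c sufficient-decrease fraction of the linearized model
#'   (default `1e-4`).
#' @param backtrack step-length reduction factor (default 0.5).
#' @param max_backtracks maximum backtracking steps per iteration (default 40).
#' @return a list of class `np_config`.
#' @export
np_config <- function(tol_np = 1e-3, tol_cg = 1e-7, kmax_np = 500L,
                      kmax_cg = 1e4, eps_active = NULL,
                      armijo_c = 1e-4, backtrack = 0.5, max_backtracks = 40L) {
  stopifnot(tol_np > 0, tol_cg > 0, kmax_np >= 1, kmax_cg >= 1,
            armijo_c > 0, armijo_c < 1, backtrack > 0, backtrack < 1)
  structure(list(tol_np = tol_np, tol_cg = tol_cg,
                 kmax_np = as.integer(kmax_np), kmax_cg = kmax_cg,
                 eps_active = eps_active, armijo_c = armijo_c,
                 backtrack = backtrack, max_backtracks = as.integer(max_backtracks)),
            class = "np_config")
}

# Conjugate gradients for H d = rhs restricted to the inactive coordinates.
# `hess_mul` applies the full Hessian; active coordinates are masked in both
# input and output so the system is the principal submatrix on the inactive
# block.  Returns the direction and the iteration count.
cg_masked <- function(hess_mul, rhs, active, tol, maxit) {
  d <- numeric(length(rhs))
  r <- rhs
  r[active] <- 0
  rs0 <- sum(r * r)
  if (rs0 == 0) return(list(d = d, iters = 0L, ok = TRUE))
  p <- r
  rs <- rs0
  it <- 0L
  ok <- TRUE
  while (it < maxit && sqrt(rs) > tol * sqrt(rs0)) {
    Hp <- hess_mul(p)
    Hp[active] <- 0
    pHp <- sum(p * Hp)
    if (!is.finite(pHp) || pHp <= 0) { ok <- FALSE; break }  # breakdown
    a <- rs / pHp
    d <- d + a * p
    r <- r - a * Hp
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    it <- it + 1L
  }
  list(d = d, iters = it, ok = ok)
}

#' Newton Projection method for non-negative quadratic programs
#'
#' Minimizes a smooth convex objective over the non-negative orthant by the
#' active-set Newton Projection method: coordinates at (or numerically at)
#' zero with positive gradient form the active set and move along the
#' projected negative gradient; the Newton system on the inactive block is
#' solved by conjugate gradients; the combined direction is globalized by a
#' projected Armijo backtracking line search.  Iterations stop when the
#' relative objective decrease drops below `cfg$tol_np` or a cap is hit.
#'
#' This is the computational core shared by [solve_hybrid()],
#' [solve_tikhonov()] and [vsh_solve()]; it operates on plain numeric
#' vectors through closures.
#'
#' @param objective function of `f` returning the scalar objective.
#' @param gradient function of `f` returning the gradient vector.
#' @param hess_mul function applying the (constant) Hessian to a vector.
#' @param f0 starting point (non-negative).
#' @param cfg an [np_config].
#' @return list with `f` (solution), `objective` (trace of accepted values,
#'   including the initial one), `np_iters`, `cg_iters`, `converged`,
#'   `cg_fallbacks` (count of CG breakdowns handled by projected-gradient
#'   steps).
#' @export
np_solve <- function(objective, gradient, hess_mul, f0, cfg = np_config()) {
  f <- as.numeric(f0)
  if (any(f < 0)) stop("starting point must be non-negative", call. = FALSE)
  obj <- objective(f)
  if (!is.finite(obj)) stop("objective is not finite at the starting point", call. = FALSE)
  trace <- obj
  cg_total <- 0L
  fallbacks <- 0L
  converged <- FALSE
  it <- 0L
  while (it < cfg$kmax_np) {
    it <- it + 1L
    g <- gradient(f)
    eps <- if (is.null(cfg$eps_active)) {
      min(1e-9 * max(f, 0), sqrt(.Machine$double.eps))
    } else cfg$eps_active
    active <- (f <= eps) & (g > 0)
    cg <- cg_masked(hess_mul, -g, active, cfg$tol_cg, cfg$kmax_cg)
    cg_total <- cg_total + cg$iters
    dir <- cg$d
    if (!cg$ok) {                       # fall back to projected gradient
      fallbacks <- fallbacks + 1L
      dir <- -g
      dir[active] <- 0
    }
    dir[active] <- -g[active]
    lam <- 1
    f_new <- f
    obj_new <- obj
    accepted <- FALSE
    for (bt in seq_len(cfg$max_backtracks)) {
      cand <- pmax(f + lam * dir, 0)
      val <- objective(cand)
      if (is.finite(val) && val <= obj + cfg$armijo_c * sum(g * (cand - f))) {
        f_new <- cand; obj_new <- val; accepted <- TRUE
        break
      }
      lam <- lam * cfg$backtrack
    }
    if (!is.finite(obj_new)) stop("objective became non-finite during NP iteration", call. = FALSE)
    if (!accepted) { converged <- TRUE; break }  # no progress possible: stationary
    rel <- abs(obj_new - obj) / max(abs(obj_new), .Machine$double.xmin)
    f <- f_new
    obj <- obj_new
    trace <- c(trace, obj)
    if (rel < cfg$tol_np) { converged <- TRUE; break }
  }
  list(f = f, objective = trace, np_iters = it, cg_iters = cg_total,
       converged = converged, cg_fallbacks = fallbacks)
}

#' Coordinatewise KKT residual of a non-negative minimizer
#'
#' For the problem `min f >= 0` of a smooth objective, first-order optimality
#' requires `min(f_i, g_i) = 0` for every coordinate (positive coordinates
#' have zero gradient; zero coordinates have non-negative gradient).  Returns
#' the maximum absolute violation.
#'
#' @param f solution vector (or matrix).
#' @param g gradient at `f`.
#' @return non-negative scalar.
#' @export
kkt_residual <- function(f, g) {
  max(abs(pmin(as.numeric(f), as.numeric(g))))
}
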