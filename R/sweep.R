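#' Parameter sweep over inversion methods
#'
#' Runs each requested (method, parameter) cell on the same data realization
#' and collects relative errors and solver effort, mirroring the usual
#' models-comparison experiment: for `"hybrid"` and `"vsh"` the truncation is
#' fixed by `tau` while `alpha` varies; `"tikhonov"` ignores `tau`.
#'
#' @param kern a [separable_kernel].
#' @param S a [data_surface] or matrix (one fixed noisy realization).
#' @param F_true optional ground truth for the error column.
#' @param methods subset of `c("hybrid", "tikhonov", "vsh")`.
#' @param alphas numeric vector of regularization parameters.
#' @param tau composite-spectrum threshold for the hybrid (also used for both
#'   VSH factors), default 1.
#' @param cfg an [np_config] for all solvers.
#' @param tikhonov_kmax optional NP-iteration cap override for the full-space
#'   Tikhonov cells.
#' @return tibble with one row per cell: `method`, `alpha`, `tau`, `k`,
#'   `err`, `np_iters`, `cg_iters`, `converged`, `seconds`, `failed`.
#' @export
run_sweep <- function(kern, S, F_true = NULL,
                      methods = c("hybrid", "tikhonov", "vsh"),
                      alphas = 10^seq(2, -4, length.out = 10),
                      tau = 1, cfg = np_config(), tikhonov_kmax = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(length(alphas) >= 1)
  fs <- factor_svds(kern)
  op <- if ("hybrid" %in% methods) kron_tsvd(fs, tau = tau) else NULL
  cfg_t <- cfg
  if (!is.null(tikhonov_kmax)) cfg_t$kmax_np <- as.integer(tikhonov_kmax)
  rows <- list()
  for (m in methods) for (a in alphas) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      switch(m,
        hybrid   = solve_hybrid(op, S, alpha = a, cfg = cfg),
        tikhonov = solve_tikhonov(kern, S, alpha = a, cfg = cfg_t),
        vsh      = vsh_solve(fs, S, cfg = vsh_config(tau1 = tau, tau2 = tau, inner = cfg),
                             mode = "model", alpha = a)
      ),
      error = function(e) e
    )
    secs <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = m, alpha = a, tau = tau, k = NA_integer_, err = NA_real_,
        np_iters = NA_integer_, cg_iters = NA_integer_, converged = FALSE,
        seconds = secs, failed = TRUE)
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      method = m, alpha = a, tau = tau,
      k = if (!is.null(res$k)) res$k else NA_integer_,
      err = if (!is.null(F_true)) relative_error(F_true, res) else NA_real_,
      np_iters = res$np_iters, cg_iters = res$cg_iters,
      converged = res$converged, seconds = secs, failed = FALSE)
  }
  dplyr::bind_rows(rows)
}
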