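#' Relative reconstruction error
#'
#' Frobenius-norm ratio `||F_true - F_est|| / ||F_true||`.
#'
#' @param F_true,F_est distributions ([t1t2_dist] or matrices) of equal shape.
#' @return non-negative scalar.
#' @export
relative_error <- function(F_true, F_est) {
  A <- if (inherits(F_true, "t1t2_dist")) F_true$F else F_true
  B <- if (inherits(F_est, "solve_result")) F_est$F$F
       else if (inherits(F_est, "t1t2_dist")) F_est$F else F_est
  if (!all(dim(A) == dim(B))) stop("distributions must have equal shape", call. = FALSE)
  nA <- norm(A, "F")
  if (nA == 0) stop("reference distribution is identically zero", call. = FALSE)
  norm(A - B, "F") / nA
}

#' Marginal projections of a distribution
#'
#' Sums the map over each axis: the `T1` profile sums over `T2` (row sums)
#' and vice versa.  Both profiles conserve the total mass of the map.
#'
#' @param F a [t1t2_dist] or matrix.
#' @return list with numeric vectors `T1` (length `N1`) and `T2`
#'   (length `N2`).
#' @export
projections <- function(F) {
  Fm <- if (inherits(F, "t1t2_dist")) F$F else F
  list(T1 = rowSums(Fm), T2 = colSums(Fm))
}

#' Local-maximum peak report
#'
#' Finds grid nodes that strictly dominate their 8-neighborhood and exceed
#' `floor * max(F)`, reported in descending height order with locations in
#' milliseconds.
#'
#' @param F a [t1t2_dist] (grid required for ms coordinates) or matrix.
#' @param floor prominence floor as a fraction of the global maximum
#'   (default 0.05).
#' @return tibble with columns `T2_ms`, `T1_ms` (grid nodes; `NA` without a
#'   grid), `height`, `i1`, `i2`.  Empty for an all-zero map.
#' @export
peak_report <- function(F, floor = 0.05) {
  Fm <- if (inherits(F, "t1t2_dist")) F$F else F
  rg <- if (inherits(F, "t1t2_dist")) F$rg else NULL
  if (any(Fm < 0)) stop("distribution must be non-negative", call. = FALSE)
  mx <- max(Fm)
  empty <- tibble::tibble(T2_ms = numeric(), T1_ms = numeric(),
                          height = numeric(), i1 = integer(), i2 = integer())
  if (mx == 0) return(empty)
  n1 <- nrow(Fm); n2 <- ncol(Fm)
  pad <- matrix(-Inf, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- Fm
  is_peak <- matrix(TRUE, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2:(n1 + 1)) + di, (2:(n2 + 1)) + dj]
    is_peak <- is_peak & (Fm > nb)
  }
  is_peak <- is_peak & (Fm >= floor * mx)
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  out <- tibble::tibble(
    T2_ms = if (!is.null(rg)) rg$T2[idx[, 2]] * 1000 else rep(NA_real_, nrow(idx)),
    T1_ms = if (!is.null(rg)) rg$T1[idx[, 1]] * 1000 else rep(NA_real_, nrow(idx)),
    height = Fm[idx],
    i1 = as.integer(idx[, 1]), i2 = as.integer(idx[, 2])
  )
  dplyr::arrange(out, dplyr::desc(.data$height))
}
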