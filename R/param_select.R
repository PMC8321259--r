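#' Picard-plot data
#'
#' Pairs the leading singular values of the composite operator with the
#' magnitudes of the spectral data coefficients `|u_i' s|` and the implied
#' solution coefficients `|u_i' s| / sigma_i`.  The discrete Picard condition
#' (DPC) holds over the range where the data coefficients decay faster, on
#' average, than the singular values; plotting these three sequences against
#' the index is the classical visual tool for choosing the truncation index.
#'
#' @param op a [kron_tsvd] (its `k` is ignored here).
#' @param S a [data_surface] or matrix.
#' @param n_terms number of leading spectral terms to tabulate.
#' @return a tibble of class `picard_data` with columns `i`, `sigma`,
#'   `fourier` (`|u_i' s|`) and `ratio` (`|u_i' s| / sigma_i`).
#' @export
picard_data <- function(op, S, n_terms = min(500L, length(op$so$sv))) {
  stopifnot(inherits(op, "kron_tsvd"))
  n_terms <- as.integer(n_terms)
  if (n_terms < 1L || n_terms > length(op$so$sv)) {
    stop("n_terms must be within the spectrum length", call. = FALSE)
  }
  co <- abs(compress_data(op, S, k = n_terms))
  sv <- op$so$sv[seq_len(n_terms)]
  out <- tibble::tibble(i = seq_len(n_terms), sigma = sv, fourier = co,
                        ratio = co / sv)
  class(out) <- c("picard_data", class(out))
  out
}

#' Truncation index from a singular-value threshold
#'
#' @param so a [spectral_ordering] (or [kron_tsvd]).
#' @param tau positive threshold; the truncation keeps all singular values
#'   `>= tau` (ties at the threshold are retained).
#' @return integer `k`.
#' @export
select_k_threshold <- function(so, tau) {
  if (inherits(so, "kron_tsvd")) so <- so$so
  stopifnot(inherits(so, "spectral_ordering"))
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  k <- sum(so$sv >= tau)
  if (k == 0L) stop("tau exceeds the largest singular value: empty truncation", call. = FALSE)
  as.integer(k)
}

#' Automatic truncation index from the discrete Picard condition
#'
#' A simple, documented heuristic: smooth the solution coefficients
#' `|u_i' s| / sigma_i` with a trailing moving geometric mean of width
#' `window`, and return the largest index `k` such that the smoothed sequence
#' is non-increasing up to `k`.  Once noise dominates, the data coefficients
#' flatten while the singular values keep decaying, so the smoothed ratio
#' turns upward; the turning point is the DPC break.
#'
#' @param pd a [picard_data] tibble.
#' @param window moving-window width (>= 1), default 5.
#' @return integer truncation index `k >= 1`.
#' @export
select_k_dpc <- function(pd, window = 5L) {
  stopifnot(inherits(pd, "picard_data"))
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  r <- pd$ratio
  if (all(r == 0)) stop("all spectral coefficients are zero; DPC selection is undefined", call. = FALSE)
  lr <- log(pmax(r, .Machine$double.xmin))
  n <- length(lr)
  cs <- cumsum(lr)
  m <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - as.integer(window) + 1L)
    m[i] <- (cs[i] - if (j > 1L) cs[j - 1L] else 0) / (i - j + 1L)
  }
  up <- which(diff(m) > 0)
  if (length(up) == 0L) return(as.integer(n))
  as.integer(up[1])
}

#' Tikhonov parameter from the truncation index
#'
#' The regularization parameter is tied to the spectrum as `alpha = sigma_k^2`:
#' the Tikhonov filter factor at `sigma_k` is then exactly one half, so the
#' penalty takes over precisely where the truncation ends.
#'
#' @param so a [spectral_ordering] (or [kron_tsvd]).
#' @param k truncation index.
#' @return positive scalar `alpha`.
#' @export
alpha_from_k <- function(so, k) {
  if (inherits(so, "kron_tsvd")) so <- so$so
  stopifnot(inherits(so, "spectral_ordering"))
  if (!is.finite(k) || k < 1 || k > length(so$sv)) stop("k out of range", call. = FALSE)
  s <- so$sv[as.integer(k)]
  if (s <= 0) stop("sigma_k must be positive", call. = FALSE)
  s^2
}
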