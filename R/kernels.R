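#' Separable IR-CPMG kernel
#'
#' Discretizes the Laplace-type kernels of the IR-CPMG experiment on the
#' given grids:
#' \deqn{K_1[i,j] = 1 - 2\exp(-t_1[i]/T_1[j]), \qquad
#'       K_2[i,j] = \exp(-t_2[i]/T_2[j]).}
#' The full forward operator is the Kronecker product `K2 %x% K1`, which is
#' never materialized; see [forward()].
#'
#' @param tg a [time_grid].
#' @param rg a [relax_grid].
#' @return an object of class `separable_kernel` with matrices `K1`
#'   (`M1 x N1`), `K2` (`M2 x N2`), the grids, and kernel kind labels.
#' @examples
#' g <- make_grids(4, 4, c(1e-3, 3), c(1e-3, 1), 3, 3, c(1e-3, 3), c(1e-3, 1))
#' kern <- build_kernels(g$time, g$relax)
#' @export
build_kernels <- function(tg, rg) {
  stopifnot(inherits(tg, "time_grid"), inherits(rg, "relax_grid"))
  K1 <- 1 - 2 * exp(-outer(tg$t1, 1 / rg$T1))
  K2 <- exp(-outer(tg$t2, 1 / rg$T2))
  separable_kernel(K1, K2, tg = tg, rg = rg, kinds = c("IR", "CPMG"))
}

#' Assemble a separable kernel from factor matrices
#'
#' Lower-level constructor accepting arbitrary user-supplied factor matrices
#' `K1` (`M1 x N1`) and `K2` (`M2 x N2`); the implied operator is
#' `K2 %x% K1` acting on `vec(F)` (column-major).
#'
#' @param K1,K2 numeric factor matrices.
#' @param tg,rg optional generating grids.
#' @param kinds length-2 character labels.
#' @return a `separable_kernel`.
#' @export
separable_kernel <- function(K1, K2, tg = NULL, rg = NULL,
                             kinds = c("custom", "custom")) {
  if (!is.matrix(K1) || !is.matrix(K2) || !all(is.finite(K1)) || !all(is.finite(K2))) {
    stop("K1 and K2 must be finite numeric matrices", call. = FALSE)
  }
  structure(list(K1 = K1, K2 = K2, tg = tg, rg = rg, kinds = kinds),
            class = "separable_kernel")
}

#' @export
print.separable_kernel <- function(x, ...) {
  cat(sprintf("<separable_kernel> K1 (%s): %d x %d; K2 (%s): %d x %d; operator %d x %d\n",
              x$kinds[1], nrow(x$K1), ncol(x$K1), x$kinds[2], nrow(x$K2), ncol(x$K2),
              nrow(x$K1) * nrow(x$K2), ncol(x$K1) * ncol(x$K2)))
  invisible(x)
}

#' Relaxation-time distribution container
#'
#' A non-negative `N1 x N2` amplitude map over a [relax_grid]; row `i` indexes
#' `T1[i]`, column `j` indexes `T2[j]`.
#'
#' @param F non-negative finite numeric matrix.
#' @param rg the generating [relax_grid] (optional but required by plotting
#'   and peak reporting).
#' @return object of class `t1t2_dist`.
#' @export
t1t2_dist <- function(F, rg = NULL) {
  if (!is.matrix(F) || !all(is.finite(F))) stop("F must be a finite matrix", call. = FALSE)
  if (any(F < 0)) stop("distribution amplitudes must be non-negative", call. = FALSE)
  if (!is.null(rg)) {
    stopifnot(inherits(rg, "relax_grid"),
              nrow(F) == length(rg$T1), ncol(F) == length(rg$T2))
  }
  structure(list(F = F, rg = rg), class = "t1t2_dist")
}

#' @export
print.t1t2_dist <- function(x, ...) {
  cat(sprintf("<t1t2_dist> %d x %d map, total mass %.4g, max %.4g\n",
              nrow(x$F), ncol(x$F), sum(x$F), max(x$F)))
  invisible(x)
}

#' Measured / simulated decay surface
#'
#' The `M1 x M2` signal matrix of an IR-CPMG acquisition; row `i` indexes
#' inversion time `t1[i]`, column `j` echo time `t2[j]`.  Entries may be
#' negative (inverted magnetization at short `t1`).
#'
#' @param S finite numeric matrix.
#' @param tg the generating [time_grid] (optional).
#' @param noise_sd known noise standard deviation, if any.
#' @param snr_db realized signal-to-noise ratio in dB, if known.
#' @return object of class `data_surface`.
#' @export
data_surface <- function(S, tg = NULL, noise_sd = NULL, snr_db = NULL) {
  if (!is.matrix(S) || !all(is.finite(S))) stop("S must be a finite matrix", call. = FALSE)
  if (!is.null(tg)) {
    stopifnot(inherits(tg, "time_grid"),
              nrow(S) == length(tg$t1), ncol(S) == length(tg$t2))
  }
  structure(list(S = S, tg = tg, noise_sd = noise_sd, snr_db = snr_db),
            class = "data_surface")
}

#' @export
print.data_surface <- function(x, ...) {
  cat(sprintf("<data_surface> %d x %d, |S|_F = %.4g%s\n",
              nrow(x$S), ncol(x$S), norm(x$S, "F"),
              if (!is.null(x$snr_db)) sprintf(", SNR %.2f dB", x$snr_db) else ""))
  invisible(x)
}

#' Forward model without materializing the Kronecker operator
#'
#' Applies the separable operator to a distribution using the identity
#' `(A %x% B) vec(X) = vec(B X t(A))`, i.e. returns `K1 F t(K2)`, the clean
#' `M1 x M2` decay surface.
#'
#' @param kern a [separable_kernel].
#' @param F a [t1t2_dist] or plain `N1 x N2` matrix.
#' @return `M1 x M2` numeric matrix.
#' @export
forward <- function(kern, F) {
  stopifnot(inherits(kern, "separable_kernel"))
  Fm <- if (inherits(F, "t1t2_dist")) F$F else F
  if (!is.matrix(Fm) || nrow(Fm) != ncol(kern$K1) || ncol(Fm) != ncol(kern$K2)) {
    stop(sprintf("distribution must be %d x %d to match the kernel",
                 ncol(kern$K1), ncol(kern$K2)), call. = FALSE)
  }
  kern$K1 %*% Fm %*% t(kern$K2)
}
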