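#' Logarithmically spaced sequence
#'
#' Geometric progression between `from` and `to` inclusive, the spacing used
#' for inversion-time and relaxation-time axes.
#'
#' @param from,to positive endpoints, `from < to`.
#' @param length.out number of points (>= 2).
#' @return numeric vector of length `length.out`.
#' @export
logspace <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

check_range <- function(r, what) {
  if (length(r) != 2L || !all(is.finite(r)) || r[1] <= 0 || r[1] >= r[2]) {
    stop(sprintf("`%s` must be a finite positive interval (lower < upper), got [%s]",
                 what, paste(signif(r, 6), collapse = ", ")), call. = FALSE)
  }
  invisible(r)
}

check_increasing_positive <- function(x, what) {
  if (length(x) < 2L || !all(is.finite(x)) || any(x <= 0) || any(diff(x) <= 0)) {
    stop(sprintf("`%s` must be finite, positive and strictly increasing with length >= 2", what),
         call. = FALSE)
  }
  invisible(x)
}

#' Acquisition time grid
#'
#' Holds the inversion times `t1` of the IR dimension and the echo times `t2`
#' of the CPMG dimension, in seconds.
#'
#' @param t1,t2 strictly increasing positive time vectors (seconds).
#' @param spacing character vector of length 2 describing the spacing of each
#'   axis (informational).
#' @return an object of class `time_grid` with elements `t1`, `t2`, `spacing`.
#' @export
time_grid <- function(t1, t2, spacing = c("log", "linear")) {
  check_increasing_positive(t1, "t1")
  check_increasing_positive(t2, "t2")
  structure(list(t1 = as.numeric(t1), t2 = as.numeric(t2), spacing = spacing),
            class = "time_grid")
}

#' Relaxation time grid
#'
#' Holds the candidate longitudinal (`T1`) and transversal (`T2`) relaxation
#' times on which the distribution is discretized, in seconds.  Log spacing
#' (geometric progression) is the default for both axes.
#'
#' @param T1,T2 strictly increasing positive relaxation-time vectors (seconds).
#' @return an object of class `relax_grid` with elements `T1`, `T2`.
#' @export
relax_grid <- function(T1, T2) {
  check_increasing_positive(T1, "T1")
  check_increasing_positive(T2, "T2")
  structure(list(T1 = as.numeric(T1), T2 = as.numeric(T2)), class = "relax_grid")
}

#' Build acquisition and relaxation grids
#'
#' Constructs the standard IR-CPMG sampling scheme: inversion times `t1`
#' log-spaced, echo times `t2` linearly spaced, and both relaxation axes in
#' geometric progression, endpoints included.
#'
#' @param M1,M2 number of inversion times / echo times (>= 2).
#' @param t1_range,t2_range positive intervals `c(lower, upper)` in seconds.
#' @param N1,N2 number of relaxation-time nodes per axis (>= 2).
#' @param T1_range,T2_range positive intervals for the relaxation axes
#'   (seconds).
#' @return list with components `time` (a [time_grid]) and `relax`
#'   (a [relax_grid]).
#' @examples
#' g <- make_grids(M1 = 8, M2 = 8, t1_range = c(1e-3, 3), t2_range = c(1e-3, 1),
#'                 N1 = 5, N2 = 5, T1_range = c(1e-3, 3), T2_range = c(1e-3, 1))
#' @export
make_grids <- function(M1, M2, t1_range, t2_range, N1, N2, T1_range, T2_range) {
  for (n in c(M1, M2, N1, N2)) {
    if (!is.finite(n) || n < 2) stop("grid sizes must be >= 2", call. = FALSE)
  }
  check_range(t1_range, "t1_range"); check_range(t2_range, "t2_range")
  check_range(T1_range, "T1_range"); check_range(T2_range, "T2_range")
  list(
    time  = time_grid(logspace(t1_range[1], t1_range[2], M1),
                      seq(t2_range[1], t2_range[2], length.out = M2)),
    relax = relax_grid(logspace(T1_range[1], T1_range[2], N1),
                       logspace(T2_range[1], T2_range[2], N2))
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> t1: %d pts [%.4g, %.4g] s (%s); t2: %d pts [%.4g, %.4g] s (%s)\n",
              length(x$t1), min(x$t1), max(x$t1), x$spacing[1],
              length(x$t2), min(x$t2), max(x$t2), x$spacing[2]))
  invisible(x)
}

#' @export
print.relax_grid <- function(x, ...) {
  cat(sprintf("<relax_grid> T1: %d pts [%.4g, %.4g] s; T2: %d pts [%.4g, %.4g] s\n",
              length(x$T1), min(x$T1), max(x$T1),
              length(x$T2), min(x$T2), max(x$T2)))
  invisible(x)
}
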