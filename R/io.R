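#' Write / read a decay surface as delimited text
#'
#' Plain-text interchange format: two header lines carrying the `t1` and `t2`
#' vectors (seconds), then the `M1 x M2` signal block, comma separated.
#'
#' @param S a [data_surface] (with its time grid) for writing.
#' @param path file path.
#' @return `read_surface` returns a [data_surface]; `write_surface` returns
#'   `path` invisibly.
#' @export
write_surface <- function(S, path) {
  stopifnot(inherits(S, "data_surface"), !is.null(S$tg))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# t1: ", paste(format(S$tg$t1, digits = 17), collapse = ",")), con)
  writeLines(paste0("# t2: ", paste(format(S$tg$t2, digits = 17), collapse = ",")), con)
  utils::write.table(S$S, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  hdr <- readLines(path, n = 2L)
  parse_vec <- function(line, tag) {
    if (!startsWith(line, paste0("# ", tag, ":"))) {
      stop(sprintf("expected a '# %s:' header line", tag), call. = FALSE)
    }
    as.numeric(strsplit(sub(paste0("^# ", tag, ": *"), "", line), ",")[[1]])
  }
  t1 <- parse_vec(hdr[1], "t1"); t2 <- parse_vec(hdr[2], "t2")
  S <- as.matrix(utils::read.table(path, sep = ",", skip = 2L))
  dimnames(S) <- NULL
  data_surface(S, time_grid(t1, t2))
}

#' Write / read a relaxation-time distribution as delimited text
#'
#' Same layout as [write_surface()] with `T1` and `T2` header lines
#' (seconds) followed by the `N1 x N2` amplitude block.
#'
#' @param F a [t1t2_dist] (with its grid) for writing.
#' @param path file path.
#' @return `read_distribution` returns a [t1t2_dist]; `write_distribution`
#'   returns `path` invisibly.
#' @export
write_distribution <- function(F, path) {
  stopifnot(inherits(F, "t1t2_dist"), !is.null(F$rg))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# T1: ", paste(format(F$rg$T1, digits = 17), collapse = ",")), con)
  writeLines(paste0("# T2: ", paste(format(F$rg$T2, digits = 17), collapse = ",")), con)
  utils::write.table(F$F, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  hdr <- readLines(path, n = 2L)
  parse_vec <- function(line, tag) {
    if (!startsWith(line, paste0("# ", tag, ":"))) {
      stop(sprintf("expected a '# %s:' header line", tag), call. = FALSE)
    }
    as.numeric(strsplit(sub(paste0("^# ", tag, ": *"), "", line), ",")[[1]])
  }
  T1 <- parse_vec(hdr[1], "T1"); T2 <- parse_vec(hdr[2], "T2")
  F <- as.matrix(utils::read.table(path, sep = ",", skip = 2L))
  dimnames(F) <- NULL
  t1t2_dist(F, relax_grid(T1, T2))
}

#' Minimal reader for a STELAR-like ascii layout
#'
#' Reads a whitespace-separated ascii file consisting of the `t1` vector
#' (one line), the `t2` vector (one line), then `M1` rows of `M2` signal
#' values.  Comment lines starting with `#` are skipped.  Times may be
#' declared in milliseconds via `unit = "ms"` and are converted to seconds.
#'
#' @param path file path.
#' @param unit `"s"` (default) or `"ms"` for the time vectors.
#' @return a [data_surface].
#' @export
read_stelar_ascii <- function(path, unit = c("s", "ms")) {
  unit <- match.arg(unit)
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (length(ln) < 3L) stop("file too short for a STELAR-like layout", call. = FALSE)
  num <- function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]])
  t1 <- num(ln[1]); t2 <- num(ln[2])
  if (unit == "ms") { t1 <- t1 / 1000; t2 <- t2 / 1000 }
  rows <- lapply(ln[-(1:2)], num)
  if (length(rows) != length(t1) || any(lengths(rows) != length(t2))) {
    stop(sprintf("signal block must be %d rows of %d values", length(t1), length(t2)),
         call. = FALSE)
  }
  data_surface(do.call(rbind, rows), time_grid(t1, t2))
}
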