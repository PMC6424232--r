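#' Time-activity curve
#'
#' A sampled tracer concentration curve: times in minutes post-injection
#' (strictly increasing, first time >= 0) and activity concentrations in
#' kBq/mL (non-negative).
#'
#' @param times Numeric vector of sample times, minutes post-injection.
#' @param values Numeric vector of activity concentrations, kBq/mL.
#' @return An object of class `tac`, a list with elements `times` and
#'   `values`.
#' @examples
#' cp <- tac(0:10, exp(-0.1 * (0:10)))
#' @export
tac <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (length(times) == 0L) stop("empty time-activity curve", call. = FALSE)
  if (anyNA(times) || anyNA(values)) stop("NA in time-activity curve", call. = FALSE)
  if (times[1] < 0) stop("first time must be >= 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (any(values < 0)) stop("activity concentrations must be >= 0", call. = FALSE)
  structure(list(times = times, values = values), class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curve: %d samples on [%g, %g] min, peak %.4g kBq/mL\n",
              length(x$times), min(x$times), max(x$times), max(x$values)))
  invisible(x)
}

#' Evaluate a time-activity curve at arbitrary times
#'
#' Linear interpolation on the stored grid; times outside the grid are an
#' error (curves are never extrapolated).
#'
#' @param cv A [tac()] object.
#' @param t Numeric vector of times, minutes.
#' @return Numeric vector of interpolated concentrations, kBq/mL.
#' @export
tac_at <- function(cv, t) {
  stopifnot(inherits(cv, "tac"))
  if (any(t < cv$times[1] - 1e-9) || any(t > cv$times[length(cv$times)] + 1e-9)) {
    stop("requested times outside the curve's support", call. = FALSE)
  }
  stats::approx(cv$times, cv$values, xout = t, rule = 2)$y
}

#' Read / write a time-activity curve as two-column CSV
#'
#' The on-disk format is a UTF-8 CSV with the one-line header
#' `time_min,kBq_per_mL`.
#'
#' @param path File path.
#' @return `read_tac` returns a [tac()]; `write_tac` returns `path`
#'   invisibly.
#' @export
read_tac <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "kBq_per_mL") %in% names(df))) {
    stop("expected columns time_min, kBq_per_mL in ", path, call. = FALSE)
  }
  tac(df$time_min, df$kBq_per_mL)
}

#' @rdname read_tac
#' @param cv A [tac()] object.
#' @export
write_tac <- function(cv, path) {
  stopifnot(inherits(cv, "tac"))
  utils::write.csv(data.frame(time_min = cv$times, kBq_per_mL = cv$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
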