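#' Venous plasma sample
#'
#' One late venous plasma measurement: time post-injection (minutes) and
#' plasma activity concentration (kBq/mL).  The sampling protocol draws two
#' samples, nominally at 55 and 85 min.
#'
#' @param time Minutes post-injection, > 0.
#' @param concentration Plasma activity concentration, kBq/mL, > 0.
#' @return An object of class `venous_sample`.
#' @export
venous_sample <- function(time, concentration) {
  if (!is.finite(time) || time <= 0) stop("sample time must be > 0", call. = FALSE)
  if (!is.finite(concentration) || concentration <= 0) {
    stop("plasma concentration must be > 0", call. = FALSE)
  }
  structure(list(time = time, concentration = concentration),
            class = "venous_sample")
}

#' Fit the patient terminal exponential
#'
#' Fits \eqn{C_p(t) = A e^{-\lambda t}} through late venous samples.  With
#' exactly two samples the fit is the closed form
#' \eqn{\lambda = \ln(c_1/c_2)/(t_2 - t_1)}, \eqn{A = c_1 e^{\lambda t_1}},
#' which passes exactly through both points; with three or more samples a
#' log-linear least-squares fit is used.
#'
#' @param ... [venous_sample()] objects (or a single list of them), at
#'   least two, with distinct times.
#' @return A list of class `terminal_exponential` with fields `A` (kBq/mL)
#'   and `lambda` (min^-1).
#' @examples
#' fit_terminal_exponential(venous_sample(55, 10), venous_sample(85, 5))
#' @export
fit_terminal_exponential <- function(...) {
  samples <- list(...)
  if (length(samples) == 1L && !inherits(samples[[1]], "venous_sample")) {
    samples <- samples[[1]]
  }
  stopifnot(all(vapply(samples, inherits, logical(1), "venous_sample")))
  if (length(samples) < 2L) stop("need at least two venous samples", call. = FALSE)
  t <- vapply(samples, `[[`, numeric(1), "time")
  c_ <- vapply(samples, `[[`, numeric(1), "concentration")
  o <- order(t)
  t <- t[o]; c_ <- c_[o]
  if (any(diff(t) == 0)) stop("degenerate fit: equal sample times", call. = FALSE)
  if (length(t) == 2L) {
    lambda <- log(c_[1] / c_[2]) / (t[2] - t[1])
    A <- c_[1] * exp(lambda * t[1])
  } else {
    fit <- stats::lm.fit(cbind(1, t), log(c_))
    lambda <- -unname(fit$coefficients[2])
    A <- exp(unname(fit$coefficients[1]))
  }
  structure(list(A = A, lambda = lambda), class = "terminal_exponential")
}

#' Evaluate a terminal exponential
#' @param te A `terminal_exponential`.
#' @param t Times, minutes.
#' @return `A * exp(-lambda * t)`, kBq/mL.
#' @export
terminal_at <- function(te, t) {
  stopifnot(inherits(te, "terminal_exponential"))
  te$A * exp(-te$lambda * t)
}

#' Population arterial input function
#'
#' A sum-of-exponentials model of the arterial plasma fluoride curve,
#' \eqn{C_p(t) = \sum_j A_j e^{-\mu_j t}}, together with its own terminal
#' exponential fitted over the venous-sampling window and the residual
#' curve \eqn{r(t) = C_p(t) - A e^{-\lambda t}} that captures the early
#' bolus/distribution phase.  The packaged default is a synthetic
#' tri-exponential chosen to resemble published fluoride input functions
#' for a ~230 MBq injection (bolus peak ~245 kBq/mL, late plasma
#' ~4-6 kBq/mL at 55-85 min); it is a documented fixture, not a measured
#' population curve.
#'
#' @param exponential_terms Matrix-like of (amplitude kBq/mL, rate min^-1)
#'   rows, or `NULL` for the packaged default.
#' @param residual_window Two-element window (minutes) over which the
#'   terminal exponential of the population curve is fitted. Default
#'   `c(55, 85)`, matching the venous sampling times.
#' @param grid_step Sampling step of the dense representation, minutes.
#' @param t_max End of the supported grid, minutes. Default 90.
#' @return Object of class `population_if` with the dense curve, its
#'   terminal exponential and the residual curve.
#' @export
population_input_function <- function(exponential_terms = NULL,
                                      residual_window = c(55, 85),
                                      grid_step = 0.1, t_max = 90) {
  if (is.null(exponential_terms)) {
    exponential_terms <- default_popif_terms()
  }
  et <- as.matrix(exponential_terms)
  if (ncol(et) != 2L || any(!is.finite(et)) || any(et[, 1] <= 0) || any(et[, 2] < 0)) {
    stop("exponential_terms must be rows of (amplitude > 0, rate >= 0)", call. = FALSE)
  }
  grid <- seq(0, t_max, by = grid_step)
  vals <- popif_eval(et, grid)
  w <- residual_window
  te <- fit_terminal_exponential(
    venous_sample(w[1], popif_eval(et, w[1])),
    venous_sample(w[2], popif_eval(et, w[2]))
  )
  residual <- vals - terminal_at(te, grid)
  structure(list(terms = et, grid = grid, values = vals,
                 terminal = te, residual = residual,
                 residual_window = w, grid_step = grid_step, t_max = t_max),
            class = "population_if")
}

popif_eval <- function(terms, t) {
  v <- numeric(length(t))
  for (j in seq_len(nrow(terms))) {
    v <- v + terms[j, 1] * exp(-terms[j, 2] * t)
  }
  v
}

default_popif_terms <- function() {
  cbind(amplitude_kBq_per_mL = c(200, 35, 10),
        rate_per_min = c(4.0, 0.25, 0.011))
}

#' @export
print.population_if <- function(x, ...) {
  cat(sprintf("Population input function: %d exponential terms on [0, %g] min\n",
              nrow(x$terms), x$t_max))
  cat(sprintf("  terminal fit over [%g, %g] min: A = %.4g kBq/mL, lambda = %.4g /min\n",
              x$residual_window[1], x$residual_window[2],
              x$terminal$A, x$terminal$lambda))
  invisible(x)
}

#' Read a population input function from a JSON config
#'
#' Config keys: `exponential_terms` (list of `[amplitude_kBq_per_mL,
#' rate_per_min]` pairs), `residual_window_min`, `grid_step_min`.
#'
#' @param path Path to the JSON file.
#' @return A [population_input_function()] object.
#' @export
read_popif_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  population_input_function(
    exponential_terms = cfg$exponential_terms,
    residual_window = cfg$residual_window_min %||% c(55, 85),
    grid_step = cfg$grid_step_min %||% 0.1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct the semi-population plasma input function
#'
#' Combines a patient's terminal exponential (from two late venous samples)
#' with the population residual curve:
#' \deqn{C_p(t) = A e^{-\lambda t} + s\, r(t).}
#' The residual is ~0 over the venous window and beyond, so the
#' reconstruction follows the patient's own late kinetics exactly while
#' borrowing the unobservable early bolus phase from the population.
#'
#' @param te A `terminal_exponential` (see [fit_terminal_exponential()]).
#' @param pop A [population_input_function()] object.
#' @param grid Times (minutes) at which to evaluate; must lie within the
#'   population curve's support. Defaults to the population grid.
#' @param residual_scale `"unit"` (s = 1, the literal "add the population
#'   residual") or `"terminal-ratio"` (s = patient / population terminal
#'   exponential value at the start of the residual window, appropriate
#'   when the patient curve is approximately a global rescaling of the
#'   population curve).
#' @return A [tac()] object.  Negative sums are clipped to 0 with a
#'   warning.
#' @export
reconstruct_input <- function(te, pop, grid = NULL,
                              residual_scale = c("unit", "terminal-ratio")) {
  stopifnot(inherits(te, "terminal_exponential"), inherits(pop, "population_if"))
  residual_scale <- match.arg(residual_scale)
  if (is.null(grid)) grid <- pop$grid
  if (min(grid) < 0 || max(grid) > pop$t_max + 1e-9) {
    stop("grid extends beyond the residual curve's support", call. = FALSE)
  }
  s <- if (residual_scale == "unit") 1 else {
    t0 <- pop$residual_window[1]
    terminal_at(te, t0) / terminal_at(pop$terminal, t0)
  }
  r <- stats::approx(pop$grid, pop$residual, xout = grid)$y
  vals <- terminal_at(te, grid) + s * r
  if (any(vals < 0)) {
    warning("reconstructed input function negative at ",
            sum(vals < 0), " grid point(s); clipped to 0")
    vals[vals < 0] <- 0
  }
  tac(grid, vals)
}

#' Trapezoidal integral of a plasma curve
#'
#' \eqn{\int_0^{T} C_p\, dt} on the stored grid (trapezoidal rule), the
#' denominator term of the static Patlak estimator.
#'
#' @param cp A [tac()] plasma curve covering `[0, t_end]`.
#' @param t_end Upper limit, minutes.
#' @return Integral in kBq min/mL.
#' @export
integrate_plasma <- function(cp, t_end) {
  stopifnot(inherits(cp, "tac"))
  if (cp$times[1] > 0 || t_end > cp$times[length(cp$times)] + 1e-9) {
    stop("plasma curve does not cover [0, t_end]", call. = FALSE)
  }
  keep <- cp$times < t_end
  t <- c(cp$times[keep], t_end)
  v <- c(cp$values[keep], tac_at(cp, t_end))
  sum(diff(t) * (v[-length(v)] + v[-1]) / 2)
}
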