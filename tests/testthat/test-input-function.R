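test_that("terminal exponential fit: closed form, round trip, errors", {
  flat <- fit_terminal_exponential(venous_sample(55, 10), venous_sample(85, 10))
  expect_equal(flat$lambda, 0)
  expect_equal(flat$A, 10)

  half <- fit_terminal_exponential(venous_sample(55, 10), venous_sample(85, 5))
  expect_equal(half$lambda, log(2) / 30)
  expect_equal(half$A * exp(-55 * half$lambda), 10, tolerance = 1e-12)
  # passes exactly through both samples
  expect_equal(terminal_at(half, c(55, 85)), c(10, 5), tolerance = 1e-12)

  # round trip from a known exponential
  te0 <- structure(list(A = 50, lambda = 0.02), class = "terminal_exponential")
  rec <- fit_terminal_exponential(venous_sample(55, terminal_at(te0, 55)),
                                  venous_sample(85, terminal_at(te0, 85)))
  expect_equal(rec$A, 50, tolerance = 1e-12)
  expect_equal(rec$lambda, 0.02, tolerance = 1e-12)

  expect_error(venous_sample(55, -1), "> 0")
  expect_error(venous_sample(0, 5), "> 0")
  expect_error(fit_terminal_exponential(venous_sample(55, 10),
                                        venous_sample(55, 9)), "degenerate")
})

test_that("three or more samples fall back to log-linear least squares", {
  te0 <- structure(list(A = 40, lambda = 0.015), class = "terminal_exponential")
  ss <- lapply(c(50, 65, 85), function(t) venous_sample(t, terminal_at(te0, t)))
  fit <- fit_terminal_exponential(ss)
  expect_equal(fit$A, 40, tolerance = 1e-10)
  expect_equal(fit$lambda, 0.015, tolerance = 1e-10)
})

test_that("population input function invariants hold", {
  pop <- population_input_function()
  expect_true(all(pop$values >= 0))
  # residual vanishes over and beyond the venous window
  late <- pop$grid >= 55
  expect_lt(max(abs(pop$residual[late])), 0.01 * max(pop$values))
  # exact zeros at the window endpoints by construction
  expect_equal(pop$residual[match(55, pop$grid)], 0, tolerance = 1e-9)
  expect_equal(pop$residual[match(85, pop$grid)], 0, tolerance = 1e-9)
  expect_error(population_input_function(cbind(c(-1, 2), c(0.1, 0.2))),
               "amplitude")
})

test_that("reconstruction identity: samples on the population terminal", {
  pop <- population_input_function()
  s1 <- venous_sample(55, terminal_at(pop$terminal, 55))
  s2 <- venous_sample(85, terminal_at(pop$terminal, 85))
  te <- fit_terminal_exponential(s1, s2)
  rec <- reconstruct_input(te, pop, residual_scale = "unit")
  expect_lt(max(abs(rec$values - pop$values)), 1e-9)
})

test_that("reconstruction limit A -> 0 returns the residual curve", {
  pop <- population_input_function()
  te <- structure(list(A = 1e-12, lambda = 0.01), class = "terminal_exponential")
  grid <- seq(0, 50, 0.5)  # early segment, where the residual is positive
  rec <- reconstruct_input(te, pop, grid = grid, residual_scale = "unit")
  r <- approx(pop$grid, pop$residual, xout = grid)$y
  expect_equal(rec$values, r, tolerance = 1e-9)
})

test_that("a globally rescaled patient is recovered by the terminal-ratio mode", {
  pop <- population_input_function()
  scale <- 0.8
  s1 <- venous_sample(55, scale * approx(pop$grid, pop$values, 55)$y)
  s2 <- venous_sample(85, scale * approx(pop$grid, pop$values, 85)$y)
  te <- fit_terminal_exponential(s1, s2)
  rec <- reconstruct_input(te, pop, residual_scale = "terminal-ratio")
  truth <- scale * pop$values
  expect_lt(max(abs(rec$values - truth) / max(truth)), 0.01)
})

test_that("reconstruction is Lipschitz in the sample concentrations", {
  pop <- population_input_function()
  c1 <- terminal_at(pop$terminal, 55)
  c2 <- terminal_at(pop$terminal, 85)
  base <- reconstruct_input(fit_terminal_exponential(
    venous_sample(55, c1), venous_sample(85, c2)), pop)
  dev <- function(eps) {
    pert <- reconstruct_input(fit_terminal_exponential(
      venous_sample(55, c1 * (1 + eps)), venous_sample(85, c2)), pop)
    max(abs(pert$values - base$values))
  }
  d1 <- dev(1e-3)
  d2 <- dev(5e-4)
  expect_lt(d1, 1)                      # bounded response to a tiny perturbation
  expect_equal(d1 / d2, 2, tolerance = 0.05)  # first-order (linear) scaling
})

test_that("beyond 55 min the reconstruction equals the patient terminal", {
  pop <- population_input_function()
  te <- structure(list(A = 12, lambda = 0.013), class = "terminal_exponential")
  rec <- reconstruct_input(te, pop)
  late <- rec$times >= 55
  expect_lt(max(abs(rec$values[late] - terminal_at(te, rec$times[late]))),
            0.01 * max(pop$values))
})

test_that("negative reconstructed values are clipped with a warning", {
  pop <- population_input_function()
  # residual dips slightly negative between the window endpoints for a
  # patient whose terminal sits near zero amplitude; force one negative
  pop$residual[100] <- -5
  te <- structure(list(A = 1e-6, lambda = 0.01), class = "terminal_exponential")
  expect_warning(rec <- reconstruct_input(te, pop), "clipped")
  expect_true(all(rec$values >= 0))
})

test_that("integrate_plasma matches closed forms and is additive", {
  grid <- seq(0, 60, 0.1)
  const <- tac(grid, rep(5, length(grid)))
  expect_equal(integrate_plasma(const, 60), 300)
  expect_equal(integrate_plasma(tac(grid, rep(0, length(grid))), 60), 0)

  A <- 30; lam <- 0.05
  ex <- tac(grid, A * exp(-lam * grid))
  analytic <- A * (1 - exp(-lam * 60)) / lam
  expect_lt(abs(integrate_plasma(ex, 60) - analytic) / analytic, 1e-3)

  # additivity over adjacent intervals and monotonicity in the integrand
  expect_equal(integrate_plasma(ex, 25) +
                 (integrate_plasma(ex, 60) - integrate_plasma(ex, 25)),
               integrate_plasma(ex, 60))
  bigger <- tac(grid, A * exp(-lam * grid) + 1)
  expect_gt(integrate_plasma(bigger, 60), integrate_plasma(ex, 60))
  expect_error(integrate_plasma(ex, 61), "cover")
})

test_that("population input function reads from a JSON config", {
  path <- system.file("extdata", "population_if.json", package = "fluorideKi")
  pop <- read_popif_config(path)
  expect_s3_class(pop, "population_if")
  expect_equal(nrow(pop$terms), 3)
  expect_equal(pop$residual_window, c(55, 85))
})
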