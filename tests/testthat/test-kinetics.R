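test_that("macro_flux matches the closed form and its bounds", {
  expect_equal(macro_flux(rate_constants(0.10, 0.30, 0.30)), 0.050)
  expect_equal(macro_flux(rate_constants(0.10, 0.30, 0.00)), 0.0)
  # independent hand arithmetic: 0.12 * 0.15 / 0.40
  expect_equal(macro_flux(rate_constants(0.12, 0.25, 0.15)), 0.045)
  expect_error(macro_flux(rate_constants(0.1, 0, 0)), "degenerate")

  rcs <- random_rate_constants(50, seed = 11)
  ki <- mapply(function(K1, k2, k3) macro_flux(rate_constants(K1, k2, k3)),
               rcs$K1, rcs$k2, rcs$k3)
  expect_true(all(ki >= 0 & ki <= rcs$K1))
  # monotone: increasing in K1 and k3, decreasing in k2
  eps <- 1e-6
  for (i in seq_len(nrow(rcs))) {
    base <- macro_flux(rate_constants(rcs$K1[i], rcs$k2[i], rcs$k3[i]))
    expect_gt(macro_flux(rate_constants(rcs$K1[i] + eps, rcs$k2[i], rcs$k3[i])), base)
    expect_gt(macro_flux(rate_constants(rcs$K1[i], rcs$k2[i], rcs$k3[i] + eps)), base)
    expect_lt(macro_flux(rate_constants(rcs$K1[i], rcs$k2[i] + eps, rcs$k3[i])), base)
  }
})

test_that("rate constants and curves enforce their invariants", {
  expect_error(rate_constants(-0.1, 0.3, 0.1), ">= 0")
  expect_error(tac(c(0, 1, 1), c(1, 1, 1)), "strictly increasing")
  expect_error(tac(c(0, 1), c(1, -1)), ">= 0")
  expect_error(tac_at(tac(0:10, rep(1, 11)), 11), "outside")
})

test_that("tissue simulation is linear and handles limiting cases", {
  plasma <- test_plasma()
  rc <- rate_constants(0.15, 0.3, 0.2, 0.005)
  t_out <- c(10, 30, 60)
  one <- simulate_tissue_curve(rc, plasma, t_out)
  # zero input -> zero output
  zero <- simulate_tissue_curve(rc, tac(plasma$times, 0 * plasma$values), t_out)
  expect_equal(zero$values, c(0, 0, 0))
  # linearity: doubling plasma doubles tissue to 1e-10
  two <- simulate_tissue_curve(rc, tac(plasma$times, 2 * plasma$values), t_out)
  expect_equal(two$values, 2 * one$values, tolerance = 1e-10)
  # coverage error
  expect_error(simulate_tissue_curve(rc, plasma, 120), "cover")
})

test_that("one-compartment limit: after a finite bolus, tissue decays as exp(-k2 t)", {
  # k3 = k4 = 0: once the input ends the system is a pure washout
  grid <- seq(0, 60, 0.1)
  bolus <- ifelse(grid <= 0.2, 100 * (1 - abs(grid - 0.1) / 0.1), 0)
  plasma <- tac(grid, pmax(bolus, 0))
  rc <- rate_constants(0.2, 0.25, 0, 0)
  tt <- c(10, 20, 40)
  tis <- simulate_tissue_curve(rc, plasma, tt)
  expect_equal(tis$values[2] / tis$values[1], exp(-0.25 * 10), tolerance = 1e-9)
  expect_equal(tis$values[3] / tis$values[1], exp(-0.25 * 30), tolerance = 1e-9)
})

test_that("constant input, k4 = 0: bound pool follows Ki*c*(t - (1-e^{-bt})/b)", {
  c0 <- 8
  grid <- seq(0, 90, 0.1)
  plasma <- tac(grid, rep(c0, length(grid)))
  rc <- rate_constants(0.18, 0.3, 0.2, 0)
  b <- rc$k2 + rc$k3
  tt <- c(20, 50, 80)
  comp <- fluorideKi:::simulate_compartments(rc, plasma, tt)
  closed <- macro_flux(rc) * c0 * (tt - (1 - exp(-b * tt)) / b)
  expect_equal(comp$bound, closed, tolerance = 1e-6)
  # asymptotically linear growth at rate Ki*c
  expect_equal((comp$bound[3] - comp$bound[2]) / 30, macro_flux(rc) * c0,
               tolerance = 1e-6)
  # bound pool non-decreasing for any non-negative input
  full <- fluorideKi:::simulate_compartments(rc, test_plasma(), seq(1, 90, 1))
  expect_true(all(diff(full$bound) >= -1e-12))
})

test_that("convolution solution matches a fine-step RK4 ODE oracle to < 1e-4", {
  plasma <- test_plasma()
  cases <- list(rate_constants(0.2, 0.3, 0.15, 0),
                rate_constants(0.1, 0.5, 0.05, 0.01),
                rate_constants(0.25, 0.15, 0.35, 0))
  for (rc in cases) {
    t_out <- c(15, 45, 75)
    sim <- simulate_tissue_curve(rc, plasma, t_out)
    ora <- rk4_tissue_oracle(rc, plasma, t_out)
    expect_lt(max(abs(sim$values - ora) / ora), 1e-4)
  }
  # with a blood volume fraction
  rc <- rate_constants(0.2, 0.3, 0.15, 0)
  sim <- simulate_tissue_curve(rc, plasma, 60, blood_volume_fraction = 0.1)
  ora <- rk4_tissue_oracle(rc, plasma, 60, blood_volume_fraction = 0.1)
  expect_lt(abs(sim$values - ora) / ora, 1e-4)
})

test_that("patlak_fit recovers an exactly linear construction", {
  plasma <- test_plasma()
  grid <- seq(0, 90, 0.5)
  cp <- tac(grid, tac_at(plasma, grid))
  icp <- fluorideKi:::cumtrapz(grid, cp$values)
  # tissue built from the defining identity y = 0.05 x + 0.40
  tissue <- tac(grid, 0.05 * icp + 0.40 * cp$values)
  fit <- patlak_fit(tissue, cp, t_star = 10)
  expect_equal(fit$Ki, 0.05, tolerance = 1e-10)
  expect_equal(fit$V0, 0.40, tolerance = 1e-10)
  # no trapping: tissue = V0 * plasma -> slope ~ 0, intercept ~ V0
  flat <- patlak_fit(tac(grid, 0.7 * cp$values), cp, t_star = 10)
  expect_equal(flat$Ki, 0, tolerance = 1e-12)
  expect_equal(flat$V0, 0.7, tolerance = 1e-10)
})

test_that("patlak_fit slope agrees with macro_flux on noiseless simulations", {
  plasma <- test_plasma()
  grid <- seq(0, 90, 0.5)
  cp <- tac(grid, tac_at(plasma, grid))
  rcs <- random_rate_constants(25, seed = 3)
  for (i in seq_len(nrow(rcs))) {
    rc <- rate_constants(rcs$K1[i], rcs$k2[i], rcs$k3[i], 0)
    tis <- simulate_tissue_curve(rc, plasma, grid)
    fit <- patlak_fit(tis, cp, t_star = 30)
    expect_lt(abs(fit$Ki - macro_flux(rc)) / macro_flux(rc), 0.05)
  }
})

test_that("patlak_fit rejects bad inputs", {
  grid <- seq(0, 90, 1)
  cp <- tac(grid, tac_at(test_plasma(), grid))
  tis <- tac(grid, cp$values)
  expect_error(patlak_fit(tis, cp, t_star = 89), "at least 3")
  cp0 <- tac(grid, c(tac_at(test_plasma(), grid)[-length(grid)], 0))
  expect_error(patlak_fit(tis, cp0, t_star = 30), "zero")
  expect_error(patlak_fit(tac(grid[-1], tis$values[-1]), cp, t_star = 30),
               "common time grid")
})

test_that("time-activity curves round-trip through CSV", {
  cv <- tac(seq(0, 10, 0.5), exp(-0.1 * seq(0, 10, 0.5)) * 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tac(cv, path)
  back <- read_tac(path)
  expect_equal(back$times, cv$times)
  expect_equal(back$values, cv$values, tolerance = 1e-12)
})
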