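# Independent oracles used across the suite.  These deliberately avoid the
# package's convolution path: the ODE oracle is a plain fixed-step RK4 over
# the two-compartment system, driven by the same piecewise-linear plasma
# curve the package sees.

rk4_tissue_oracle <- function(rc, plasma, t_out, h = 0.01,
                              blood_volume_fraction = 0) {
  cp <- function(t) tac_at(plasma, t)
  f <- function(t, y) {
    c(rc$K1 * cp(t) - (rc$k2 + rc$k3) * y[1] + rc$k4 * y[2],
      rc$k3 * y[1] - rc$k4 * y[2])
  }
  t_out <- sort(t_out)
  y <- c(0, 0)
  t <- 0
  out <- numeric(length(t_out))
  for (j in seq_along(t_out)) {
    n <- ceiling((t_out[j] - t) / h)
    hh <- if (n > 0) (t_out[j] - t) / n else 0
    for (i in seq_len(n)) {
      k1 <- f(t, y)
      k2 <- f(t + hh / 2, y + hh / 2 * k1)
      k3 <- f(t + hh / 2, y + hh / 2 * k2)
      k4 <- f(t + hh, y + hh * k3)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    out[j] <- sum(y) + blood_volume_fraction * cp(t)
  }
  out
}

# Exhaustive-scan segmentation oracle for single-blob images: every voxel
# at or above the threshold fraction of the global maximum, as a sorted
# linear-index vector.  Valid when the supra-threshold set is one
# connected blob (true for the Gaussian phantoms).
brute_force_roi <- function(image, threshold_fraction = 0.40) {
  sort(which(image >= threshold_fraction * max(image)))
}

roi_linear_indices <- function(roi, dims) {
  v <- roi$voxels
  sort(v[, 1] + dims[1] * (v[, 2] - 1L) + dims[1] * dims[2] * (v[, 3] - 1L))
}

# dense tri-exponential plasma fixture shared by several tests
test_plasma <- function(grid_step = 0.1, t_max = 90) {
  pop <- population_input_function(grid_step = grid_step, t_max = t_max)
  tac(pop$grid, pop$values)
}

random_rate_constants <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(K1 = runif(n, 0.05, 0.30),
             k2 = runif(n, 0.10, 0.60),
             k3 = runif(n, 0.05, 0.40))
}
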