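#' Specification of a synthetic cohort
#'
#' Collects every dial of the synthetic-study generator.  Defaults state
#' the cohort the package emulates: 12 patients, 4 progressive (PD) and 8
#' non-progressive, 2-6 index-eligible lesions each, injected activity
#' 228 +/- 15 MBq, scan at 60 min with venous samples at 55 and 85 min.
#' Baseline rate constants are log-normal with medians K1 = 0.20
#' mL min^-1 mL^-1, k2 = 0.30 min^-1, k3 = 0.15 min^-1 (median
#' Ki ~ 0.067, matching typical metastasis values), k4 = 0.  Treatment
#' multiplies Ki by a log-normal factor (median x1.9 for PD, x1.1 for
#' non-PD) applied through k3; a flare mode occasionally inflates a
#' non-PD lesion.  A disease-burden coefficient depresses the patient's
#' input function in proportion to the summed lesion flux, which is the
#' mechanism that decouples SUV from Ki.
#'
#' @param n_patients Number of patients. Default 12.
#' @param pd_fraction Fraction of patients that are truly PD. Default 1/3.
#' @param lesions_range Inclusive integer range of lesions per patient.
#'   Default `c(2, 6)`.
#' @param K1_median,K1_sdlog,k2_median,k2_sdlog,k3_median,k3_sdlog
#'   Log-normal baseline distributions of the rate constants.
#' @param k4 Bound-pool efflux rate, min^-1. Default 0.
#' @param pd_multiplier_median,pd_multiplier_sdlog Log-normal Ki
#'   multiplier for PD lesions. Default median 1.9, sdlog 0.25.
#' @param nonpd_multiplier_median,nonpd_multiplier_sdlog Non-PD
#'   multiplier. Default median 1.1, sdlog 0.15.
#' @param flare_prob Probability that a non-PD lesion flares. Default
#'   0.15 (~5 of 32 lesions).
#' @param flare_multiplier_median,flare_multiplier_sdlog Flare-mode Ki
#'   multiplier. Default median 1.5, sdlog 0.25.
#' @param venous_noise_cv,scan_noise_cv Multiplicative measurement noise
#'   (coefficient of variation) on venous samples and on C_bone(T).
#'   Default 0.05 each.
#' @param injected_mean,injected_sd Injected activity, MBq.
#'   Default 228 / 15.
#' @param weight_mean,weight_sd Body weight, kg. Default 70 / 12.
#' @param volume_median,volume_sdlog Lesion ROI volume, cm^3 (log-normal).
#'   Default median 6, sdlog 0.6.
#' @param suv_heterogeneity_median,suv_heterogeneity_sdlog Per-lesion
#'   SUVmax/SUVmean ratio (log-normal, fixed across visits).
#'   Default median 1.85, sdlog 0.12.
#' @param burden_coeff Input-function depression: the patient/visit plasma
#'   curve is the population curve times
#'   `exp(-burden_coeff * sum(true lesion Ki))`. Default 1.0; set 0 to
#'   disable.
#' @param blood_pool_fraction Plasma-pool signal fraction added to lesion
#'   concentration for SUV. Default 0.05.
#' @param scan_time_min Static scan uptake time T, minutes. Default 60.
#' @param venous_times_min Venous sampling times, minutes.
#'   Default `c(55, 85)`.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 12, pd_fraction = 1 / 3,
                        lesions_range = c(2, 6),
                        K1_median = 0.20, K1_sdlog = 0.25,
                        k2_median = 0.30, k2_sdlog = 0.25,
                        k3_median = 0.15, k3_sdlog = 0.30,
                        k4 = 0,
                        pd_multiplier_median = 1.9, pd_multiplier_sdlog = 0.25,
                        nonpd_multiplier_median = 1.1, nonpd_multiplier_sdlog = 0.15,
                        flare_prob = 0.15,
                        flare_multiplier_median = 1.5, flare_multiplier_sdlog = 0.25,
                        venous_noise_cv = 0.05, scan_noise_cv = 0.05,
                        injected_mean = 228, injected_sd = 15,
                        weight_mean = 70, weight_sd = 12,
                        volume_median = 6, volume_sdlog = 0.6,
                        suv_heterogeneity_median = 1.85,
                        suv_heterogeneity_sdlog = 0.12,
                        burden_coeff = 1.0,
                        blood_pool_fraction = 0.05,
                        scan_time_min = 60,
                        venous_times_min = c(55, 85)) {
  spec <- as.list(environment())
  if (pd_fraction < 0 || pd_fraction > 1) stop("pd_fraction must be in [0,1]", call. = FALSE)
  if (venous_noise_cv < 0 || scan_noise_cv < 0) stop("noise CVs must be >= 0", call. = FALSE)
  if (flare_prob < 0 || flare_prob > 1) stop("flare_prob must be in [0,1]", call. = FALSE)
  if (lesions_range[1] < 1 || lesions_range[2] < lesions_range[1]) {
    stop("invalid lesions_range", call. = FALSE)
  }
  if (any(c(K1_median, k2_median, k3_median) <= 0) || k4 < 0) {
    stop("rate-constant distributions must yield positive constants", call. = FALSE)
  }
  structure(spec, class = "cohort_spec")
}

# mean-one multiplicative log-normal noise
noise_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

rlnorm_median <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

# Scale k3 (and, when the extraction fraction saturates, K1) so that the
# lesion's macro flux is multiplied by m.
apply_ki_multiplier <- function(rc, m, max_extraction = 0.9) {
  e <- rc$k3 / (rc$k2 + rc$k3)
  e_target <- m * e
  if (e_target <= max_extraction) {
    rate_constants(rc$K1, rc$k2, rc$k2 * e_target / (1 - e_target), rc$k4)
  } else {
    k3_new <- rc$k2 * max_extraction / (1 - max_extraction)
    rate_constants(rc$K1 * e_target / max_extraction, rc$k2, k3_new, rc$k4)
  }
}

#' Generate a complete synthetic cohort
#'
#' Draws per-lesion baseline kinetics, applies group-specific treatment
#' multipliers through k3, simulates lesion concentration at the scan
#' time under the (burden-depressed) patient input function, and records
#' noisy venous samples and SUV measurements — everything the static
#' quantification pipeline needs, plus the ground truth to score it.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed; the generator is deterministic given
#'   `(spec, seed)`.
#' @param pop A [population_input_function()]; default the packaged one.
#' @return List of class `synthetic_cohort` with data.frames:
#'   `patients` (id, group, weight, per-visit injected activity),
#'   `lesions` (measured C_bone, SUV, volume per visit),
#'   `venous` (patient, visit, time, concentration),
#'   `truth` (rate constants and true Ki per visit, multiplier, flare
#'   flag, input-function scale), and the `seed`/`spec` used.
#' @export
generate_cohort <- function(spec, seed, pop = population_input_function()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  n_pd <- round(spec$pd_fraction * spec$n_patients)
  ids <- sprintf("P%02d", seq_len(spec$n_patients))
  groups <- rep(c("PD", "non-PD"), c(n_pd, spec$n_patients - n_pd))

  patients <- data.frame(
    patient_id = ids, group = groups,
    body_weight_kg = pmax(40, stats::rnorm(spec$n_patients, spec$weight_mean, spec$weight_sd)),
    injected_MBq_baseline = stats::rnorm(spec$n_patients, spec$injected_mean, spec$injected_sd),
    injected_MBq_week8 = stats::rnorm(spec$n_patients, spec$injected_mean, spec$injected_sd))

  truth <- NULL; lesions <- NULL; venous <- NULL
  T <- spec$scan_time_min
  for (p in seq_len(spec$n_patients)) {
    nles_choices <- seq(spec$lesions_range[1], spec$lesions_range[2])
    nles <- nles_choices[sample.int(length(nles_choices), 1)]
    K1 <- rlnorm_median(nles, spec$K1_median, spec$K1_sdlog)
    k2 <- rlnorm_median(nles, spec$k2_median, spec$k2_sdlog)
    k3 <- rlnorm_median(nles, spec$k3_median, spec$k3_sdlog)
    is_pd <- groups[p] == "PD"
    flare <- if (is_pd) rep(FALSE, nles) else stats::runif(nles) < spec$flare_prob
    mult <- if (is_pd) {
      rlnorm_median(nles, spec$pd_multiplier_median, spec$pd_multiplier_sdlog)
    } else {
      rlnorm_median(nles, spec$nonpd_multiplier_median, spec$nonpd_multiplier_sdlog)
    }
    mult[flare] <- rlnorm_median(sum(flare), spec$flare_multiplier_median,
                                 spec$flare_multiplier_sdlog)
    rc_b <- lapply(seq_len(nles), function(i) rate_constants(K1[i], k2[i], k3[i], spec$k4))
    rc_w <- lapply(seq_len(nles), function(i) apply_ki_multiplier(rc_b[[i]], mult[i]))
    ki_b <- vapply(rc_b, macro_flux, numeric(1))
    ki_w <- vapply(rc_w, macro_flux, numeric(1))
    scale_b <- exp(-spec$burden_coeff * sum(ki_b))
    scale_w <- exp(-spec$burden_coeff * sum(ki_w))
    vol <- rlnorm_median(nles, spec$volume_median, spec$volume_sdlog)
    het <- rlnorm_median(nles, spec$suv_heterogeneity_median,
                         spec$suv_heterogeneity_sdlog)

    for (visit in c("baseline", "week8")) {
      rcs <- if (visit == "baseline") rc_b else rc_w
      inj <- if (visit == "baseline") patients$injected_MBq_baseline[p] else
        patients$injected_MBq_week8[p]
      # plasma scales with injected dose (so SUV is dose-invariant) and is
      # depressed by whole-body sequestration in proportion to summed flux
      sc <- (inj / spec$injected_mean) *
        (if (visit == "baseline") scale_b else scale_w)
      cp <- tac(pop$grid, pop$values * sc)
      cp_T <- tac_at(cp, T)
      cb <- vapply(rcs, function(rc) {
        simulate_tissue_curve(rc, cp, T)$values
      }, numeric(1))
      cb_meas <- cb * noise_factor(nles, spec$scan_noise_cv)
      conc_suv <- cb_meas + spec$blood_pool_fraction * cp_T
      suv_mean <- suv(conc_suv, inj, patients$body_weight_kg[p])
      lesions <- rbind(lesions, data.frame(
        patient_id = ids[p],
        lesion_id = sprintf("%s-L%02d", ids[p], seq_len(nles)),
        visit = visit,
        C_bone_T_kBq_mL = cb_meas,
        suv_max = suv_mean * het,
        suv_mean = suv_mean,
        volume_cm3 = vol))
      vs <- tac_at(cp, spec$venous_times_min) *
        noise_factor(length(spec$venous_times_min), spec$venous_noise_cv)
      venous <- rbind(venous, data.frame(
        patient_id = ids[p], visit = visit,
        time_min = spec$venous_times_min, kBq_per_mL = vs))
      truth <- rbind(truth, data.frame(
        patient_id = ids[p],
        lesion_id = sprintf("%s-L%02d", ids[p], seq_len(nles)),
        visit = visit, group = groups[p],
        K1 = vapply(rcs, `[[`, numeric(1), "K1"),
        k2 = vapply(rcs, `[[`, numeric(1), "k2"),
        k3 = vapply(rcs, `[[`, numeric(1), "k3"),
        k4 = spec$k4,
        ki_true = if (visit == "baseline") ki_b else ki_w,
        v0_true = vapply(rcs, function(rc) {
          rc$K1 * rc$k2 / (rc$k2 + rc$k3)^2
        }, numeric(1)),
        multiplier = mult, flare = flare,
        input_scale = sc,
        C_bone_true = cb))
    }
  }
  structure(list(patients = patients, lesions = lesions, venous = venous,
                 truth = truth, seed = as.integer(seed), spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort (seed %d): %d patients, %d lesions\n",
              x$seed, nrow(x$patients), nrow(x$lesions) / 2L))
  invisible(x)
}

#' Quantify a synthetic (or real) cohort through the static pipeline
#'
#' For each patient and visit: fit the terminal exponential to the venous
#' samples, reconstruct the semi-population input function, integrate it
#' to the scan time, and convert each lesion's C_bone(T) to a static-Patlak
#' Ki.  Returns one row per lesion with baseline/week-8 Ki and SUV, ready
#' for [classify_response()].
#'
#' @param cohort A [generate_cohort()] result, or a list with `lesions`,
#'   `venous` and `patients` data.frames in the same schemas.
#' @param pop A [population_input_function()].
#' @param V0 Patlak intercept used by [static_ki()]. Default 0.40.
#' @param residual_scale Residual scaling mode of [reconstruct_input()];
#'   the default here is `"terminal-ratio"` because simulated patients
#'   differ from the population curve by a global scale.
#' @param scan_time_min Scan time T, minutes. Default 60.
#' @return data.frame with per-lesion `ki`, `suv_max`, `suv_mean`
#'   baseline/week8 columns and the per-visit input-function summaries.
#' @export
quantify_cohort <- function(cohort, pop = population_input_function(),
                            V0 = 0.40, residual_scale = "terminal-ratio",
                            scan_time_min = 60) {
  les <- cohort$lesions
  ven <- cohort$venous
  out <- NULL
  for (p in unique(les$patient_id)) {
    row <- list(patient_id = p)
    for (visit in c("baseline", "week8")) {
      v <- ven[ven$patient_id == p & ven$visit == visit, ]
      if (nrow(v) < 2L) stop("patient ", p, " lacks venous samples at ", visit, call. = FALSE)
      te <- fit_terminal_exponential(lapply(seq_len(nrow(v)), function(i) {
        venous_sample(v$time_min[i], v$kBq_per_mL[i])
      }))
      cp <- reconstruct_input(te, pop, residual_scale = residual_scale)
      icp <- integrate_plasma(cp, scan_time_min)
      cpT <- tac_at(cp, scan_time_min)
      l <- les[les$patient_id == p & les$visit == visit, ]
      ki <- static_ki(l$C_bone_T_kBq_mL, cpT, icp, V0 = V0)
      out <- rbind(out, data.frame(
        patient_id = p, lesion_id = l$lesion_id, visit = visit,
        ki = ki, suv_max = l$suv_max, suv_mean = l$suv_mean,
        volume_cm3 = l$volume_cm3,
        cp_T = cpT, integral_cp = icp))
    }
  }
  # pivot to one row per lesion with *_baseline / *_week8 columns
  b <- out[out$visit == "baseline", ]
  w <- out[out$visit == "week8", ]
  m <- merge(b, w, by = c("patient_id", "lesion_id"),
             suffixes = c("_baseline", "_week8"))
  m[order(m$patient_id, m$lesion_id), setdiff(names(m), c("visit_baseline", "visit_week8"))]
}

#' Generate a Gaussian-blob lesion phantom
#'
#' A small 3-D voxel grid holding one isotropic Gaussian lesion on a flat
#' background, for exercising [segment_lesion()] and the SUV operators.
#' The set of voxels at or above a fraction f of the peak is analytically
#' the ball of radius \eqn{\sigma \sqrt{2 \ln(1/f)}} voxels (for zero
#' background), so the 40% threshold corresponds to
#' \eqn{\sigma \sqrt{2 \ln 2.5}}.
#'
#' @param peak_kBq_mL Peak lesion concentration, kBq/mL.
#' @param grid_shape Integer dimensions of the image. Default
#'   `c(25, 25, 25)`.
#' @param sigma_vox Gaussian sigma in voxel units. Default 2.5.
#' @param center Voxel index triple of the blob centre; default the grid
#'   centre.
#' @param background Flat background level, kBq/mL. Default 0.
#' @param voxel_volume Voxel volume, mL. Default 0.064.
#' @return List: `image` (3-D array), `seed_voxel` (= centre), `sigma_vox`,
#'   `voxel_volume`, and `threshold_radius_vox` for the 40% level set.
#' @export
generate_phantom <- function(peak_kBq_mL, grid_shape = c(25, 25, 25),
                             sigma_vox = 2.5, center = NULL,
                             background = 0, voxel_volume = 0.064) {
  if (is.null(center)) center <- ceiling(grid_shape / 2)
  r40 <- sigma_vox * sqrt(2 * log(1 / 0.4))
  if (any(center - r40 < 1) || any(center + r40 > grid_shape)) {
    stop("geometry error: lesion does not fit in the grid", call. = FALSE)
  }
  idx <- expand.grid(i = seq_len(grid_shape[1]),
                     j = seq_len(grid_shape[2]),
                     k = seq_len(grid_shape[3]))
  r2 <- (idx$i - center[1])^2 + (idx$j - center[2])^2 + (idx$k - center[3])^2
  img <- array(background + peak_kBq_mL * exp(-r2 / (2 * sigma_vox^2)),
               dim = grid_shape)
  list(image = img, seed_voxel = as.integer(center), sigma_vox = sigma_vox,
       voxel_volume = voxel_volume, threshold_radius_vox = r40)
}
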