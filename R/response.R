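#' Select index lesions
#'
#' Applies the index-lesion rule: keep lesions that are both hot
#' (`SUV_max >= suv_min`) and large (equivalent-sphere diameter from the
#' ROI volume `>= diameter_min_cm`), rank by `SUV_max` descending (ties:
#' larger volume, then lexical `lesion_id`), and keep at most `max_n`.
#'
#' @param lesions data.frame with columns `lesion_id`, `suv_max`,
#'   `volume_cm3`.
#' @param max_n Maximum number of index lesions. Default 5.
#' @param suv_min Minimum `SUV_max`. Default 10.
#' @param diameter_min_cm Minimum equivalent-sphere diameter, cm.
#'   Default 1.
#' @return The selected rows, ordered by rank.  Zero eligible lesions
#'   raises a warning (the patient is excluded from lesion-level
#'   statistics) and returns an empty data.frame.
#' @export
select_index_lesions <- function(lesions, max_n = 5, suv_min = 10,
                                 diameter_min_cm = 1) {
  stopifnot(all(c("lesion_id", "suv_max", "volume_cm3") %in% names(lesions)))
  d <- sphere_diameter_cm(lesions$volume_cm3)
  elig <- lesions[lesions$suv_max >= suv_min & d >= diameter_min_cm, , drop = FALSE]
  if (nrow(elig) == 0L) {
    warning("no eligible index lesions; patient excluded")
    return(elig)
  }
  o <- order(-elig$suv_max, -elig$volume_cm3, elig$lesion_id)
  elig <- elig[o, , drop = FALSE]
  utils::head(elig, max_n)
}

#' Equivalent-sphere diameter from a volume
#' @param volume_cm3 Volume, cm^3.
#' @return Diameter of the sphere with that volume, cm.
#' @export
sphere_diameter_cm <- function(volume_cm3) {
  2 * (3 * volume_cm3 / (4 * pi))^(1 / 3)
}

#' Percentage change from baseline
#' @param pre_value Baseline value (> 0).
#' @param post_value Follow-up value.
#' @return `100 * (post - pre) / pre`.
#' @export
percent_change <- function(pre_value, post_value) {
  if (any(pre_value <= 0)) stop("baseline value must be > 0", call. = FALSE)
  100 * (post_value - pre_value) / pre_value
}

#' Classify a percentage change as PD / SD / PR
#'
#' Progressive disease (PD) is a change strictly greater than
#' `+threshold_pct`; partial response (PR) strictly less than
#' `-threshold_pct`; stable disease (SD) otherwise (boundary values
#' inclusive).  Non-PD pools SD and PR.
#'
#' @param change Percentage change(s).
#' @param threshold_pct Threshold, percent. Default 25.
#' @return Factor with ordered levels `PR < SD < PD`.
#' @examples
#' classify_change(c(97.5, -28, 20.4, 25))  # PD PR SD SD
#' @export
classify_change <- function(change, threshold_pct = 25) {
  if (any(!is.finite(change))) stop("change must be finite", call. = FALSE)
  cls <- ifelse(change > threshold_pct, "PD",
                ifelse(change < -threshold_pct, "PR", "SD"))
  factor(cls, levels = c("PR", "SD", "PD"), ordered = TRUE)
}

#' Patient-level percentage change
#'
#' The per-patient response value is the arithmetic mean of the per-lesion
#' percentage changes over that patient's index lesions (not the
#' percentage change of the patient-mean values).
#'
#' @param lesion_changes Non-empty numeric vector of per-lesion percentage
#'   changes.
#' @return Mean percentage change.
#' @export
patient_change <- function(lesion_changes) {
  if (length(lesion_changes) == 0L) stop("no lesion changes supplied", call. = FALSE)
  mean(lesion_changes)
}

#' Response classification of a paired lesion table
#'
#' Computes per-lesion and per-patient percentage changes and PD/SD/PR
#' classes for each metric from a lesion table with one row per lesion
#' carrying baseline and week-8 values.
#'
#' @param lesion_table data.frame with columns `patient_id`, `lesion_id`
#'   and, per metric in `metrics`, `<metric>_baseline` and `<metric>_week8`
#'   — or, alternatively, a precomputed `<metric>_pct_change` column.
#' @param metrics Character vector of metric names. Default
#'   `c("ki", "suv_max", "suv_mean")`.
#' @param threshold_pct PD/PR threshold, percent. Default 25.
#' @return List of class `response_result` with data.frames `lesion`
#'   (changes + classes per lesion) and `patient` (mean change + class per
#'   patient), plus the threshold used.
#' @export
classify_response <- function(lesion_table,
                              metrics = c("ki", "suv_max", "suv_mean"),
                              threshold_pct = 25) {
  stopifnot(is.data.frame(lesion_table), "patient_id" %in% names(lesion_table))
  lesion <- lesion_table[, intersect(c("patient_id", "lesion_id"),
                                     names(lesion_table)), drop = FALSE]
  for (m in metrics) {
    pc_col <- paste0(m, "_pct_change")
    if (pc_col %in% names(lesion_table)) {
      pc <- lesion_table[[pc_col]]
    } else {
      b <- lesion_table[[paste0(m, "_baseline")]]
      w <- lesion_table[[paste0(m, "_week8")]]
      if (is.null(b) || is.null(w)) {
        stop("lesion table lacks columns for metric '", m, "'", call. = FALSE)
      }
      pc <- percent_change(b, w)
    }
    lesion[[pc_col]] <- pc
    lesion[[paste0(m, "_class")]] <- classify_change(pc, threshold_pct)
  }
  pid <- unique(lesion$patient_id)
  patient <- data.frame(patient_id = pid)
  for (m in metrics) {
    pc <- vapply(pid, function(p) {
      patient_change(lesion[[paste0(m, "_pct_change")]][lesion$patient_id == p])
    }, numeric(1))
    patient[[paste0(m, "_pct_change")]] <- pc
    patient[[paste0(m, "_class")]] <- classify_change(pc, threshold_pct)
  }
  structure(list(lesion = lesion, patient = patient,
                 metrics = metrics, threshold_pct = threshold_pct),
            class = "response_result")
}

#' @export
print.response_result <- function(x, ...) {
  cat(sprintf("Response result: %d lesions, %d patients, threshold %g%%\n",
              nrow(x$lesion), nrow(x$patient), x$threshold_pct))
  invisible(x)
}

#' Cohort summary statistics
#'
#' Group means and SDs of percentage change per metric for PD and non-PD
#' patients, Pearson correlations between Ki and SUV metrics, paired
#' t-tests baseline vs week 8 (log-transforming first when a Shapiro-Wilk
#' check at alpha = 0.05 rejects normality of the paired differences and
#' all values are positive), and a two-sample t-test of percentage change
#' PD vs non-PD.  All p-values two-sided; no multiplicity adjustment.
#'
#' @param result A [classify_response()] result.
#' @param reference data.frame with columns `patient_id` and
#'   `reference_label` in `{"PD", "non-PD"}`.
#' @param paired_values Optional data.frame with per-observation
#'   `<metric>_baseline` / `<metric>_week8` columns for the paired tests
#'   (e.g. the lesion table); omitted tests are skipped.
#' @return List of class `cohort_summary` with elements `group_stats`,
#'   `correlations`, `paired_tests`, `group_comparison`.
#' @export
cohort_stats <- function(result, reference, paired_values = NULL) {
  stopifnot(inherits(result, "response_result"))
  pat <- merge(result$patient, reference, by = "patient_id")
  ref <- pat$reference_label
  if (!all(ref %in% c("PD", "non-PD"))) {
    stop("reference labels must be 'PD' or 'non-PD'", call. = FALSE)
  }
  metrics <- result$metrics

  group_stats <- do.call(rbind, lapply(metrics, function(m) {
    pc <- pat[[paste0(m, "_pct_change")]]
    do.call(rbind, lapply(c("PD", "non-PD"), function(g) {
      x <- pc[ref == g]
      data.frame(metric = m, group = g, n = length(x),
                 mean_pct_change = mean(x),
                 sd_pct_change = if (length(x) > 1) stats::sd(x) else NA_real_)
    }))
  }))

  # Pearson r between Ki and each SUV metric on the percent-change scale,
  # patient level; lesion level too when lesion changes are available
  correlations <- NULL
  if ("ki" %in% metrics) {
    for (m in setdiff(metrics, "ki")) {
      for (lvl in c("patient", "lesion")) {
        d <- result[[lvl]]
        x <- d[["ki_pct_change"]]
        y <- d[[paste0(m, "_pct_change")]]
        r <- tryCatch(stats::cor.test(x, y), error = function(e) NULL)
        correlations <- rbind(correlations, data.frame(
          comparison = paste0("ki_vs_", m), level = lvl,
          r = if (is.null(r)) NA_real_ else unname(r$estimate),
          p = if (is.null(r)) NA_real_ else r$p.value))
      }
    }
  }

  paired_tests <- NULL
  if (!is.null(paired_values)) {
    paired_tests <- do.call(rbind, lapply(metrics, function(m) {
      b <- paired_values[[paste0(m, "_baseline")]]
      w <- paired_values[[paste0(m, "_week8")]]
      if (is.null(b) || is.null(w)) return(NULL)
      lt <- needs_log_transform(w - b) && all(b > 0) && all(w > 0)
      if (lt) { b <- log(b); w <- log(w) }
      tt <- stats::t.test(w, b, paired = TRUE)
      data.frame(metric = m, log_transformed = lt,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }))
  }

  group_comparison <- do.call(rbind, lapply(metrics, function(m) {
    pc <- pat[[paste0(m, "_pct_change")]]
    x <- pc[ref == "PD"]; y <- pc[ref == "non-PD"]
    if (length(x) < 2 || length(y) < 2) {
      stop("need >= 2 patients per group for group comparisons", call. = FALSE)
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      warning("degenerate variance in group comparison for ", m)
      return(data.frame(metric = m, mean_PD = mean(x), mean_nonPD = mean(y),
                        t = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(x, y)
    data.frame(metric = m, mean_PD = mean(x), mean_nonPD = mean(y),
               t = unname(tt$statistic), p = tt$p.value)
  }))

  structure(list(group_stats = group_stats, correlations = correlations,
                 paired_tests = paired_tests,
                 group_comparison = group_comparison),
            class = "cohort_summary")
}

# Shapiro-Wilk gate at alpha = 0.05; degenerate vectors count as "normal"
needs_log_transform <- function(x, alpha = 0.05) {
  if (length(unique(x)) < 3L || length(x) < 3L) return(FALSE)
  stats::shapiro.test(x)$p.value < alpha
}

#' Patient-level confusion counts against the reference standard
#'
#' For each metric: how many reference-PD patients the metric classifies
#' PD (true positives), how many reference-non-PD patients it classifies
#' SD or PR (true negatives), and how many reference-non-PD patients it
#' calls PD (false positives).
#'
#' @param result A [classify_response()] result.
#' @param reference data.frame with `patient_id`, `reference_label`.
#' @return data.frame with one row per metric: `n_PD`, `n_nonPD`,
#'   `identified_PD`, `identified_nonPD`, `false_positive`.
#' @export
confusion_counts <- function(result, reference) {
  stopifnot(inherits(result, "response_result"))
  pat <- merge(result$patient, reference, by = "patient_id")
  ref <- pat$reference_label
  do.call(rbind, lapply(result$metrics, function(m) {
    cls <- pat[[paste0(m, "_class")]]
    data.frame(metric = m,
               n_PD = sum(ref == "PD"),
               n_nonPD = sum(ref == "non-PD"),
               identified_PD = sum(ref == "PD" & cls == "PD"),
               identified_nonPD = sum(ref == "non-PD" & cls != "PD"),
               false_positive = sum(ref == "non-PD" & cls == "PD"))
  }))
}
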