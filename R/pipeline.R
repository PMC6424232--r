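#' Pipeline configuration
#'
#' Bundles every constant of the static-Ki response pipeline: the
#' population input-function terms, the Patlak intercept V0, the response
#' threshold, index-lesion rules, isotope half-life, scan time and RNG
#' seed.  Serializes round-trip stably to JSON.
#'
#' @param popif_terms Population input-function (amplitude, rate) rows;
#'   default the packaged tri-exponential.
#' @param V0 Patlak intercept. Default 0.40.
#' @param threshold_pct PD/PR threshold, percent. Default 25.
#' @param max_index_lesions,suv_min,diameter_min_cm Index-lesion rules.
#' @param half_life_min Isotope half-life, minutes. Default 109.77 (18F).
#' @param scan_time_min Uptake time T, minutes. Default 60.
#' @param residual_scale Residual scaling mode for input reconstruction.
#' @param seed RNG seed recorded in reports. Default 1.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(popif_terms = NULL, V0 = 0.40, threshold_pct = 25,
                            max_index_lesions = 5, suv_min = 10,
                            diameter_min_cm = 1, half_life_min = 109.77,
                            scan_time_min = 60,
                            residual_scale = "terminal-ratio", seed = 1) {
  if (is.null(popif_terms)) popif_terms <- default_popif_terms()
  popif_terms <- as.matrix(popif_terms)
  stopifnot(threshold_pct > 0, max_index_lesions > 0, suv_min > 0,
            diameter_min_cm > 0, half_life_min > 0, scan_time_min > 0)
  structure(list(popif_terms = popif_terms, V0 = V0,
                 threshold_pct = threshold_pct,
                 max_index_lesions = max_index_lesions, suv_min = suv_min,
                 diameter_min_cm = diameter_min_cm,
                 half_life_min = half_life_min, scan_time_min = scan_time_min,
                 residual_scale = residual_scale, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#' @param path File path.
#' @return `read_pipeline_config` returns a [pipeline_config()];
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    popif_terms = cfg$popif_terms,
    V0 = cfg$V0 %||% 0.40,
    threshold_pct = cfg$threshold_pct %||% 25,
    max_index_lesions = cfg$max_index_lesions %||% 5,
    suv_min = cfg$suv_min %||% 10,
    diameter_min_cm = cfg$diameter_min_cm %||% 1,
    half_life_min = cfg$half_life_min %||% 109.77,
    scan_time_min = cfg$scan_time_min %||% 60,
    residual_scale = cfg$residual_scale %||% "terminal-ratio",
    seed = cfg$seed %||% 1
  )
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$popif_terms <- unname(apply(config$popif_terms, 1, as.numeric, simplify = FALSE))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full response pipeline on a lesion table
#'
#' Classifies per-lesion and per-patient response with
#' [classify_response()], and, when reference labels are supplied, adds
#' cohort statistics and confusion counts.  The report is deterministic
#' for fixed inputs and carries a hash of the configuration.
#'
#' @param config A [pipeline_config()].
#' @param lesion_table Lesion table (see [classify_response()]).
#' @param reference Optional data.frame `patient_id`, `reference_label`.
#' @return List of class `pipeline_report` with sections `config_hash`,
#'   `seed`, `lesion`, `patient`, and (with a reference) `cohort` and
#'   `confusion`.
#' @export
run_pipeline <- function(config, lesion_table, reference = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.data.frame(lesion_table) || nrow(lesion_table) == 0L) {
    stop("validation error: empty or invalid lesion table", call. = FALSE)
  }
  res <- classify_response(lesion_table, threshold_pct = config$threshold_pct)
  report <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    threshold_pct = config$threshold_pct,
    lesion = res$lesion,
    patient = res$patient
  )
  if (!is.null(reference)) {
    if (!all(c("patient_id", "reference_label") %in% names(reference))) {
      stop("validation error: reference needs patient_id, reference_label",
           call. = FALSE)
    }
    stats <- cohort_stats(res, reference, paired_values = lesion_table)
    report$cohort <- list(
      group_stats = stats$group_stats,
      correlations = stats$correlations,
      paired_tests = stats$paired_tests,
      group_comparison = stats$group_comparison
    )
    report$confusion <- confusion_counts(res, reference)
  }
  structure(report, class = "pipeline_report")
}

# small deterministic config digest (djb2 over the JSON serialization);
# identifies the config in reports without a crypto dependency
config_hash <- function(config) {
  x <- unclass(config)
  x$popif_terms <- as.numeric(config$popif_terms)
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Write a pipeline report
#'
#' JSON body plus per-lesion and per-patient CSVs next to it.  Bodies are
#' byte-identical across runs on identical inputs (no timestamps).
#'
#' @param report A [run_pipeline()] result.
#' @param path Output JSON path; CSVs are written alongside with
#'   `_lesion.csv` / `_patient.csv` suffixes.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", factor = "string")
  stem <- sub("\\.json$", "", path)
  utils::write.csv(report$lesion, paste0(stem, "_lesion.csv"), row.names = FALSE)
  utils::write.csv(report$patient, paste0(stem, "_patient.csv"), row.names = FALSE)
  invisible(path)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic cohort), `quantify`
#' (venous samples + lesion concentrations -> Ki/SUV lesion table),
#' `classify` (lesion table + reference labels -> response report),
#' `report` (print a human-readable summary of a report JSON) and
#' `fixtures` (print the packaged fixture paths).  Returns the exit
#' status (0 success, 2 validation error, 1 internal error) instead of
#' quitting, so it is scriptable and testable; wrap with
#' `quit(status = ki_cli())` in a launcher script.
#'
#' @param args Character vector of arguments; defaults to the command
#'   line.
#' @return Integer exit status, invisibly.
#' @export
ki_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) {
      cat("usage: fluorideKi <simulate|quantify|classify|report|fixtures> [flags]\n")
      return(invisible(2L))
    }
    cmd <- args[1]
    flags <- parse_flags(args[-1])
    switch(cmd,
      simulate = cli_simulate(flags),
      quantify = cli_quantify(flags),
      classify = cli_classify(flags),
      report = cli_report(flags),
      fixtures = cli_fixtures(flags),
      { message("unknown subcommand: ", cmd); 2L }
    )
  },
  validation_error = function(e) { message("error: ", conditionMessage(e)); 2L },
  error = function(e) { message("internal error: ", conditionMessage(e)); 1L })
  invisible(status)
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

validation_error <- function(...) {
  stop(structure(class = c("validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

need_flag <- function(flags, name) {
  if (is.null(flags[[name]])) validation_error("missing required flag --", name)
  flags[[name]]
}

cli_simulate <- function(flags) {
  out <- need_flag(flags, "out")
  seed <- as.integer(flags$seed %||% 1)
  spec <- if (!is.null(flags$spec)) do.call(cohort_spec, jsonlite::read_json(flags$spec, simplifyVector = TRUE)) else cohort_spec()
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(spec, seed)
  hdr <- function(path) writeLines(sprintf("# seed=%d", seed), path)
  for (nm in c("patients", "lesions", "venous", "truth")) {
    path <- file.path(out, paste0(nm, ".csv"))
    hdr(path)
    suppressWarnings(utils::write.table(cohort[[nm]], path, append = TRUE,
                                        sep = ",", row.names = FALSE, quote = FALSE))
  }
  message("wrote cohort (seed ", seed, ") to ", out)
  0L
}

read_cohort_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

cli_quantify <- function(flags) {
  dir <- need_flag(flags, "cohort")
  out <- need_flag(flags, "out")
  for (f in c("lesions.csv", "venous.csv", "patients.csv")) {
    if (!file.exists(file.path(dir, f))) validation_error("missing ", f, " in ", dir)
  }
  cfg <- if (!is.null(flags$config)) read_pipeline_config(flags$config) else pipeline_config()
  cohort <- list(lesions = read_cohort_csv(file.path(dir, "lesions.csv")),
                 venous = read_cohort_csv(file.path(dir, "venous.csv")),
                 patients = read_cohort_csv(file.path(dir, "patients.csv")))
  pop <- population_input_function(cfg$popif_terms)
  tab <- quantify_cohort(cohort, pop, V0 = cfg$V0,
                         residual_scale = cfg$residual_scale,
                         scan_time_min = cfg$scan_time_min)
  utils::write.csv(tab, out, row.names = FALSE)
  message("wrote lesion table to ", out)
  0L
}

cli_classify <- function(flags) {
  lt_path <- need_flag(flags, "lesion-table")
  out <- need_flag(flags, "out")
  if (!file.exists(lt_path)) validation_error("no such file: ", lt_path)
  lesion_table <- utils::read.csv(lt_path)
  if (nrow(lesion_table) == 0L) validation_error("empty lesion table: ", lt_path)
  reference <- NULL
  if (!is.null(flags$reference)) {
    if (!file.exists(flags$reference)) validation_error("no such file: ", flags$reference)
    reference <- utils::read.csv(flags$reference)
  }
  cfg <- if (!is.null(flags$config)) read_pipeline_config(flags$config) else pipeline_config()
  if (!is.null(flags[["threshold-pct"]])) {
    cfg$threshold_pct <- as.numeric(flags[["threshold-pct"]])
  }
  report <- tryCatch(run_pipeline(cfg, lesion_table, reference),
                     error = function(e) validation_error(conditionMessage(e)))
  write_report(report, out)
  message("wrote report to ", out)
  0L
}

cli_report <- function(flags) {
  path <- need_flag(flags, "report")
  if (!file.exists(path)) validation_error("no such file: ", path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  cat(sprintf("Report (config %s, threshold %g%%)\n", rep$config_hash, rep$threshold_pct))
  if (!is.null(rep$confusion)) {
    cat("Patient-level confusion counts:\n")
    print(rep$confusion)
  }
  if (!is.null(rep$cohort$group_stats)) {
    cat("Group percent-change statistics:\n")
    print(rep$cohort$group_stats)
  }
  0L
}

cli_fixtures <- function(flags) {
  paths <- c(
    table3 = system.file("extdata", "table3_patients.csv", package = "fluorideKi"),
    reference = system.file("extdata", "table3_reference.csv", package = "fluorideKi"),
    popif = system.file("extdata", "population_if.json", package = "fluorideKi")
  )
  for (nm in names(paths)) cat(nm, ": ", paths[[nm]], "\n", sep = "")
  0L
}
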