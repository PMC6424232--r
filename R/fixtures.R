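#' Packaged reference-cohort fixture
#'
#' Per-patient summary values of a published 12-patient endocrine-therapy
#' cohort (4 clinically progressive, 8 non-progressive): baseline and
#' week-8 Ki (mL min^-1 mL^-1), SUVmax and SUVmean (g/mL), and the printed
#' per-patient percentage changes (each the mean over that patient's index
#' lesions, which is why a printed change can differ from the ratio of the
#' printed, rounded visit means).  Used as a regression fixture for the
#' response pipeline.
#'
#' @return List with data.frames `lesion_table` (one aggregated row per
#'   patient, suitable for [classify_response()]) and `reference`
#'   (clinical reference-standard labels).
#' @export
table3_cohort <- function() {
  lt <- utils::read.csv(system.file("extdata", "table3_patients.csv",
                                    package = "fluorideKi"))
  ref <- utils::read.csv(system.file("extdata", "table3_reference.csv",
                                     package = "fluorideKi"))
  list(lesion_table = lt, reference = ref)
}
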