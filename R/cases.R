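# Per-artery case records: the packaged six-patient tables and helpers.

PATIENT_CASES_MD5 <- "0e882eb092b3f39ff38e1472d5237727"

#' Load the packaged per-artery case records
#'
#' Returns the twelve renal-artery records of the six F/B EVAR patients:
#' tilt angle (degrees), entry depth (mm), branch stent diameter (mm),
#' aortic stent diameter (mm) and follow-up patency. The `flow` column is
#' `NA` on load; it is filled either by simulation ([surrogate_flow()] /
#' [reconstruct_case_flows()]) or by the user.
#'
#' @return Data frame with columns `patient_id`, `side`, `tilt_angle`,
#'   `entry_depth`, `branch_diameter`, `aortic_diameter`, `patency`,
#'   `flow`.
#' @export
load_patient_cases <- function() {
  path <- system.file("extdata", "patient_cases.csv", package = "branchflow",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, PATIENT_CASES_MD5)) {
    stop("patient_cases.csv checksum mismatch: fixture has been altered",
         call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 12)
  df$flow <- NA_real_
  df
}

#' Tilt-angle ranges by patency
#'
#' The maximum tilt angle among occluded arteries and the minimum among
#' patent arteries — the separation the case series exhibits.
#'
#' @param records case records with `tilt_angle` and `patency`.
#' @return Named vector `occluded_max`, `patent_min`.
#' @export
patency_angle_ranges <- function(records) {
  stopifnot(all(c("tilt_angle", "patency") %in% names(records)))
  c(occluded_max = max(records$tilt_angle[records$patency == "occluded"]),
    patent_min = min(records$tilt_angle[records$patency == "patent"]))
}
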