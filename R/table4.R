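#' Reconstruct the published flow-group membership
#'
#' The case series' differential analysis prints only group summaries
#' (tilt-angle medians 126.9 and 86.5 degrees and an exact Mann-Whitney
#' p of 0.004), not which artery fell in which flow group. The published
#' simulation states that exactly the occluded arteries were in reflux,
#' which puts all four of them in the low-flow group; the two patent
#' arteries completing that group are recovered here by constraint
#' search: among all choose(8, 2) completions, keep those whose
#' tilt-angle group medians and exact Mann-Whitney p-value round to the
#' published values. The search shows this membership is unique, which is
#' what makes the published medians and p recomputable from the case
#' tables at all.
#'
#' Note the published quartiles are *not* consistent with this (or any
#' single) membership, so they are not used as constraints.
#'
#' @param records case records from [load_patient_cases()].
#' @param median_high,median_low published tilt-angle group medians,
#'   degrees.
#' @param p_published published two-sided exact Mann-Whitney p (3 dp).
#' @return List with `low` and `high` record subsets and `n_candidates`,
#'   the number of memberships consistent with the constraints (1 when
#'   unique). Errors if no or several memberships match.
#' @export
reconstruct_table4_membership <- function(records, median_high = 126.9,
                                          median_low = 86.5,
                                          p_published = 0.004) {
  stopifnot(all(c("tilt_angle", "patency") %in% names(records)))
  occ <- which(records$patency == "occluded")
  pat <- which(records$patency == "patent")
  n_low <- nrow(records) / 2
  need <- n_low - length(occ)
  stopifnot(need >= 1, length(pat) >= need)
  combos <- utils::combn(pat, need)
  hits <- list()
  for (k in seq_len(ncol(combos))) {
    low_idx <- c(occ, combos[, k])
    hi_idx <- setdiff(seq_len(nrow(records)), low_idx)
    lo <- records$tilt_angle[low_idx]
    hi <- records$tilt_angle[hi_idx]
    if (round(stats::median(lo), 1) != median_low) next
    if (round(stats::median(hi), 1) != median_high) next
    p <- exact_mann_whitney(lo, hi)$p
    if (round(p, 3) != p_published) next
    hits[[length(hits) + 1L]] <- low_idx
  }
  if (length(hits) == 0) {
    stop("no membership reproduces the published group summary", call. = FALSE)
  }
  if (length(hits) > 1) {
    stop(sprintf("membership not unique: %d candidates match", length(hits)),
         call. = FALSE)
  }
  low_idx <- hits[[1]]
  list(low = records[low_idx, , drop = FALSE],
       high = records[-low_idx, , drop = FALSE],
       n_candidates = length(hits))
}
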