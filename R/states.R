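#' Health states of the AAA screening cohort model
#'
#' The model tracks an AAA (abdominal aortic aneurysm) cohort over twelve
#' internal states. The published structure has eleven mutually exclusive
#' statuses; internally the detected-large status is split into an operable
#' track (proceeds to elective repair) and an inoperable track
#' (contraindicated for surgery, keeps the untreated rupture rate).
#' [aggregate_states()] merges the two back into the eleven reporting
#' statuses.
#'
#' @return `aaa_states()` returns the character vector of internal state
#'   names, in model order.
#' @export
aaa_states <- function() {
  c("no_aaa",
    "undet_small", "undet_medium", "undet_large",
    "det_small", "det_medium",
    "det_large_operable", "det_large_inoperable",
    "post_evar", "post_osr",
    "death_aaa", "death_other")
}

#' @rdname aaa_states
#' @return `aaa_states_reported()` returns the eleven published status names.
#' @export
aaa_states_reported <- function() {
  c("no_aaa",
    "undet_small", "undet_medium", "undet_large",
    "det_small", "det_medium", "det_large",
    "post_evar", "post_osr",
    "death_aaa", "death_other")
}

# states in which the cohort member is alive
living_states <- function() {
  setdiff(aaa_states(), c("death_aaa", "death_other"))
}

#' Aggregate internal occupancy to the eleven published statuses
#'
#' @param occupancy a named vector or matrix (columns named by
#'   [aaa_states()]) of state occupancy.
#' @return occupancy over [aaa_states_reported()], with the operable and
#'   inoperable detected-large tracks summed into `det_large`.
#' @export
aggregate_states <- function(occupancy) {
  if (is.matrix(occupancy)) {
    stopifnot(identical(colnames(occupancy), aaa_states()))
    out <- occupancy[, setdiff(aaa_states(), c("det_large_operable", "det_large_inoperable")), drop = FALSE]
    det_large <- occupancy[, "det_large_operable"] + occupancy[, "det_large_inoperable"]
    out <- cbind(out, det_large = det_large)
    out[, aaa_states_reported(), drop = FALSE]
  } else {
    stopifnot(identical(names(occupancy), aaa_states()))
    out <- occupancy[setdiff(aaa_states(), c("det_large_operable", "det_large_inoperable"))]
    out["det_large"] <- occupancy["det_large_operable"] + occupancy["det_large_inoperable"]
    out[aaa_states_reported()]
  }
}
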