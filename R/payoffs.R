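# Costs and utilities attached to states and events.
# Surveillance of detected aneurysms is a per-cycle state cost; screening,
# repair and reoperation are event costs attached to flows.

#' Per-cycle cost of occupying a state
#'
#' Only detected small and medium aneurysms carry a recurring cost
#' (ultrasound surveillance); surgery and screening are event costs.
#'
#' @param state a state name from [aaa_states()].
#' @param params an [aaa_parameters()] object.
#' @return cost in US$ per cycle of occupancy.
#' @export
cycle_state_cost <- function(state, params) {
  if (!state %in% aaa_states()) {
    stop(sprintf("unknown state '%s'", state), call. = FALSE)
  }
  p <- parameter_points(params)
  switch(state,
         det_small = p$cost_followup_small_per_cycle,
         det_medium = p$cost_followup_medium_per_cycle,
         0)
}

#' Outcome distribution of aneurysm repair
#'
#' Repair is a mixture over procedure (EVAR vs OSR, setting-specific mix)
#' followed by 30-day survival; 30-day deaths count as death from AAA
#' within the surgery cycle.
#'
#' @param setting `"elective"` or `"emergency"`.
#' @param params an [aaa_parameters()] object, or a plain list of point
#'   values from [parameter_points()].
#' @return named probability vector over `post_evar`, `post_osr`,
#'   `death_aaa`, summing to 1.
#' @examples
#' surgery_outcome("elective", aaa_parameters())
#' @export
surgery_outcome <- function(setting = c("elective", "emergency"), params) {
  setting <- match.arg(setting)
  p <- if (inherits(params, "aaa_parameters")) parameter_points(params) else params
  if (setting == "elective") {
    evar <- p$prop_evar_elective
    d_evar <- p$p_death_elective_evar; d_osr <- p$p_death_elective_osr
  } else {
    evar <- p$prop_evar_emergency
    d_evar <- p$p_death_emergency_evar; d_osr <- p$p_death_emergency_osr
  }
  c(post_evar = evar * (1 - d_evar),
    post_osr = (1 - evar) * (1 - d_osr),
    death_aaa = evar * d_evar + (1 - evar) * d_osr)
}

#' Expected reoperation cost per cycle in a post-operative state
#'
#' Reoperation probabilities are published per year for a limited window
#' after the index repair (two years post-EVAR, one year post-OSR). Within
#' the window the annual probability is converted to the cycle length and
#' multiplied by the matching procedure cost; outside the window the cost is
#' zero. Reoperation affects cost only (no state change or added mortality).
#'
#' @param state `"post_evar"` or `"post_osr"`.
#' @param years_since_operation elapsed time since the index repair, years.
#' @param params an [aaa_parameters()] object.
#' @return expected cost in US$ for one cycle spent in the state.
#' @export
expected_reoperation_cost <- function(state, years_since_operation, params) {
  if (!state %in% c("post_evar", "post_osr")) {
    stop(sprintf("'%s' is not a post-operative state", state), call. = FALSE)
  }
  p <- parameter_points(params)
  if (state == "post_evar") {
    window <- p$reop_window_years_evar
    p_annual <- p$p_reop_evar_annual
    cost <- p$cost_evar
  } else {
    window <- p$reop_window_years_osr
    p_annual <- p$p_reop_osr_annual
    cost <- p$cost_osr
  }
  if (years_since_operation <= 0 || years_since_operation > window) return(0)
  annual_to_cycle_probability(p_annual, p$cycles_per_year) * cost
}

#' EQ-5D utility weight of a state at a given age
#'
#' Living states carry the age-band utility (65-69, 70-74, 75-79, 80+);
#' post-operative states additionally carry the permanent post-repair
#' disutility; death states are 0.
#'
#' @param state a state name from [aaa_states()].
#' @param age current age in years.
#' @param params an [aaa_parameters()] object.
#' @return utility weight for one year lived in the state at that age.
#' @export
cycle_utility <- function(state, age, params) {
  if (!state %in% aaa_states()) {
    stop(sprintf("unknown state '%s'", state), call. = FALSE)
  }
  if (state %in% c("death_aaa", "death_other")) return(0)
  p <- parameter_points(params)
  u <- age_band_utility(age, p)
  if (state %in% c("post_evar", "post_osr")) u <- u + p$disutility_postop
  u
}

age_band_utility <- function(age, p) {
  ifelse(age < 70, p$utility_65_69,
         ifelse(age < 75, p$utility_70_74,
                ifelse(age < 80, p$utility_75_79, p$utility_80_plus)))
}

#' Screening cost per invited cohort member
#'
#' Only attendees incur the ultrasound cost; the no-screening strategy
#' incurs nothing.
#'
#' @param params an [aaa_parameters()] object.
#' @param strategy `"screening"` or `"no_screening"`.
#' @return cost in US$ at cycle 0 per cohort member.
#' @export
screening_event_cost <- function(params, strategy = c("no_screening", "screening")) {
  strategy <- match.arg(strategy)
  if (strategy == "no_screening") return(0)
  p <- parameter_points(params)
  p$attendance * p$cost_screen
}
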