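# Discounting, half-cycle correction, outcome aggregation and incremental
# cost-effectiveness analysis.

#' Discount factor for a model cycle
#'
#' Per-cycle compounding of the annual rate: `(1 + rate)^(-t / cycles_per_year)`
#' with cycle 0 (age 65) undiscounted.
#'
#' @param cycle_index cycle number, 0-based (vectorized).
#' @param annual_rate annual discount rate (>= 0).
#' @param cycles_per_year model cycles per year.
#' @return discount factor(s) in (0, 1].
#' @export
discount_factor <- function(cycle_index, annual_rate, cycles_per_year = 4) {
  if (annual_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle_index / cycles_per_year)
}

#' Half-cycle-corrected occupancy
#'
#' Trapezoidal correction: membership during cycle t is taken as the mean of
#' the occupancy at the start of cycles t and t+1, i.e. states are assumed
#' to change midway through a cycle. Applied to state-based costs and
#' utilities; one-off event costs are dated to their cycle uncorrected.
#'
#' @param occupancy a (cycles+1) x states matrix of start-of-cycle
#'   occupancy (e.g. `trace$occupancy`).
#' @return a cycles x states matrix of corrected within-cycle occupancy.
#' @export
half_cycle_corrected_occupancy <- function(occupancy) {
  if (!is.matrix(occupancy)) occupancy <- as.matrix(occupancy)
  n <- nrow(occupancy)
  if (n < 2) stop("need at least two cycle boundaries", call. = FALSE)
  (occupancy[-n, , drop = FALSE] + occupancy[-1, , drop = FALSE]) / 2
}

#' Aggregate a cohort trace into discounted cost, QALYs and life-years
#'
#' QALYs and life-years accrue on half-cycle-corrected occupancy, weighted
#' by the cycle discount factor and the cycle length in years. Costs
#' combine: surveillance state costs on corrected occupancy; repair costs
#' on the elective/emergency procedure flows at their cycle; expected
#' reoperation costs, convolved from post-operative inflows over the
#' eligible window with other-cause survival; and the screening cost,
#' charged undiscounted at cycle 0.
#'
#' @param trace an `aaa_trace` from [run_cohort()].
#' @param params an [aaa_parameters()] object (must be the set that produced
#'   the trace).
#' @param life_table the `aaa_life_table` used for the run (needed for
#'   survival inside the reoperation window).
#' @param annual_rate discount rate; default the parameter set's.
#' @return an `aaa_result` list: `strategy`, discounted `cost`, `qaly`,
#'   `ly`, and a cost breakdown.
#' @export
aggregate_trace <- function(trace, params, life_table, annual_rate = NULL) {
  p <- parameter_points(params)
  if (is.null(annual_rate)) annual_rate <- p$discount_rate_annual
  cpy <- p$cycles_per_year
  n <- trace$n_cycles
  occ_c <- half_cycle_corrected_occupancy(trace$occupancy)
  d <- discount_factor(seq_len(n) - 1, annual_rate, cpy)
  ages <- trace$age[seq_len(n)]

  # utilities: living states share the age-band utility, post-op states
  # carry the disutility on top
  u_band <- age_band_utility(ages, p)
  living <- living_states()
  live_occ <- rowSums(occ_c[, living, drop = FALSE])
  postop_occ <- occ_c[, "post_evar"] + occ_c[, "post_osr"]
  qaly <- sum(d * (live_occ * u_band + postop_occ * p$disutility_postop)) / cpy
  ly <- sum(d * live_occ) / cpy

  surveillance <- sum(d * (occ_c[, "det_small"] * p$cost_followup_small_per_cycle +
                           occ_c[, "det_medium"] * p$cost_followup_medium_per_cycle))
  fl <- trace$flows
  procedures <- sum(d * ((fl[, "elective_evar"] + fl[, "emergency_evar"]) * p$cost_evar +
                         (fl[, "elective_osr"] + fl[, "emergency_osr"]) * p$cost_osr))
  reop <- reoperation_cost_total(trace, params, life_table, d)
  screening <- screening_event_cost(params, trace$strategy)
  cost <- surveillance + procedures + reop + screening

  structure(list(strategy = trace$strategy, cost = cost, qaly = qaly, ly = ly,
                 breakdown = c(screening = screening, surveillance = surveillance,
                               procedures = procedures, reoperation = reop)),
            class = "aaa_result")
}

# expected discounted reoperation cost: members entering a post-operative
# state at cycle boundary u are eligible for reoperation during the
# following window cycles, surviving other-cause death in between.
reoperation_cost_total <- function(trace, params, life_table, d) {
  p <- parameter_points(params)
  cpy <- p$cycles_per_year
  n <- trace$n_cycles
  ages <- trace$age
  q_cycle <- annual_to_cycle_probability(annual_death_prob(life_table, ages), cpy)
  total <- 0
  for (state in c("post_evar", "post_osr")) {
    inflow_col <- paste0("inflow_", state)
    window_cycles <- round((if (state == "post_evar") p$reop_window_years_evar
                            else p$reop_window_years_osr) * cpy)
    inflow <- trace$flows[, inflow_col]
    for (u in which(inflow > 0)) {
      # present in the state from boundary u+1; reoperation may occur in
      # each of the window cycles, i.e. cycles u+1 .. u+window
      surv <- 1
      for (k in seq_len(window_cycles)) {
        s <- u + k  # 1-based row index of cycle u+k-1... see below
        if (s > n) break
        yrs <- k / cpy
        per_cycle_cost <- expected_reoperation_cost(state, yrs, params)
        total <- total + inflow[u] * surv * per_cycle_cost * d[s]
        surv <- surv * (1 - q_cycle[s])
      }
    }
  }
  total
}

#' Incremental comparison of two strategy results
#'
#' Differences are screening minus comparator; ICERs are reported only for
#' the trade-off quadrants (positive incremental cost and effect, or both
#' negative). Standard dominance rules: cheaper and at least as effective
#' (or equally costly and more effective) is `dominant`; costlier and no
#' more effective is `dominated`.
#'
#' @param screening,comparator `aaa_result` objects from [aggregate_trace()].
#' @return an `aaa_incremental` list: `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `icer_qaly`, `icer_ly` (NA when undefined), `dominance`.
#' @export
incremental <- function(screening, comparator) {
  dc <- screening$cost - comparator$cost
  dq <- screening$qaly - comparator$qaly
  dl <- screening$ly - comparator$ly
  dominance <- if (dc <= 0 && dq >= 0 && (dc < 0 || dq > 0)) "dominant"
               else if (dc >= 0 && dq <= 0 && (dc > 0 || dq < 0)) "dominated"
               else "tradeoff"
  icer_q <- if (dominance == "tradeoff" && dq != 0) dc / dq else NA_real_
  icer_l <- if (dominance == "tradeoff" && dl != 0) dc / dl else NA_real_
  structure(list(delta_cost = dc, delta_qaly = dq, delta_ly = dl,
                 icer_qaly = icer_q, icer_ly = icer_l, dominance = dominance),
            class = "aaa_incremental")
}

#' Convert US$ (official exchange rate) to PPP dollars
#'
#' Costs were collected in Iranian rials and converted at the official rate
#' of 34,212 rials per US$; the purchasing-power-parity rate is 12,993
#' rials per US$. Re-expressing an official-rate dollar amount in PPP
#' dollars multiplies by 34,212 / 12,993.
#'
#' @param amount_usd amount in US$ at the official exchange rate (>= 0).
#' @return the amount in PPP dollars.
#' @examples
#' usd_to_ppp(5566)  # 14655.9
#' @export
usd_to_ppp <- function(amount_usd) {
  if (any(amount_usd < 0, na.rm = TRUE)) stop("amount must be >= 0", call. = FALSE)
  amount_usd * 34212 / 12993
}

#' @export
print.aaa_result <- function(x, ...) {
  cat(sprintf("%s: cost $%.2f, QALY %.4f, LY %.4f\n",
              x$strategy, x$cost, x$qaly, x$ly))
  invisible(x)
}

#' @export
print.aaa_incremental <- function(x, ...) {
  cat(sprintf("incremental (screening - no screening): cost $%.2f, QALY %.4f, LY %.4f\n",
              x$delta_cost, x$delta_qaly, x$delta_ly))
  if (x$dominance == "tradeoff") {
    cat(sprintf("ICER: $%.0f per QALY, $%.0f per LY\n", x$icer_qaly, x$icer_ly))
  } else {
    cat(sprintf("screening is %s\n", x$dominance))
  }
  invisible(x)
}
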