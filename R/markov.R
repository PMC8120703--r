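# One-cycle dynamics of the AAA cohort model.
#
# Within a cycle, events resolve in a fixed order: other-cause death first
# (competing risk), then rupture, then opportunistic detection, then growth,
# then elective repair for occupants of the detected-large operable state.
# The same event decomposition produces both the transition matrix and the
# per-unit-occupancy event-flow coefficients, so costs attach to exactly the
# transitions the matrix encodes.

#' Initial cohort distribution
#'
#' At model start the cohort of 65-year-old men carries AAA prevalence split
#' across the three size classes, all initially undetected. Under the
#' screening strategy, the attending fraction of each undetected aneurysm
#' moves to the matching detected state; detected large aneurysms split into
#' the operable / inoperable (contraindicated) tracks at detection.
#'
#' @param params an [aaa_parameters()] object.
#' @param strategy `"screening"` or `"no_screening"`.
#' @return a named occupancy vector over [aaa_states()], summing to 1.
#' @export
initial_state_vector <- function(params, strategy = c("no_screening", "screening")) {
  strategy <- match.arg(strategy)
  p <- parameter_points(params)
  v <- stats::setNames(numeric(length(aaa_states())), aaa_states())
  prev <- p$prevalence_aaa
  mix <- c(small = p$proportion_small, medium = p$proportion_medium,
           large = p$proportion_large)
  v["no_aaa"] <- 1 - prev
  undet <- prev * mix
  if (strategy == "no_screening") {
    v[c("undet_small", "undet_medium", "undet_large")] <- undet
  } else {
    att <- p$attendance
    v[c("undet_small", "undet_medium", "undet_large")] <- (1 - att) * undet
    v["det_small"] <- att * undet["small"]
    v["det_medium"] <- att * undet["medium"]
    oper <- p$p_elective_surgery_if_large
    v["det_large_operable"] <- att * undet["large"] * oper
    v["det_large_inoperable"] <- att * undet["large"] * (1 - oper)
  }
  v
}

# distribution over (post_evar, post_osr, death_aaa) conditional on rupture:
# a fraction reaches emergency repair, the remainder dies of the rupture.
rupture_destination <- function(p) {
  em <- surgery_outcome("emergency", p)
  pe <- p$p_emergency_surgery_after_rupture
  c(post_evar = pe * em[["post_evar"]],
    post_osr = pe * em[["post_osr"]],
    death_aaa = pe * em[["death_aaa"]] + (1 - pe))
}

# transition rows and flow coefficients conditional on surviving other
# causes; returns list(M = 12x12 conditional matrix, flows = 12 x nflow).
cycle_dynamics <- function(p) {
  st <- aaa_states()
  n <- length(st)
  M <- matrix(0, n, n, dimnames = list(st, st))
  flow_names <- c("rupture", "opportunistic_detection",
                  "elective_evar", "elective_osr",
                  "emergency_evar", "emergency_osr",
                  "periop_death")
  FL <- matrix(0, n, length(flow_names), dimnames = list(st, flow_names))

  rup <- rupture_destination(p)
  el <- surgery_outcome("elective", p)
  oper <- p$p_elective_surgery_if_large
  det <- p$p_opportunistic_detection

  add_rupture <- function(state, pr) {
    M[state, c("post_evar", "post_osr", "death_aaa")] <<-
      M[state, c("post_evar", "post_osr", "death_aaa")] + pr * rup
    FL[state, "rupture"] <<- FL[state, "rupture"] + pr
    FL[state, "emergency_evar"] <<- FL[state, "emergency_evar"] +
      pr * p$p_emergency_surgery_after_rupture * p$prop_evar_emergency
    FL[state, "emergency_osr"] <<- FL[state, "emergency_osr"] +
      pr * p$p_emergency_surgery_after_rupture * (1 - p$prop_evar_emergency)
    FL[state, "periop_death"] <<- FL[state, "periop_death"] +
      pr * p$p_emergency_surgery_after_rupture *
        (p$prop_evar_emergency * p$p_death_emergency_evar +
         (1 - p$prop_evar_emergency) * p$p_death_emergency_osr)
  }
  enter_detected_large <- function(state, mass) {
    M[state, "det_large_operable"] <<- M[state, "det_large_operable"] + mass * oper
    M[state, "det_large_inoperable"] <<- M[state, "det_large_inoperable"] + mass * (1 - oper)
  }

  M["no_aaa", "undet_small"] <- p$p_incidence
  M["no_aaa", "no_aaa"] <- 1 - p$p_incidence

  # undetected small: rupture, then detection, then growth
  pr <- p$p_rupture_small; g <- p$p_small_to_medium
  add_rupture("undet_small", pr)
  sv <- 1 - pr
  M["undet_small", "undet_small"] <- sv * (1 - det) * (1 - g)
  M["undet_small", "undet_medium"] <- sv * (1 - det) * g
  M["undet_small", "det_small"] <- sv * det * (1 - g)
  M["undet_small", "det_medium"] <- sv * det * g
  FL["undet_small", "opportunistic_detection"] <- sv * det

  # undetected medium
  pr <- p$p_rupture_medium; g <- p$p_medium_to_large
  add_rupture("undet_medium", pr)
  sv <- 1 - pr
  M["undet_medium", "undet_medium"] <- sv * (1 - det) * (1 - g)
  M["undet_medium", "undet_large"] <- sv * (1 - det) * g
  M["undet_medium", "det_medium"] <- sv * det * (1 - g)
  enter_detected_large("undet_medium", sv * det * g)
  FL["undet_medium", "opportunistic_detection"] <- sv * det

  # undetected large
  pr <- p$p_rupture_undetected_large
  add_rupture("undet_large", pr)
  sv <- 1 - pr
  M["undet_large", "undet_large"] <- sv * (1 - det)
  enter_detected_large("undet_large", sv * det)
  FL["undet_large", "opportunistic_detection"] <- sv * det

  # detected small (under surveillance)
  pr <- p$p_rupture_small; g <- p$p_small_to_medium
  add_rupture("det_small", pr)
  M["det_small", "det_small"] <- (1 - pr) * (1 - g)
  M["det_small", "det_medium"] <- (1 - pr) * g

  # detected medium
  pr <- p$p_rupture_medium; g <- p$p_medium_to_large
  add_rupture("det_medium", pr)
  M["det_medium", "det_medium"] <- (1 - pr) * (1 - g)
  enter_detected_large("det_medium", (1 - pr) * g)

  # detected large, operable: rupture first, survivors undergo elective repair
  pr <- p$p_rupture_detected_large
  add_rupture("det_large_operable", pr)
  sv <- 1 - pr
  M["det_large_operable", c("post_evar", "post_osr", "death_aaa")] <-
    M["det_large_operable", c("post_evar", "post_osr", "death_aaa")] + sv * el
  FL["det_large_operable", "elective_evar"] <- sv * p$prop_evar_elective
  FL["det_large_operable", "elective_osr"] <- sv * (1 - p$prop_evar_elective)
  FL["det_large_operable", "periop_death"] <-
    FL["det_large_operable", "periop_death"] + sv * el[["death_aaa"]]

  # detected large, contraindicated for surgery
  pr <- p$p_rupture_contraindicated_large
  add_rupture("det_large_inoperable", pr)
  M["det_large_inoperable", "det_large_inoperable"] <- 1 - pr

  M["post_evar", "post_evar"] <- 1
  M["post_osr", "post_osr"] <- 1
  M["death_aaa", "death_aaa"] <- 1
  M["death_other", "death_other"] <- 1

  list(M = M, flows = FL)
}

#' One-cycle transition matrix at a given age
#'
#' Builds the 12-state one-cycle transition matrix: other-cause death (from
#' the life table, converted to the cycle length) applies first as a
#' competing risk; the survivors' mass then follows the AAA event sequence
#' rupture -> opportunistic detection -> growth -> elective repair. Death
#' rows are absorbing. The dynamics are identical across strategies (the
#' strategies differ only in the initial distribution and the screening
#' cost); the `strategy` argument is accepted for interface symmetry.
#'
#' @param params an [aaa_parameters()] object.
#' @param life_table an `aaa_life_table` covering `age`.
#' @param age current integer age.
#' @param strategy `"screening"` or `"no_screening"` (no effect on dynamics).
#' @return a row-stochastic matrix over [aaa_states()].
#' @export
build_transition_matrix <- function(params, life_table, age,
                                    strategy = c("no_screening", "screening")) {
  match.arg(strategy)
  p <- parameter_points(params)
  q <- cycle_other_cause_death_prob(life_table, age, p$cycles_per_year)
  dyn <- cycle_dynamics(p)
  M <- dyn$M * (1 - q)
  M[, "death_other"] <- M[, "death_other"] + q
  M["death_aaa", ] <- 0; M["death_aaa", "death_aaa"] <- 1
  M["death_other", ] <- 0; M["death_other", "death_other"] <- 1
  if (any(M < -1e-15) || any(M > 1 + 1e-15)) {
    stop("transition matrix entry outside [0, 1]; inconsistent parameters",
         call. = FALSE)
  }
  if (any(abs(rowSums(M) - 1) > 1e-12)) {
    stop("transition matrix rows do not sum to 1", call. = FALSE)
  }
  M
}

#' Run the cohort simulation
#'
#' Iterates the cohort from `start_age` over 3-month cycles to the lifetime
#' horizon. One extra closing cycle at the terminal age (where the life
#' table forces q = 1) sends all remaining mass to the death states. Event
#' flows (ruptures, detections, elective and emergency repairs by procedure,
#' perioperative deaths, new post-operative entries) are recorded per cycle
#' so costs can attach to them.
#'
#' @param initial occupancy vector from [initial_state_vector()], or `NULL`
#'   to build it from `params` and `strategy`.
#' @param params an [aaa_parameters()] object.
#' @param life_table an `aaa_life_table` covering the age span.
#' @param strategy `"screening"` or `"no_screening"`.
#' @return an `aaa_trace` object: list with `occupancy` (cycles+1 x 12
#'   matrix; row t is occupancy at the start of cycle t), `flows` (cycles x
#'   flow types, including `screens` at cycle 0 and post-operative inflows),
#'   `age` (age at the start of each cycle), `strategy`, `params`.
#' @export
run_cohort <- function(initial = NULL, params, life_table,
                       strategy = c("no_screening", "screening")) {
  strategy <- match.arg(strategy)
  if (is.null(initial)) initial <- initial_state_vector(params, strategy)
  st <- aaa_states()
  stopifnot(identical(names(initial), st))
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-12) {
    stop("initial occupancy must be nonnegative and sum to 1", call. = FALSE)
  }
  p <- parameter_points(params)
  cpy <- as.integer(p$cycles_per_year)
  n_cycles <- (p$end_age - p$start_age) * cpy + 1L  # + terminal closing cycle

  dyn <- cycle_dynamics(p)
  flow_names <- c(colnames(dyn$flows), "inflow_post_evar", "inflow_post_osr",
                  "screens")
  occ <- matrix(0, n_cycles + 1L, length(st), dimnames = list(NULL, st))
  flows <- matrix(0, n_cycles, length(flow_names),
                  dimnames = list(NULL, flow_names))
  ages <- p$start_age + (seq_len(n_cycles + 1L) - 1L) %/% cpy
  ages <- pmin(ages, p$end_age)

  occ[1L, ] <- initial
  if (strategy == "screening") flows[1L, "screens"] <- p$attendance
  for (t in seq_len(n_cycles)) {
    age <- ages[t]
    q <- cycle_other_cause_death_prob(life_table, age, cpy)
    M <- dyn$M * (1 - q)
    M[, "death_other"] <- M[, "death_other"] + q
    M["death_aaa", ] <- 0; M["death_aaa", "death_aaa"] <- 1
    M["death_other", ] <- 0; M["death_other", "death_other"] <- 1
    cur <- occ[t, ]
    nxt <- drop(cur %*% M)
    flows[t, colnames(dyn$flows)] <- drop(cur %*% (dyn$flows * (1 - q)))
    flows[t, "inflow_post_evar"] <-
      sum(cur[setdiff(st, "post_evar")] * M[setdiff(st, "post_evar"), "post_evar"])
    flows[t, "inflow_post_osr"] <-
      sum(cur[setdiff(st, "post_osr")] * M[setdiff(st, "post_osr"), "post_osr"])
    if (abs(sum(nxt) - 1) > 1e-12) {
      stop(sprintf("cohort mass not conserved at cycle %d", t), call. = FALSE)
    }
    occ[t + 1L, ] <- nxt
  }
  structure(list(occupancy = occ, flows = flows, age = ages,
                 n_cycles = n_cycles, strategy = strategy, params = params),
            class = "aaa_trace")
}

#' @export
print.aaa_trace <- function(x, ...) {
  cat(sprintf("AAA cohort trace: %s strategy, %d cycles (ages %d-%d)\n",
              x$strategy, x$n_cycles, min(x$age), max(x$age)))
  dead <- x$occupancy[nrow(x$occupancy), c("death_aaa", "death_other")]
  cat(sprintf("final occupancy: death from AAA %.5f, other causes %.5f\n",
              dead[1], dead[2]))
  invisible(x)
}

#' Export a cohort trace as a delimited text table
#'
#' One row per cycle: cycle index, age, the eleven published state
#' occupancies (the operable and inoperable detected-large tracks are
#' aggregated), and the event flows.
#'
#' @param trace an `aaa_trace` from [run_cohort()].
#' @param path output file; when `NULL` the data frame is returned only.
#' @return the exported data frame, invisibly when written.
#' @export
export_trace <- function(trace, path = NULL) {
  occ <- aggregate_states(trace$occupancy[seq_len(trace$n_cycles), , drop = FALSE])
  df <- data.frame(cycle = seq_len(trace$n_cycles) - 1L,
                   age = trace$age[seq_len(trace$n_cycles)],
                   occ, trace$flows, check.names = FALSE)
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
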