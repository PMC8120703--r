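# Independent test oracles.
#
# microsim_occupancy() is a discrete-event micro-simulation of the cohort:
# each cycle it applies the event sequence (other-cause death, rupture and
# its emergency pathway, opportunistic detection, growth, elective repair)
# with staged binomial draws over walker counts. It is written directly from
# the model's clinical rules and shares no code with cycle_dynamics() /
# build_transition_matrix(), so agreement between the two is a genuine
# cross-check of the cohort dynamics.

microsim_occupancy <- function(params, life_table, strategy, n_walkers,
                               n_cycles, seed) {
  p <- parameter_points(params)
  st <- aaa_states()
  set.seed(seed)
  counts <- stats::setNames(
    drop(stats::rmultinom(1, n_walkers, initial_state_vector(params, strategy))),
    st)
  occ <- matrix(0, n_cycles + 1, length(st), dimnames = list(NULL, st))
  occ[1, ] <- counts

  rbin <- function(n, prob) if (n == 0) 0L else stats::rbinom(1, n, prob)

  for (t in seq_len(n_cycles)) {
    age <- p$start_age + (t - 1) %/% p$cycles_per_year
    q <- 1 - (1 - annual_death_prob(life_table, age))^(1 / p$cycles_per_year)
    nw <- stats::setNames(integer(length(st)), st)

    rupture_outcome <- function(k) {
      em <- rbin(k, p$p_emergency_surgery_after_rupture)
      nw["death_aaa"] <<- nw["death_aaa"] + (k - em)  # no repair, fatal
      evar <- rbin(em, p$prop_evar_emergency)
      osr <- em - evar
      evar_died <- rbin(evar, p$p_death_emergency_evar)
      osr_died <- rbin(osr, p$p_death_emergency_osr)
      nw["post_evar"] <<- nw["post_evar"] + (evar - evar_died)
      nw["post_osr"] <<- nw["post_osr"] + (osr - osr_died)
      nw["death_aaa"] <<- nw["death_aaa"] + evar_died + osr_died
    }
    enter_detected_large <- function(k) {
      oper <- rbin(k, p$p_elective_surgery_if_large)
      nw["det_large_operable"] <<- nw["det_large_operable"] + oper
      nw["det_large_inoperable"] <<- nw["det_large_inoperable"] + (k - oper)
    }
    elective_repair <- function(k) {
      evar <- rbin(k, p$prop_evar_elective)
      osr <- k - evar
      evar_died <- rbin(evar, p$p_death_elective_evar)
      osr_died <- rbin(osr, p$p_death_elective_osr)
      nw["post_evar"] <<- nw["post_evar"] + (evar - evar_died)
      nw["post_osr"] <<- nw["post_osr"] + (osr - osr_died)
      nw["death_aaa"] <<- nw["death_aaa"] + evar_died + osr_died
    }
    survivors <- function(state) {
      n0 <- counts[[state]]
      died <- rbin(n0, q)
      nw["death_other"] <<- nw["death_other"] + died
      n0 - died
    }

    # absorbing states
    nw["death_aaa"] <- nw["death_aaa"] + counts[["death_aaa"]]
    nw["death_other"] <- nw["death_other"] + counts[["death_other"]]

    a <- survivors("no_aaa")
    inc <- rbin(a, p$p_incidence)
    nw["no_aaa"] <- nw["no_aaa"] + (a - inc)
    nw["undet_small"] <- nw["undet_small"] + inc

    a <- survivors("undet_small")
    rup <- rbin(a, p$p_rupture_small); rupture_outcome(rup)
    det <- rbin(a - rup, p$p_opportunistic_detection)
    und <- (a - rup) - det
    gd <- rbin(det, p$p_small_to_medium)
    gu <- rbin(und, p$p_small_to_medium)
    nw["det_medium"] <- nw["det_medium"] + gd
    nw["det_small"] <- nw["det_small"] + (det - gd)
    nw["undet_medium"] <- nw["undet_medium"] + gu
    nw["undet_small"] <- nw["undet_small"] + (und - gu)

    a <- survivors("undet_medium")
    rup <- rbin(a, p$p_rupture_medium); rupture_outcome(rup)
    det <- rbin(a - rup, p$p_opportunistic_detection)
    und <- (a - rup) - det
    gd <- rbin(det, p$p_medium_to_large)
    gu <- rbin(und, p$p_medium_to_large)
    enter_detected_large(gd)
    nw["det_medium"] <- nw["det_medium"] + (det - gd)
    nw["undet_large"] <- nw["undet_large"] + gu
    nw["undet_medium"] <- nw["undet_medium"] + (und - gu)

    a <- survivors("undet_large")
    rup <- rbin(a, p$p_rupture_undetected_large); rupture_outcome(rup)
    det <- rbin(a - rup, p$p_opportunistic_detection)
    enter_detected_large(det)
    nw["undet_large"] <- nw["undet_large"] + (a - rup - det)

    a <- survivors("det_small")
    rup <- rbin(a, p$p_rupture_small); rupture_outcome(rup)
    g <- rbin(a - rup, p$p_small_to_medium)
    nw["det_medium"] <- nw["det_medium"] + g
    nw["det_small"] <- nw["det_small"] + (a - rup - g)

    a <- survivors("det_medium")
    rup <- rbin(a, p$p_rupture_medium); rupture_outcome(rup)
    g <- rbin(a - rup, p$p_medium_to_large)
    enter_detected_large(g)
    nw["det_medium"] <- nw["det_medium"] + (a - rup - g)

    a <- survivors("det_large_operable")
    rup <- rbin(a, p$p_rupture_detected_large); rupture_outcome(rup)
    elective_repair(a - rup)

    a <- survivors("det_large_inoperable")
    rup <- rbin(a, p$p_rupture_contraindicated_large); rupture_outcome(rup)
    nw["det_large_inoperable"] <- nw["det_large_inoperable"] + (a - rup)

    nw["post_evar"] <- nw["post_evar"] + survivors("post_evar")
    nw["post_osr"] <- nw["post_osr"] + survivors("post_osr")

    stopifnot(sum(nw) == n_walkers)
    counts <- nw
    occ[t + 1, ] <- counts
  }
  occ / n_walkers
}

# trapezoid-free survival oracle: probability of being alive at each cycle
# boundary under other-cause mortality only
survival_oracle <- function(life_table, start_age, end_age, cycles_per_year,
                            n_cycles) {
  ages <- start_age + (seq_len(n_cycles) - 1) %/% cycles_per_year
  ages <- pmin(ages, end_age)
  q <- 1 - (1 - annual_death_prob(life_table, ages))^(1 / cycles_per_year)
  c(1, cumprod(1 - q))
}

# small flat life table for fast unit tests
flat_life_table <- function(q = 0.02, start_age = 65, end_age = 100) {
  qx <- rep(q, end_age - start_age + 1)
  qx[length(qx)] <- 1
  life_table(start_age:end_age, qx)
}

test_life_table <- function() synth_life_table()
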