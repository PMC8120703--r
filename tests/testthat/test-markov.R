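test_that("initial cohort distribution follows prevalence, size mix and attendance", {
  p <- aaa_parameters()
  v <- initial_state_vector(p, "no_screening")
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_equal(v[["no_aaa"]], 0.97)
  expect_equal(v[["undet_small"]], 0.03 * 0.789)
  expect_equal(v[["undet_small"]], 0.023670)
  expect_equal(v[["undet_large"]], 0.03 * 0.091)
  expect_true(all(v[c("det_small", "det_medium", "det_large_operable",
                      "det_large_inoperable")] == 0))

  vs <- initial_state_vector(p, "screening")
  expect_equal(sum(vs), 1, tolerance = 1e-12)
  expect_equal(vs[["det_small"]], 0.75 * 0.023670)
  expect_equal(vs[["det_small"]], 0.0177525)
  expect_equal(vs[["undet_small"]], 0.0059175)
  # detected large splits into operable / contraindicated at detection
  expect_equal(vs[["det_large_operable"]], 0.75 * 0.03 * 0.091 * 0.918)
  expect_equal(vs[["det_large_inoperable"]], 0.75 * 0.03 * 0.091 * 0.082)
  # screening never detects less than no screening
  det_states <- c("det_small", "det_medium", "det_large_operable", "det_large_inoperable")
  expect_gt(sum(vs[det_states]), sum(v[det_states]))

  p0 <- aaa_parameters(prevalence_aaa = list(point = 0, low = 0))
  for (strat in c("no_screening", "screening")) {
    v0 <- initial_state_vector(p0, strat)
    expect_equal(v0[["no_aaa"]], 1)
    expect_equal(sum(v0) - v0[["no_aaa"]], 0)
  }
})

test_that("transition matrices are row-stochastic with absorbing death states", {
  p <- aaa_parameters()
  lt <- test_life_table()
  for (age in c(65, 72, 99, 100)) {
    M <- build_transition_matrix(p, lt, age)
    expect_true(all(M >= 0) && all(M <= 1))
    expect_equal(rowSums(M), stats::setNames(rep(1, 12), aaa_states()),
                 tolerance = 1e-12)
    expect_equal(M["death_aaa", "death_aaa"], 1)
    expect_equal(M["death_other", "death_other"], 1)
  }
})

test_that("all-zero event probabilities and zero mortality give the identity matrix", {
  zero <- list(prevalence_aaa = 0, p_incidence = list(point = 0, low = 0),
               p_small_to_medium = list(point = 0, low = 0),
               p_medium_to_large = list(point = 0, low = 0),
               p_rupture_small = list(point = 0, low = 0),
               p_rupture_medium = list(point = 0, low = 0),
               p_rupture_undetected_large = list(point = 0, low = 0),
               p_rupture_detected_large = list(point = 0, low = 0),
               p_rupture_contraindicated_large = list(point = 0, low = 0),
               p_opportunistic_detection = list(point = 0, low = 0))
  p <- do.call(aaa_parameters, zero)
  lt <- flat_life_table(q = 0)
  M <- build_transition_matrix(p, lt, 70)
  # only the detected-large operable row acts (elective repair of survivors)
  expect_equal(M["det_large_operable", "post_evar"], 0.8 * 0.987)
  M["det_large_operable", ] <- 0; M["det_large_operable", "det_large_operable"] <- 1
  expect_equal(unname(M), diag(12), tolerance = 1e-15)
})

test_that("rupture pathway composes emergency surgery and its 30-day mortality", {
  p <- aaa_parameters()
  lt <- flat_life_table(q = 0)
  M <- build_transition_matrix(p, lt, 70)
  # untreated large aneurysm: rupture is fatal unless emergency repair succeeds
  emergency_death <- 0.05 * 0.307 + 0.95 * 0.5
  expect_equal(emergency_death, 0.49035)
  expect_equal(M["undet_large", "death_aaa"],
               0.0282 * ((1 - 0.368) + 0.368 * emergency_death),
               tolerance = 1e-12)
  expect_equal(M["undet_large", "death_aaa"], 0.022911, tolerance = 1e-5)
})

test_that("cohort run conserves mass, closes at the horizon, and exports", {
  p <- aaa_parameters()
  lt <- test_life_table()
  for (strat in c("no_screening", "screening")) {
    tr <- run_cohort(NULL, p, lt, strat)
    expect_equal(rowSums(tr$occupancy), rep(1, tr$n_cycles + 1), tolerance = 1e-12)
    expect_true(all(tr$occupancy >= 0))
    expect_true(all(tr$flows >= 0))
    # lifetime horizon: everyone absorbed at the end
    final <- tr$occupancy[nrow(tr$occupancy), ]
    expect_equal(final[["death_aaa"]] + final[["death_other"]], 1, tolerance = 1e-12)
  }
  tr <- run_cohort(NULL, p, lt, "screening")
  df <- export_trace(tr)
  expect_equal(nrow(df), tr$n_cycles)
  expect_true(all(aaa_states_reported() %in% names(df)))
  expect_equal(df$age[1], 65)
  expect_equal(df$screens[1], 0.75)
  expect_equal(sum(df$screens), 0.75)  # one-time screen only
})

test_that("with no aneurysms the cohort reproduces pure life-table survival", {
  p <- aaa_parameters(prevalence_aaa = list(point = 0, low = 0),
                      p_incidence = list(point = 0, low = 0))
  lt <- test_life_table()
  for (strat in c("no_screening", "screening")) {
    tr <- run_cohort(NULL, p, lt, strat)
    alive <- rowSums(tr$occupancy[, setdiff(aaa_states(), c("death_aaa", "death_other"))])
    expected <- survival_oracle(lt, 65, 100, 4, tr$n_cycles)
    expect_equal(alive, expected, tolerance = 1e-9)
    expect_equal(tr$occupancy[nrow(tr$occupancy), "death_aaa"][[1]], 0)
  }
})

test_that("event flows balance the AAA death ledger over a short run", {
  p <- aaa_parameters()
  lt <- test_life_table()
  tr <- run_cohort(NULL, p, lt, "screening")
  k <- 10  # first ten cycles
  occ10 <- tr$occupancy[k + 1, ]
  fl <- tr$flows[seq_len(k), ]
  ruptures <- sum(fl[, "rupture"])
  emergency_entries <- sum(fl[, "emergency_evar"] + fl[, "emergency_osr"])
  periop_deaths <- sum(fl[, "periop_death"])
  # deaths from AAA = unrepaired ruptures + perioperative deaths
  expect_equal(occ10[["death_aaa"]],
               (ruptures - emergency_entries) + periop_deaths,
               tolerance = 1e-12)
  # flows cannot exceed the occupancy that produced them
  expect_true(all(fl[, "rupture"] <=
                    rowSums(tr$occupancy[seq_len(k), c("undet_small", "undet_medium",
                                                       "undet_large", "det_small",
                                                       "det_medium", "det_large_operable",
                                                       "det_large_inoperable")])))
})

test_that("cohort dynamics agree with an independent micro-simulation oracle", {
  p <- aaa_parameters()
  lt <- test_life_table()
  n_walkers <- 2e5
  for (strat in c("no_screening", "screening")) {
    tr <- run_cohort(NULL, p, lt, strat)
    sim <- microsim_occupancy(p, lt, strat, n_walkers, 40, seed = 2024)
    for (cycle in c(1, 4, 40)) {
      expected <- tr$occupancy[cycle + 1, ]
      observed <- sim[cycle + 1, ]
      se <- sqrt(pmax(expected * (1 - expected), 1e-12) / n_walkers)
      expect_true(all(abs(observed - expected) <= 3 * se + 2 / n_walkers),
                  label = sprintf("%s occupancy at cycle %d within 3 MC SE",
                                  strat, cycle))
    }
  }
})

test_that("screening detects at least as much as no screening after one cycle", {
  p <- aaa_parameters()
  lt <- test_life_table()
  det <- c("det_small", "det_medium", "det_large_operable", "det_large_inoperable")
  tr_s <- run_cohort(NULL, p, lt, "screening")
  tr_n <- run_cohort(NULL, p, lt, "no_screening")
  expect_gte(sum(tr_s$occupancy[2, det]) + sum(tr_s$occupancy[2, c("post_evar", "post_osr")]),
             sum(tr_n$occupancy[2, det]) + sum(tr_n$occupancy[2, c("post_evar", "post_osr")]))
})
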