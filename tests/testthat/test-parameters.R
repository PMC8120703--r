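test_that("bundled default configuration reproduces the published inputs", {
  path <- system.file("extdata", "aaa_params.yaml", package = "aaascreen")
  p <- read_parameters(path)
  expect_equal(p$prevalence_aaa$point, 0.03)
  expect_equal(p$prevalence_aaa$low, 0.01)
  expect_equal(p$prevalence_aaa$high, 0.04)
  expect_equal(p$prevalence_aaa$family, "beta")
  expect_equal(p$p_incidence$point, 0.00207)
  expect_equal(p$p_incidence$family, "gamma")
  expect_equal(p$p_rupture_undetected_large$point, 0.0282)
  expect_equal(p$cost_evar$point, 12433)
  expect_equal(p$cost_evar$high, 20722)
  expect_equal(p$cost_screen$point, 39.17)
  expect_equal(p$cost_screen$family, "normal")
  expect_equal(p$utility_65_69$point, 0.83)
  expect_equal(p$utility_65_69$family, "fixed")
  expect_equal(p$disutility_postop$point, -0.02)
  expect_equal(p$discount_rate_annual$point, 0.03)
  expect_equal(p$cycles_per_year, 4)
  # identical to the programmatic default
  expect_equal(unclass(p), unclass(aaa_parameters()))
})

test_that("parameter overrides pass through and ranges pin to scalar overrides", {
  p <- aaa_parameters(discount_rate_annual = 0)
  expect_equal(p$discount_rate_annual$point, 0)
  expect_equal(p$prevalence_aaa$point, 0.03)  # untouched
  p2 <- aaa_parameters(cost_evar = list(point = 15000))
  expect_equal(p2$cost_evar$point, 15000)
  expect_equal(p2$cost_evar$low, 8289)
  expect_error(aaa_parameters(not_a_parameter = 1), "unknown parameter")
})

test_that("parameter round-trip through YAML is field-by-field identical", {
  path <- withr::local_tempfile(fileext = ".yaml")
  p <- aaa_parameters(prevalence_aaa = list(point = 0.02),
                      cycles_per_year = 2)
  write_parameters(p, path)
  p2 <- read_parameters(path)
  expect_equal(unclass(p2), unclass(p))
  # idempotent: re-serializing the re-read set gives the same file
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("validation rejects malformed parameter sets", {
  expect_error(aaa_parameters(prevalence_aaa = list(low = 0.05)),
               "low <= point <= high")
  expect_error(aaa_parameters(attendance = list(point = 1.2, high = 1.3)),
               "outside \\[0, 1\\]")
  expect_error(aaa_parameters(proportion_small = list(point = 0.5, low = 0.5,
                                                      high = 0.5)),
               "proportions sum")
  p <- aaa_parameters()
  p$cost_osr <- NULL
  expect_error(validate_parameters(p), "cost_osr")
  expect_error(read_parameters("/nonexistent/params.yaml"), "does not exist")
})

test_that("method-of-moments distributions match the point estimate and range", {
  # beta for prevalence 0.03 (0.01-0.04): hand-derived hyperparameters
  d <- derive_distribution(list(point = 0.03, low = 0.01, high = 0.04,
                                family = "beta"))
  s <- 0.03 / 3.92
  nu <- 0.03 * 0.97 / s^2 - 1
  expect_equal(d$alpha, 0.03 * nu, tolerance = 1e-12)
  expect_equal(d$beta, 0.97 * nu, tolerance = 1e-12)
  expect_equal(d$alpha, 14.875, tolerance = 1e-4)
  expect_equal(d$beta, 480.97, tolerance = 1e-4)
  # normal for screening cost
  d <- derive_distribution(list(point = 39.17, low = 25.25, high = 57.29,
                                family = "normal"))
  expect_equal(d$mean, 39.17)
  expect_equal(d$sd, (57.29 - 25.25) / 3.92, tolerance = 1e-12)
  expect_equal(d$sd, 8.173, tolerance = 1e-3)
  # fixed family is a point mass
  d <- derive_distribution(list(point = 0.83, low = 0.83, high = 0.83,
                                family = "fixed"))
  expect_identical(draw_distribution(d, 5), rep(0.83, 5))
  # infeasible beta moments rejected
  expect_error(derive_distribution(list(point = 0.5, low = 0, high = 5,
                                        family = "beta")), "too large")
})

test_that("every ranged parameter's derived distribution recovers its moments", {
  withr::local_seed(101)
  base <- aaa_parameters()
  specs <- base[!names(base) %in% aaascreen:::setting_names()]
  specs <- specs[vapply(specs, function(s)
    !s$family %in% c("fixed", "dirichlet") && s$low < s$high, logical(1))]
  n <- 1e6
  for (nm in names(specs)) {
    s <- specs[[nm]]
    d <- derive_distribution(s)
    expect_equal(distribution_mean(d), s$point, tolerance = 1e-6)
    x <- draw_distribution(d, n)
    sd_target <- (s$high - s$low) / 3.92
    expect_equal(mean(x), s$point, tolerance = 5 * sd_target / sqrt(n) / s$point + 1e-9,
                 label = sprintf("mean of %s draws", nm))
    # central 95%% mass approximately spans the stated range
    qs <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    width <- s$high - s$low
    expect_lt(abs((qs[2] - qs[1]) - width), 0.15 * width)
  }
})

test_that("dirichlet size mix derives, draws on the simplex, and handles zeros", {
  d <- derive_dirichlet(c(0.789, 0.12, 0.091), 100)
  expect_equal(d$concentration, c(78.9, 12.0, 9.1))
  withr::local_seed(7)
  x <- draw_distribution(d, 1e5)
  expect_true(all(x >= 0))
  expect_equal(rowSums(x), rep(1, 1e5), tolerance = 1e-12)
  expect_equal(colMeans(x), c(0.789, 0.12, 0.091), tolerance = 0.005)
  # structural zero stays zero
  d0 <- derive_dirichlet(c(1, 0, 0), 100)
  x0 <- draw_distribution(d0, 10)
  expect_true(all(x0[, 2:3] == 0))
  expect_true(all(x0[, 1] == 1))
  expect_error(derive_dirichlet(c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(derive_dirichlet(c(0.5, 0.5), 0), "positive")
})

test_that("annual-to-cycle probability conversion is exact, monotone and composes", {
  expect_equal(annual_to_cycle_probability(0, 4), 0)
  expect_equal(annual_to_cycle_probability(1, 4), 1)
  expect_equal(annual_to_cycle_probability(0.1, 4), 1 - 0.9^0.25)
  expect_equal(annual_to_cycle_probability(0.1, 4), 0.025996, tolerance = 1e-5)
  p <- seq(0, 1, by = 0.01)
  pc <- annual_to_cycle_probability(p, 4)
  expect_true(all(diff(pc) > 0))
  # composing the cycle probability over a year recovers the annual one
  expect_equal(1 - (1 - pc)^4, p, tolerance = 1e-12)
  expect_error(annual_to_cycle_probability(1.1, 4), "\\[0, 1\\]")
})
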