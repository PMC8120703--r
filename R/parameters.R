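#' Model parameters for the AAA screening cost-effectiveness model
#'
#' `aaa_parameters()` builds the default parameter set of the screening
#' model: prevalence and size mix of abdominal aortic aneurysms in
#' 65-year-old men, 3-monthly growth and rupture probabilities, detection and
#' surgery pathway probabilities, 30-day repair mortality, EQ-5D utilities by
#' age band, costs (US$, payer perspective), and run settings (3-month
#' cycles, start age 65, lifetime horizon capped at 100).
#'
#' Each uncertain parameter is a spec with a point estimate, a range
#' interpreted as a central 95% interval, and a sampling-distribution family
#' (`beta`, `gamma`, `normal`, `dirichlet`, or `fixed`). A `fixed` parameter
#' is never sampled in probabilistic sensitivity analysis; it may still carry
#' a range that the one-way deterministic analysis explores (the discount
#' rate works this way). The three aneurysm size proportions are a joint
#' `dirichlet` block.
#'
#' @param ... named overrides. For an uncertain parameter give either a
#'   single number (replaces the point estimate, keeps range and family) or a
#'   list with any of `point`, `low`, `high`, `family`. Settings
#'   (`cycles_per_year`, `start_age`, `end_age`, `dirichlet_concentration`,
#'   `reop_window_years_evar`, `reop_window_years_osr`) take single values.
#' @return an object of class `aaa_parameters`: a named list of parameter
#'   specs plus settings, validated by [validate_parameters()].
#' @examples
#' p <- aaa_parameters()
#' p$prevalence_aaa$point
#' p0 <- aaa_parameters(discount_rate_annual = 0)
#' @export
aaa_parameters <- function(...) {
  spec <- function(point, low = point, high = point, family = "fixed") {
    list(point = point, low = low, high = high, family = family)
  }
  params <- list(
    prevalence_aaa     = spec(0.03, 0.01, 0.04, "beta"),
    proportion_small   = spec(0.789, family = "dirichlet"),
    proportion_medium  = spec(0.12,  family = "dirichlet"),
    proportion_large   = spec(0.091, family = "dirichlet"),
    # transition probabilities, per 3-month cycle
    p_incidence        = spec(0.00207, 0.0013, 0.0029, "gamma"),
    p_small_to_medium  = spec(0.037, 0.033, 0.042, "beta"),
    p_medium_to_large  = spec(0.175, 0.119, 0.231, "beta"),
    # rupture probabilities, per 3-month cycle
    p_rupture_small               = spec(0.00023, 0.00013, 0.00038, "beta"),
    p_rupture_medium              = spec(0.00160, 0.00043, 0.00588, "beta"),
    p_rupture_undetected_large    = spec(0.0282, 0.01974, 0.03666, "beta"),
    p_rupture_detected_large      = spec(0.0125, 0.008, 0.018, "beta"),
    p_rupture_contraindicated_large = spec(0.0282, 0.01974, 0.03666, "beta"),
    # detection and surgical pathway
    p_opportunistic_detection        = spec(0.0114, 0.00798, 0.01482, "beta"),
    p_emergency_surgery_after_rupture = spec(0.368, 0.200, 0.500, "beta"),
    p_elective_surgery_if_large      = spec(0.918, 0.85, 0.95, "beta"),
    p_reop_evar_annual = spec(0.063, 0.0441, 0.0819, "beta"),
    p_reop_osr_annual  = spec(0.039, 0.0273, 0.0507, "beta"),
    attendance         = spec(0.75, 0.65, 0.85, "beta"),
    prop_evar_emergency = spec(0.05, 0, 0.1, "beta"),
    prop_evar_elective  = spec(0.8, 0.7, 0.9, "beta"),
    # 30-day mortality after repair
    p_death_elective_evar  = spec(0.013, 0.004, 0.023, "beta"),
    p_death_elective_osr   = spec(0.030, 0.021, 0.050, "beta"),
    p_death_emergency_evar = spec(0.307, 0.152, 0.492, "beta"),
    p_death_emergency_osr  = spec(0.5, 0.35, 0.65, "beta"),
    # EQ-5D utilities by age band; no published uncertainty
    utility_65_69 = spec(0.83),
    utility_70_74 = spec(0.81),
    utility_75_79 = spec(0.79),
    utility_80_plus = spec(0.74),
    disutility_postop = spec(-0.02),
    # discount rate: fixed in PSA, but carries the one-way DSA range
    discount_rate_annual = spec(0.03, 0, 0.06, "fixed"),
    # costs, US$ (official exchange rate)
    cost_evar   = spec(12433, 8289, 20722, "gamma"),
    cost_osr    = spec(6442, 4295, 10737, "gamma"),
    cost_screen = spec(39.17, 25.25, 57.29, "normal"),
    cost_followup_small_per_cycle  = spec(9.79, 6.31, 14.32, "normal"),
    cost_followup_medium_per_cycle = spec(19.58, 12.63, 28.64, "normal"),
    # settings
    cycles_per_year = 4,
    start_age = 65,
    end_age = 100,
    dirichlet_concentration = 100,
    reop_window_years_evar = 2,
    reop_window_years_osr = 1
  )
  params <- apply_overrides(params, list(...))
  class(params) <- "aaa_parameters"
  validate_parameters(params)
  params
}

setting_names <- function() {
  c("cycles_per_year", "start_age", "end_age", "dirichlet_concentration",
    "reop_window_years_evar", "reop_window_years_osr")
}

apply_overrides <- function(params, overrides) {
  if (length(overrides) == 0) return(params)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("parameter overrides must be named", call. = FALSE)
  }
  for (nm in names(overrides)) {
    if (!nm %in% names(params)) {
      stop(sprintf("unknown parameter '%s'", nm), call. = FALSE)
    }
    val <- overrides[[nm]]
    if (nm %in% setting_names()) {
      params[[nm]] <- val
    } else if (is.list(val)) {
      bad <- setdiff(names(val), c("point", "low", "high", "family"))
      if (length(bad)) {
        stop(sprintf("invalid spec fields for '%s': %s", nm,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      params[[nm]][names(val)] <- val
    } else {
      # scalar override replaces the point estimate and pins the range to it
      params[[nm]]$point <- val
      params[[nm]]$low <- min(params[[nm]]$low, val)
      params[[nm]]$high <- max(params[[nm]]$high, val)
    }
  }
  params
}

#' Validate a parameter set
#'
#' Checks every invariant of the model parameter set: probabilities in
#' \[0, 1\], costs nonnegative, `low <= point <= high` for every ranged
#' parameter, beta-family parameters within the unit interval, and the
#' aneurysm size proportions summing to 1 (tolerance 1e-9).
#'
#' @param params an `aaa_parameters` object (or plain list of the same shape).
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending parameter.
#' @export
validate_parameters <- function(params) {
  required <- c(
    "prevalence_aaa", "proportion_small", "proportion_medium", "proportion_large",
    "p_incidence", "p_small_to_medium", "p_medium_to_large",
    "p_rupture_small", "p_rupture_medium", "p_rupture_undetected_large",
    "p_rupture_detected_large", "p_rupture_contraindicated_large",
    "p_opportunistic_detection", "p_emergency_surgery_after_rupture",
    "p_elective_surgery_if_large", "p_reop_evar_annual", "p_reop_osr_annual",
    "attendance", "prop_evar_emergency", "prop_evar_elective",
    "p_death_elective_evar", "p_death_elective_osr",
    "p_death_emergency_evar", "p_death_emergency_osr",
    "utility_65_69", "utility_70_74", "utility_75_79", "utility_80_plus",
    "disutility_postop", "discount_rate_annual",
    "cost_evar", "cost_osr", "cost_screen",
    "cost_followup_small_per_cycle", "cost_followup_medium_per_cycle",
    setting_names()
  )
  missing <- setdiff(required, names(params))
  if (length(missing)) {
    stop(sprintf("missing parameter(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  prob_params <- grep("^(p_|prevalence|proportion|attendance|prop_)", required, value = TRUE)
  cost_params <- grep("^cost_", required, value = TRUE)
  for (nm in setdiff(required, setting_names())) {
    s <- params[[nm]]
    if (!all(c("point", "low", "high", "family") %in% names(s))) {
      stop(sprintf("parameter '%s' is not a {point, low, high, family} spec", nm),
           call. = FALSE)
    }
    if (!is.finite(s$point) || !is.finite(s$low) || !is.finite(s$high)) {
      stop(sprintf("parameter '%s' has non-finite values", nm), call. = FALSE)
    }
    if (s$low > s$point || s$point > s$high) {
      stop(sprintf("parameter '%s' violates low <= point <= high (%g, %g, %g)",
                   nm, s$low, s$point, s$high), call. = FALSE)
    }
    if (!s$family %in% c("beta", "gamma", "normal", "dirichlet", "fixed")) {
      stop(sprintf("parameter '%s' has unknown family '%s'", nm, s$family),
           call. = FALSE)
    }
    if (nm %in% prob_params && (s$low < 0 || s$high > 1)) {
      stop(sprintf("probability parameter '%s' outside [0, 1]", nm), call. = FALSE)
    }
    if (s$family == "beta" && (s$low < 0 || s$high > 1)) {
      stop(sprintf("beta parameter '%s' outside [0, 1]", nm), call. = FALSE)
    }
    if (nm %in% cost_params && s$point < 0) {
      stop(sprintf("cost parameter '%s' is negative", nm), call. = FALSE)
    }
  }
  mix <- params$proportion_small$point + params$proportion_medium$point +
    params$proportion_large$point
  if (abs(mix - 1) > 1e-9) {
    stop(sprintf("aneurysm size proportions sum to %.12f, not 1", mix),
         call. = FALSE)
  }
  for (nm in setting_names()) {
    if (!is.numeric(params[[nm]]) || length(params[[nm]]) != 1 || params[[nm]] < 0) {
      stop(sprintf("setting '%s' must be a single nonnegative number", nm),
           call. = FALSE)
    }
  }
  if (params$end_age <= params$start_age) {
    stop("end_age must exceed start_age", call. = FALSE)
  }
  invisible(params)
}

#' Extract point estimates from a parameter set
#'
#' @param params an `aaa_parameters` object.
#' @return a named list of point estimates (uncertain parameters collapsed to
#'   their `point` field) plus the settings.
#' @export
parameter_points <- function(params) {
  lapply(params, function(x) if (is.list(x)) x$point else x)
}

#' Read / write a parameter configuration file
#'
#' The configuration is a YAML file whose keys mirror the fields of
#' [aaa_parameters()]: each uncertain parameter is a `{point, low, high,
#' family}` block and each setting a single number. The bundled default
#' (`system.file("extdata", "aaa_params.yaml", package = "aaascreen")`)
#' reproduces the published point estimates and ranges.
#'
#' @param path file path of the YAML configuration.
#' @return `read_parameters()` returns a validated `aaa_parameters` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("parameter configuration '%s' does not exist", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  params <- lapply(raw, function(x) {
    if (is.list(x)) {
      x[c("point", "low", "high", "family")]
    } else {
      x
    }
  })
  class(params) <- "aaa_parameters"
  validate_parameters(params)
  params
}

#' @rdname read_parameters
#' @param params an `aaa_parameters` object to serialize.
#' @return `write_parameters()` returns `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  out <- lapply(unclass(params), function(x) {
    if (is.list(x)) x[c("point", "low", "high", "family")] else x
  })
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Convert an annual probability to a per-cycle probability
#'
#' Assumes a constant hazard within the year:
#' `1 - (1 - p_annual)^(1 / cycles_per_year)`. Composing the per-cycle
#' probability over a full year recovers the annual probability.
#'
#' @param p_annual annual probability, in \[0, 1\].
#' @param cycles_per_year number of model cycles per year (4 for 3-month
#'   cycles).
#' @return the per-cycle probability.
#' @examples
#' annual_to_cycle_probability(0.1, 4)  # 0.025996
#' @export
annual_to_cycle_probability <- function(p_annual, cycles_per_year = 4) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual > 1)) {
    stop("p_annual must lie in [0, 1]", call. = FALSE)
  }
  if (cycles_per_year <= 0) {
    stop("cycles_per_year must be positive", call. = FALSE)
  }
  1 - (1 - p_annual)^(1 / cycles_per_year)
}

#' @export
print.aaa_parameters <- function(x, ...) {
  specs <- x[!names(x) %in% setting_names()]
  cat("AAA screening model parameters\n")
  df <- data.frame(
    parameter = names(specs),
    point = vapply(specs, function(s) s$point, numeric(1)),
    low = vapply(specs, function(s) s$low, numeric(1)),
    high = vapply(specs, function(s) s$high, numeric(1)),
    family = vapply(specs, function(s) s$family, character(1)),
    row.names = NULL, check.names = FALSE
  )
  print(df, digits = 6)
  cat(sprintf("settings: %d cycles/year, ages %d-%d\n",
              as.integer(x$cycles_per_year), as.integer(x$start_age),
              as.integer(x$end_age)))
  invisible(x)
}
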