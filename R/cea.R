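#' Cost-effectiveness analysis of one-time AAA screening
#'
#' Runs the full base-case analysis: two identical cohorts of 65-year-old
#' men, one invited to a single ultrasound screen, one not, simulated over
#' 3-month cycles to the lifetime horizon; discounted costs, QALYs and
#' life-years per strategy; and their incremental comparison (ICER per QALY
#' and per life-year).
#'
#' @param params an [aaa_parameters()] object (default: the published point
#'   estimates).
#' @param life_table an `aaa_life_table`; default the bundled synthetic
#'   Iranian-male table ([iran_male_life_table()]).
#' @param discount_rate optional override of the annual discount rate.
#' @return an object of class `aaa_cea`: list with `results` (per-strategy
#'   `aaa_result`s), `incremental`, `traces`, `params`, `life_table`.
#' @examples
#' \donttest{
#' fit <- aaa_cea()
#' fit
#' summary(fit)
#' }
#' @export
aaa_cea <- function(params = aaa_parameters(), life_table = iran_male_life_table(),
                    discount_rate = NULL) {
  validate_parameters(params)
  if (!is.null(discount_rate)) {
    params$discount_rate_annual$point <- discount_rate
    params$discount_rate_annual$low <- min(params$discount_rate_annual$low, discount_rate)
    params$discount_rate_annual$high <- max(params$discount_rate_annual$high, discount_rate)
  }
  traces <- list(
    no_screening = run_cohort(NULL, params, life_table, "no_screening"),
    screening = run_cohort(NULL, params, life_table, "screening")
  )
  results <- lapply(traces, aggregate_trace, params = params, life_table = life_table)
  inc <- incremental(results$screening, results$no_screening)
  structure(list(results = results, incremental = inc, traces = traces,
                 params = params, life_table = life_table),
            class = "aaa_cea")
}

#' @export
print.aaa_cea <- function(x, ...) {
  cat("One-time AAA ultrasound screening vs no screening\n")
  cat(sprintf("  no screening: cost $%8.2f  QALY %7.4f  LY %7.4f\n",
              x$results$no_screening$cost, x$results$no_screening$qaly,
              x$results$no_screening$ly))
  cat(sprintf("  screening:    cost $%8.2f  QALY %7.4f  LY %7.4f\n",
              x$results$screening$cost, x$results$screening$qaly,
              x$results$screening$ly))
  inc <- x$incremental
  cat(sprintf("  incremental:  cost $%8.2f  QALY %7.4f  LY %7.4f\n",
              inc$delta_cost, inc$delta_qaly, inc$delta_ly))
  if (inc$dominance == "tradeoff") {
    cat(sprintf("  ICER: $%.0f per QALY, $%.0f per LY\n",
                inc$icer_qaly, inc$icer_ly))
  } else {
    cat(sprintf("  screening is %s\n", inc$dominance))
  }
  invisible(x)
}

#' @export
summary.aaa_cea <- function(object, ppp = FALSE, ...) {
  tab <- cea_table(object, ppp = ppp)
  structure(list(table = tab, ppp = ppp,
                 discount = object$params$discount_rate_annual$point),
            class = "summary.aaa_cea")
}

#' @export
print.summary.aaa_cea <- function(x, ...) {
  cat(sprintf("AAA screening cost-effectiveness (discount rate %.1f%%%s)\n",
              100 * x$discount, if (x$ppp) ", PPP dollars" else ""))
  print(x$table, digits = 6, row.names = FALSE)
  invisible(x)
}

#' Tabulate a cost-effectiveness analysis
#'
#' Builds the standard two-strategy results table: average cost, QALY and
#' life-years per strategy, the increments, and the ICERs.
#'
#' @param fit an `aaa_cea` object.
#' @param ppp report monetary columns in PPP dollars via [usd_to_ppp()].
#' @return a data frame with one row per strategy plus an incremental row.
#' @export
cea_table <- function(fit, ppp = FALSE) {
  conv <- if (ppp) usd_to_ppp else identity
  r <- fit$results; inc <- fit$incremental
  data.frame(
    strategy = c("no_screening", "screening", "incremental"),
    cost = conv(c(r$no_screening$cost, r$screening$cost, inc$delta_cost)),
    qaly = c(r$no_screening$qaly, r$screening$qaly, inc$delta_qaly),
    ly = c(r$no_screening$ly, r$screening$ly, inc$delta_ly),
    icer_qaly = c(NA, NA, conv(inc$icer_qaly)),
    icer_ly = c(NA, NA, conv(inc$icer_ly))
  )
}

#' @export
plot.aaa_cea <- function(x, strategy = "screening", ...) {
  trace <- x$traces[[strategy]]
  occ <- aggregate_states(trace$occupancy)
  t_years <- (seq_len(nrow(occ)) - 1) / parameter_points(x$params)$cycles_per_year
  alive <- 1 - occ[, "death_aaa"] - occ[, "death_other"]
  graphics::plot(t_years, alive, type = "l", lwd = 2,
                 xlab = "years since age 65", ylab = "proportion",
                 ylim = c(0, 1), main = sprintf("cohort survival (%s)", strategy), ...)
  graphics::lines(t_years, occ[, "death_aaa"], lty = 2)
  graphics::legend("topright", c("alive", "dead from AAA"), lty = c(1, 2), lwd = c(2, 1))
  invisible(x)
}

#' Export the results table as delimited text
#'
#' @param fit an `aaa_cea` object.
#' @param path output file.
#' @param ppp also append PPP-converted monetary columns.
#' @return the exported data frame, invisibly.
#' @export
export_results <- function(fit, path, ppp = FALSE) {
  df <- cea_table(fit, ppp = FALSE)
  if (ppp) {
    df$cost_ppp <- usd_to_ppp(df$cost)
    df$icer_qaly_ppp <- ifelse(is.na(df$icer_qaly), NA, usd_to_ppp(df$icer_qaly))
    df$icer_ly_ppp <- ifelse(is.na(df$icer_ly), NA, usd_to_ppp(df$icer_ly))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
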