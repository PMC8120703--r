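# One-way deterministic sensitivity analysis (tornado) and probabilistic
# sensitivity analysis (CEAC).

#' One-way deterministic sensitivity analysis for a single parameter
#'
#' Re-runs the full two-strategy analysis with the named parameter at its
#' low and at its high value, all other parameters held at their point
#' estimates.
#'
#' @param param_name name of a parameter in the set.
#' @param base an [aaa_parameters()] object.
#' @param life_table an `aaa_life_table`.
#' @param low,high values to use; default the parameter's own range.
#' @return a one-row data frame: parameter, `icer_low`, `icer_high`,
#'   `spread` (absolute ICER difference), plus the low/high inputs.
#' @export
one_way <- function(param_name, base, life_table, low = NULL, high = NULL) {
  if (!param_name %in% names(base) || param_name %in% setting_names()) {
    stop(sprintf("unknown or non-varying parameter '%s'", param_name), call. = FALSE)
  }
  spec <- base[[param_name]]
  if (is.null(low)) low <- spec$low
  if (is.null(high)) high <- spec$high
  icer_at <- function(value) {
    p <- base
    p[[param_name]]$point <- value
    p[[param_name]]$low <- min(p[[param_name]]$low, value)
    p[[param_name]]$high <- max(p[[param_name]]$high, value)
    aaa_cea(p, life_table)$incremental$icer_qaly
  }
  icer_low <- icer_at(low)
  icer_high <- icer_at(high)
  data.frame(parameter = param_name, low = low, high = high,
             icer_low = icer_low, icer_high = icer_high,
             spread = abs(icer_high - icer_low))
}

#' Full one-way sensitivity analysis with tornado ranking
#'
#' Runs [one_way()] for every parameter carrying a genuine range (low <
#' high), or a chosen subset, and ranks parameters by the absolute ICER
#' spread (descending; ties broken alphabetically).
#'
#' @param base an [aaa_parameters()] object.
#' @param life_table an `aaa_life_table`.
#' @param param_names optional character vector restricting the analysis.
#' @return an `aaa_dsa` data frame sorted for a tornado diagram.
#' @export
run_dsa <- function(base = aaa_parameters(), life_table = iran_male_life_table(),
                    param_names = NULL) {
  ranged <- names(base)[vapply(base, function(s)
    is.list(s) && s$low < s$high, logical(1))]
  if (!is.null(param_names)) {
    unknown <- setdiff(param_names, names(base))
    if (length(unknown)) {
      stop(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    ranged <- intersect(param_names, ranged)
  }
  if (length(ranged) == 0) stop("no ranged parameters to vary", call. = FALSE)
  rows <- lapply(ranged, one_way, base = base, life_table = life_table)
  tornado(do.call(rbind, rows))
}

#' Rank one-way results for a tornado diagram
#'
#' @param dsa_results data frame of [one_way()] rows.
#' @return the rows sorted by `spread` descending, ties alphabetical by
#'   parameter name, classed `aaa_dsa`.
#' @export
tornado <- function(dsa_results) {
  if (is.null(dsa_results) || nrow(dsa_results) == 0) {
    stop("no one-way results to rank", call. = FALSE)
  }
  out <- dsa_results[order(-dsa_results$spread, dsa_results$parameter), ]
  rownames(out) <- NULL
  class(out) <- c("aaa_dsa", "data.frame")
  out
}

#' @export
plot.aaa_dsa <- function(x, n_top = min(10L, nrow(x)), base_icer = NULL, ...) {
  d <- x[seq_len(n_top), ]
  d <- d[rev(seq_len(nrow(d))), ]
  lo <- pmin(d$icer_low, d$icer_high); hi <- pmax(d$icer_low, d$icer_high)
  old <- graphics::par(mar = c(4, 12, 2, 1)); on.exit(graphics::par(old))
  graphics::plot(NULL, xlim = range(lo, hi), ylim = c(0.5, nrow(d) + 0.5),
                 yaxt = "n", xlab = "ICER ($ per QALY)", ylab = "",
                 main = "one-way sensitivity (tornado)", ...)
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi, seq_len(nrow(d)) + 0.35,
                 col = "grey80")
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.7)
  if (!is.null(base_icer)) graphics::abline(v = base_icer, lty = 2)
  invisible(x)
}

#' Export a tornado table as delimited text
#' @param dsa an `aaa_dsa` data frame.
#' @param path output file.
#' @return the exported data frame, invisibly.
#' @export
export_tornado <- function(dsa, path) {
  utils::write.csv(dsa, path, row.names = FALSE)
  invisible(dsa)
}

#' Draw one parameter set for probabilistic sensitivity analysis
#'
#' Every uncertain parameter is replaced by a draw from its derived
#' distribution (beta/gamma/normal by method of moments from the point
#' estimate and 95% range); the three aneurysm size proportions are drawn
#' jointly from their Dirichlet; `fixed` parameters are left unchanged. A
#' draw that violates the parameter-set invariants (e.g. a negative normal
#' cost draw) is rejected and redrawn, up to 100 attempts.
#'
#' @param base an [aaa_parameters()] object.
#' @return a valid `aaa_parameters` object with all points replaced by one
#'   joint draw.
#' @export
draw_parameter_set <- function(base) {
  for (attempt in seq_len(100)) {
    drawn <- base
    for (nm in names(base)) {
      s <- base[[nm]]
      if (!is.list(s) || s$family %in% c("fixed", "dirichlet")) next
      dist <- derive_distribution(s)
      val <- draw_distribution(dist, 1)
      drawn[[nm]]$point <- val
      drawn[[nm]]$low <- min(s$low, val)
      drawn[[nm]]$high <- max(s$high, val)
    }
    if (base$proportion_small$family == "dirichlet") {
      mix <- derive_dirichlet(c(base$proportion_small$point,
                                base$proportion_medium$point,
                                base$proportion_large$point),
                              base$dirichlet_concentration)
      mx <- drop(draw_distribution(mix, 1))
      drawn$proportion_small$point <- mx[1]
      drawn$proportion_medium$point <- mx[2]
      drawn$proportion_large$point <- mx[3]
      for (nm in c("proportion_small", "proportion_medium", "proportion_large")) {
        drawn[[nm]]$low <- min(drawn[[nm]]$low, drawn[[nm]]$point)
        drawn[[nm]]$high <- max(drawn[[nm]]$high, drawn[[nm]]$point)
      }
    }
    ok <- tryCatch({ validate_parameters(drawn); TRUE },
                   error = function(e) FALSE)
    if (ok) return(drawn)
  }
  stop("could not draw a valid parameter set in 100 attempts", call. = FALSE)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter sets, runs both strategies under each shared
#' draw, and records the incremental cost, QALYs and life-years. Each draw
#' uses its own RNG substream derived from `seed`, so results are
#' reproducible and independent of skipped draws.
#'
#' @param base an [aaa_parameters()] object.
#' @param life_table an `aaa_life_table`.
#' @param n number of draws (default 1000).
#' @param seed integer seed (required).
#' @return an `aaa_psa` object: `samples` data frame (`draw`, `delta_cost`,
#'   `delta_qaly`, `delta_ly`), `n_failed`, `seed`, `base`.
#' @export
run_psa <- function(base = aaa_parameters(), life_table = iran_male_life_table(),
                    n = 1000, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("run_psa() requires an explicit seed", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  substream <- sample.int(.Machine$integer.max - 1L, n)
  rows <- vector("list", n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    set.seed(substream[i])
    res <- tryCatch({
      drawn <- draw_parameter_set(base)
      fit <- aaa_cea(drawn, life_table)
      data.frame(draw = i,
                 delta_cost = fit$incremental$delta_cost,
                 delta_qaly = fit$incremental$delta_qaly,
                 delta_ly = fit$incremental$delta_ly)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[i]] <- res
  }
  samples <- do.call(rbind, rows)
  if (n_failed > 0) {
    message(sprintf("PSA: %d of %d draws failed and were skipped", n_failed, n))
  }
  structure(list(samples = samples, n_failed = n_failed, seed = seed,
                 base = base),
            class = "aaa_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that screening is
#' cost-effective: the fraction of PSA draws with strictly positive net
#' monetary benefit, `lambda * delta_QALY - delta_cost > 0` (ties count as
#' not cost-effective).
#'
#' @param psa an `aaa_psa` object, or a data frame with `delta_cost` and
#'   `delta_qaly` columns.
#' @param thresholds nonnegative willingness-to-pay grid ($ per QALY).
#' @return an `aaa_ceac` data frame: `threshold`, `probability`.
#' @export
ceac <- function(psa, thresholds = seq(0, 20000, by = 500)) {
  samples <- if (inherits(psa, "aaa_psa")) psa$samples else psa
  if (is.null(samples) || nrow(samples) == 0) {
    stop("no PSA samples", call. = FALSE)
  }
  if (any(thresholds < 0)) stop("thresholds must be >= 0", call. = FALSE)
  prob <- vapply(thresholds, function(l) {
    mean(l * samples$delta_qaly - samples$delta_cost > 0)
  }, numeric(1))
  structure(data.frame(threshold = thresholds, probability = prob),
            class = c("aaa_ceac", "data.frame"))
}

#' @export
print.aaa_psa <- function(x, ...) {
  s <- x$samples
  cat(sprintf("AAA screening PSA: %d draws (%d failed), seed %d\n",
              nrow(s) + x$n_failed, x$n_failed, x$seed))
  cat(sprintf("mean incremental cost $%.1f, QALY %.4f, LY %.4f\n",
              mean(s$delta_cost), mean(s$delta_qaly), mean(s$delta_ly)))
  invisible(x)
}

#' @export
plot.aaa_ceac <- function(x, ...) {
  graphics::plot(x$threshold, x$probability, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = "willingness to pay ($ per QALY)",
                 ylab = "probability cost-effective",
                 main = "cost-effectiveness acceptability curve", ...)
  graphics::abline(h = c(0.5, 0.95), lty = 3, col = "grey50")
  invisible(x)
}

#' Export a CEAC as delimited text
#' @param curve an `aaa_ceac` data frame.
#' @param path output file.
#' @return the exported data frame, invisibly.
#' @export
export_ceac <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(curve)
}
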