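#' Derive a sampling distribution from a point estimate and range
#'
#' Ranges are read as central 95% intervals, so the standard deviation is
#' `(high - low) / (2 * 1.96)`. Hyperparameters are then obtained by method
#' of moments: beta from (mean, sd) on the unit interval, gamma from
#' (mean, sd) with shape = (mean/sd)^2, normal directly. A `fixed` family
#' (or a degenerate range) yields a point mass.
#'
#' @param spec a parameter spec: list with `point`, `low`, `high`, `family`.
#' @return a `DistributionParams` list: `family` plus its hyperparameters
#'   (`alpha`/`beta`, `shape`/`scale`, `mean`/`sd`, or `value`).
#' @examples
#' derive_distribution(list(point = 0.03, low = 0.01, high = 0.04,
#'                          family = "beta"))
#' @export
derive_distribution <- function(spec) {
  stopifnot(all(c("point", "low", "high", "family") %in% names(spec)))
  if (spec$family == "dirichlet") {
    stop("dirichlet components are derived jointly; use derive_dirichlet()",
         call. = FALSE)
  }
  m <- spec$point
  s <- (spec$high - spec$low) / (2 * 1.96)
  if (spec$family == "fixed" || s == 0) {
    return(list(family = "fixed", value = m))
  }
  switch(spec$family,
    beta = {
      if (m <= 0 || m >= 1) {
        stop(sprintf("beta mean %g outside (0, 1)", m), call. = FALSE)
      }
      nu <- m * (1 - m) / s^2 - 1
      if (nu <= 0) {
        stop(sprintf("beta sd %g too large for mean %g", s, m), call. = FALSE)
      }
      list(family = "beta", alpha = m * nu, beta = (1 - m) * nu)
    },
    gamma = {
      if (m <= 0) stop("gamma mean must be positive", call. = FALSE)
      list(family = "gamma", shape = (m / s)^2, scale = s^2 / m)
    },
    normal = list(family = "normal", mean = m, sd = s),
    stop(sprintf("unknown distribution family '%s'", spec$family), call. = FALSE)
  )
}

#' Derive the joint Dirichlet for the aneurysm size mix
#'
#' The published size proportions (small, medium, large) come without a
#' dispersion, so the Dirichlet concentration is `proportion_i * scale` with
#' a configurable effective sample size `scale`. Zero proportions stay
#' structurally zero.
#'
#' @param proportions numeric vector summing to 1.
#' @param concentration_scale effective sample size of the Dirichlet
#'   (default 100).
#' @return a `DistributionParams` list with `family = "dirichlet"` and the
#'   concentration vector (zero entries marked to remain fixed at 0).
#' @export
derive_dirichlet <- function(proportions, concentration_scale = 100) {
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  if (any(proportions < 0)) stop("proportions must be nonnegative", call. = FALSE)
  if (!is.finite(concentration_scale) || concentration_scale <= 0) {
    stop("concentration_scale must be strictly positive", call. = FALSE)
  }
  list(family = "dirichlet",
       concentration = proportions * concentration_scale)
}

#' Draw from a derived distribution
#'
#' @param dist a `DistributionParams` list from [derive_distribution()] or
#'   [derive_dirichlet()].
#' @param n number of draws.
#' @return for scalar families a numeric vector of length `n`; for
#'   `dirichlet` an `n x k` matrix of draws on the simplex.
#' @export
draw_distribution <- function(dist, n = 1) {
  switch(dist$family,
    fixed = rep(dist$value, n),
    beta = stats::rbeta(n, dist$alpha, dist$beta),
    gamma = stats::rgamma(n, shape = dist$shape, scale = dist$scale),
    normal = stats::rnorm(n, dist$mean, dist$sd),
    dirichlet = {
      conc <- dist$concentration
      draws <- matrix(0, n, length(conc))
      pos <- conc > 0
      # gamma representation; zero-concentration components stay exactly 0
      g <- matrix(stats::rgamma(n * sum(pos), shape = rep(conc[pos], each = n)),
                  n, sum(pos))
      draws[, pos] <- g / rowSums(g)
      draws
    },
    stop(sprintf("unknown distribution family '%s'", dist$family), call. = FALSE)
  )
}

#' Mean of a derived distribution (closed form)
#' @param dist a `DistributionParams` list.
#' @return the distribution mean (vector for dirichlet).
#' @keywords internal
distribution_mean <- function(dist) {
  switch(dist$family,
    fixed = dist$value,
    beta = dist$alpha / (dist$alpha + dist$beta),
    gamma = dist$shape * dist$scale,
    normal = dist$mean,
    dirichlet = dist$concentration / sum(dist$concentration)
  )
}
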