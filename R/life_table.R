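#' Read an age-specific life table
#'
#' Reads a delimited text life table of annual all-cause death probabilities
#' for single years of age (header `age,qx`) or an abridged 5-year table
#' (header `age_start,age_end,qx`). Abridged rows are expanded to single
#' years assuming a constant annual probability within the band:
#' `q1 = 1 - (1 - q5)^(1/5)` (generally, the band-width root).
#'
#' @param path path to the delimited text file (comma separated).
#' @return an `aaa_life_table` object: data frame with integer `age` and
#'   annual death probability `qx`, contiguous in age.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("life table '%s' does not exist", path), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("age_start", "age_end", "qx") %in% names(df))) {
    rows <- lapply(seq_len(nrow(df)), function(i) {
      a0 <- df$age_start[i]; a1 <- df$age_end[i]
      w <- a1 - a0 + 1
      if (w < 1) stop("abridged row with age_end < age_start", call. = FALSE)
      data.frame(age = a0:a1, qx = 1 - (1 - df$qx[i])^(1 / w))
    })
    df <- do.call(rbind, rows)
  } else if (!all(c("age", "qx") %in% names(df))) {
    stop("life table must have columns age,qx or age_start,age_end,qx",
         call. = FALSE)
  }
  life_table(df$age, df$qx)
}

#' Construct a life table from age and probability vectors
#'
#' @param age integer ages (single years, contiguous).
#' @param qx annual probability of death at each age, in \[0, 1\].
#' @return an `aaa_life_table` object.
#' @export
life_table <- function(age, qx) {
  if (length(age) != length(qx)) stop("age and qx lengths differ", call. = FALSE)
  o <- order(age)
  age <- as.integer(age[o]); qx <- qx[o]
  if (anyDuplicated(age)) stop("duplicate ages in life table", call. = FALSE)
  if (any(diff(age) != 1L)) stop("ages must be contiguous single years", call. = FALSE)
  if (any(!is.finite(qx)) || any(qx < 0) || any(qx > 1)) {
    stop("life-table probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(data.frame(age = age, qx = qx), class = c("aaa_life_table", "data.frame"))
}

#' Annual death probability at a given age
#' @param lt an `aaa_life_table`.
#' @param age integer age (vectorized).
#' @return annual probability q_x.
#' @export
annual_death_prob <- function(lt, age) {
  idx <- match(age, lt$age)
  if (anyNA(idx)) {
    stop(sprintf("age(s) %s outside life table [%d, %d]",
                 paste(age[is.na(idx)], collapse = ", "),
                 min(lt$age), max(lt$age)), call. = FALSE)
  }
  lt$qx[idx]
}

#' Per-cycle other-cause death probability
#'
#' Converts the annual probability at `age` to the model's cycle length
#' assuming constant hazard within the year.
#'
#' @inheritParams annual_death_prob
#' @param cycles_per_year model cycles per year.
#' @return per-cycle probability of death from other causes.
#' @examples
#' lt <- life_table(65:70, rep(0.02, 6))
#' cycle_other_cause_death_prob(lt, 65, 4)  # 0.005038
#' @export
cycle_other_cause_death_prob <- function(lt, age, cycles_per_year = 4) {
  annual_to_cycle_probability(annual_death_prob(lt, age), cycles_per_year)
}

#' Generate a synthetic Gompertz-Makeham life table
#'
#' Annual death probabilities follow a Gompertz-Makeham hazard,
#' `q_x = 1 - exp(-(makeham_level + gompertz_scale * exp(gompertz_rate * x)))`,
#' with the terminal age forced to `q = 1` so a lifetime-horizon cohort run
#' closes. This is the package's synthetic-mortality generator for testing
#' and for standing in where a national life table is not distributed.
#'
#' @param makeham_level age-independent annual hazard component (>= 0).
#' @param gompertz_scale scale of the exponential senescent hazard (> 0).
#' @param gompertz_rate exponential rate per year of age (> 0).
#' @param start_age,end_age age span of the table (terminal q forced to 1).
#' @return an `aaa_life_table`.
#' @export
synth_life_table <- function(makeham_level = 0.002, gompertz_scale = 3.5e-5,
                             gompertz_rate = 0.094, start_age = 65,
                             end_age = 100) {
  if (makeham_level < 0) stop("makeham_level must be >= 0", call. = FALSE)
  if (gompertz_scale <= 0) stop("gompertz_scale must be > 0", call. = FALSE)
  if (gompertz_rate <= 0) stop("gompertz_rate must be > 0", call. = FALSE)
  age <- start_age:end_age
  hazard <- makeham_level + gompertz_scale * exp(gompertz_rate * age)
  qx <- 1 - exp(-hazard)
  qx[length(qx)] <- 1
  life_table(age, qx)
}

#' Bundled synthetic Iranian-male life table
#'
#' Loads the life table used by default in the worked analyses: a synthetic
#' Gompertz-Makeham table calibrated so that male life expectancy at 65
#' matches published Iranian values (about 15 years). The national life
#' table underlying the original analysis is not redistributable, so this
#' stand-in is generated, not transcribed; absolute (per-strategy) results
#' depend on it more than incremental ones do.
#'
#' @return an `aaa_life_table` for ages 65-100.
#' @export
iran_male_life_table <- function() {
  read_life_table(system.file("extdata", "life_table_iran_male_synthetic.csv",
                              package = "aaascreen", mustWork = TRUE))
}

#' Life expectancy implied by a life table
#'
#' Trapezoidal (half-year survivorship) life expectancy at `age`, used as an
#' independent check on cohort runs.
#'
#' @param lt an `aaa_life_table`.
#' @param age starting age.
#' @return remaining life expectancy in years.
#' @export
life_expectancy <- function(lt, age = min(lt$age)) {
  q <- lt$qx[lt$age >= age]
  surv <- cumprod(1 - q)
  # person-years: trapezoid between successive survivorship values
  l <- c(1, surv)
  sum((l[-length(l)] + l[-1]) / 2)
}
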