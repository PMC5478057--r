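#' Mean age at first reproduction
#'
#' From the age-specific conditional probabilities `alpha[n]` that a female
#' which has not yet bred starts to reproduce at attained age `n`:
#' `AFR = alpha_1 + sum_{n=2..4} n * alpha_n * prod_{i<n} (1 - alpha_i)`.
#' With `alpha[4] = 1` (every survivor breeds by age 4) this is the mean of
#' a proper distribution over ages 1-4.
#'
#' @param alpha Numeric vector of length 4 of first-breeding probabilities
#'   at attained ages 1-4.
#' @return Mean age at first reproduction in years.
#' @export
#' @examples
#' mean_age_first_reproduction(c(0, 0.33, 0.63, 1))  # 2.92
mean_age_first_reproduction <- function(alpha) {
  stopifnot(length(alpha) == 4L, all(alpha >= 0 & alpha <= 1))
  if (alpha[4L] != 1)
    warning("alpha[4] != 1: the age distribution is improper and the mean is not a true AFR")
  surv <- cumprod(1 - alpha[1:3])     # P(not yet bred before age n)
  alpha[1L] + sum((2:4) * alpha[2:4] * surv)
}

#' Life expectancy beyond age one
#'
#' Under constant adult apparent survival `phi` the further life expectancy
#' of a one-year-old is `-1 / log(phi)` years.
#'
#' @param phi_ad Adult apparent survival probability, strictly in (0, 1).
#' @return Expected further years of life.
#' @export
life_expectancy <- function(phi_ad) {
  if (any(phi_ad <= 0 | phi_ad >= 1))
    stop("life expectancy is undefined at phi = 0 or 1")
  -1 / log(phi_ad)
}

#' Expected years of reproductive opportunity
#'
#' Life expectancy at age one minus the immature years after age one:
#' `life_expectancy - (afr - 1)`.
#'
#' @param life_expectancy Further life expectancy at age 1, years.
#' @param afr Mean age at first reproduction, years (>= 1).
#' @return Expected breeding-capable years.
#' @export
reproductive_years <- function(life_expectancy, afr) {
  stopifnot(all(afr >= 1))
  life_expectancy - (afr - 1)
}

#' Geometric mean of a survival series
#'
#' Used to summarise year-specific first-year survival with a single rate:
#' `exp(mean(log(x)))`.
#'
#' @param x Numeric vector with entries in (0, 1].
#' @export
geometric_mean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires positive entries")
  exp(mean(log(x)))
}

#' Per-species life-history summary
#'
#' Combines fitted or model-averaged rates into the derived life-history
#' quantities: mean age at first reproduction, further life expectancy at
#' age 1, expected reproductive years, and the geometric mean of the
#' (possibly year-specific) first-year survival series.
#'
#' @param phi_ad Named vector of adult survival per species.
#' @param alpha 4 x S matrix (or length-4 vector recycled) of first-breeding
#'   probabilities per species.
#' @param phi_juv List (or vector) of first-year survival series per
#'   species.
#' @return Data frame with one row per species.
#' @export
#' @examples
#' life_history_summary(c(blythii = 0.84, myotis = 0.80),
#'                      cbind(blythii = c(0, 0.33, 0.63, 1),
#'                            myotis = c(0, 0.93, 0.98, 1)),
#'                      phi_juv = c(blythii = 0.52, myotis = 0.52))
life_history_summary <- function(phi_ad, alpha, phi_juv) {
  alpha <- as.matrix(alpha)
  if (ncol(alpha) == 1L) alpha <- alpha[, rep(1L, length(phi_ad)), drop = FALSE]
  if (!is.list(phi_juv)) phi_juv <- as.list(phi_juv)
  stopifnot(ncol(alpha) == length(phi_ad), length(phi_juv) == length(phi_ad))
  afr <- apply(alpha, 2L, mean_age_first_reproduction)
  le <- life_expectancy(phi_ad)
  data.frame(species = names(phi_ad) %||% seq_along(phi_ad),
             afr = afr, phi_ad = unname(phi_ad), life_expectancy = unname(le),
             reproductive_years = unname(reproductive_years(le, afr)),
             juvenile_survival_geomean = vapply(phi_juv, geometric_mean, numeric(1)),
             row.names = NULL)
}
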