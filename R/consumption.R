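# Gamma model of consumption among current drinkers. The shape parameter
# kappa is a sex-specific constant derived from the empirical mean--SD
# relation of survey consumption distributions; the scale theta carries all
# region/age dependence through the per-drinker mean. The density is
# truncated at a consumption cap and renormalized.

#' Mean--standard-deviation relation for drinker consumption
#'
#' Across survey consumption distributions, the standard deviation of
#' consumption among drinkers is approximately proportional to its mean:
#' `SD = beta * mean`. The proportionality coefficient `beta` is
#' sex-specific and is the single quantity from which the gamma shape is
#' derived.
#'
#' @param beta Coefficient linking SD to mean (dimensionless, > 0).
#' @param beta_se Standard error of `beta` (>= 0); drives the uncertainty of
#'   the gamma shape via the delta method.
#' @return An object of class `"mean_sd_relation"`.
#' @seealso [kappa_from_beta()], [kappa_variance()]
#' @export
mean_sd_relation <- function(beta, beta_se = 0) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("beta must be a single positive number", call. = FALSE)
  if (!is.numeric(beta_se) || length(beta_se) != 1L || !is.finite(beta_se) ||
        beta_se < 0)
    stop("beta_se must be a single non-negative number", call. = FALSE)
  structure(list(beta = beta, beta_se = beta_se), class = "mean_sd_relation")
}

as_relation <- function(x) {
  if (inherits(x, "mean_sd_relation")) x else mean_sd_relation(x)
}

#' Gamma shape parameter from the mean--SD coefficient
#'
#' For a gamma distribution, SD/mean = 1/sqrt(shape). Imposing
#' `SD = beta * mean` therefore fixes the shape at `kappa = 1 / beta^2`,
#' independent of region, age group and scale.
#'
#' @param relation A [mean_sd_relation()] (or a bare positive `beta`).
#' @return The gamma shape `kappa` (dimensionless).
#' @export
#' @examples
#' kappa_from_beta(1)    # exponential: SD equals mean
#' kappa_from_beta(0.5)  # 4
kappa_from_beta <- function(relation) {
  relation <- as_relation(relation)
  1 / relation$beta^2
}

#' Delta-method variance of the gamma shape
#'
#' With `kappa = 1 / beta^2`, the delta method gives
#' `var(kappa) = (d kappa / d beta)^2 * var(beta) = 4 * beta_se^2 / beta^6`.
#' Used to generate random samples of `kappa` in the Monte Carlo engine.
#'
#' @param relation A [mean_sd_relation()].
#' @return Variance of `kappa` (dimensionless).
#' @export
kappa_variance <- function(relation) {
  relation <- as_relation(relation)
  4 * relation$beta_se^2 / relation$beta^6
}

#' Mean consumption per current drinker
#'
#' Converts the (coverage-adjusted) adult per-capita consumption of a
#' stratum into mean consumption per current drinker:
#' `coverage_factor * per_capita_mean / p_drinker`, where
#' `p_drinker = 1 - p_abstainer - p_former`. The coverage factor (default
#' 0.8) discounts the registry-based per-capita estimate for wastage and for
#' undercoverage in the epidemiological studies behind the risk curves.
#'
#' @param profile An [exposure_profile()].
#' @return Mean consumption among current drinkers, g/day.
#' @export
drinker_mean <- function(profile) {
  p_drinker <- 1 - profile$p_abstainer - profile$p_former
  drinker_mean_num(profile$per_capita_mean, profile$coverage_factor, p_drinker)
}

drinker_mean_num <- function(per_capita, coverage, p_drinker) {
  if (any(p_drinker <= 0))
    stop("proportion of current drinkers must be > 0", call. = FALSE)
  if (any(per_capita <= 0))
    stop("per-capita consumption must be > 0", call. = FALSE)
  coverage * per_capita / p_drinker
}

#' Truncated gamma specification for drinker consumption
#'
#' Builds the gamma density of consumption among current drinkers: scale
#' `theta = mean_drinker / kappa` (so the untruncated gamma mean equals the
#' requested drinker mean), truncated at `cap` grams/day and renormalized by
#' `1 / pgamma(cap, kappa, scale = theta)` so the density integrates to 1 on
#' \[0, cap\].
#'
#' @param mean_drinker Mean consumption per current drinker, g/day (> 0).
#' @param kappa Gamma shape (> 0), see [kappa_from_beta()].
#' @param cap Truncation point, g/day; defaults to 150, beyond which
#'   sustained consumption is considered implausible.
#' @return An object of class `"gamma_spec"` with fields `kappa`, `theta`,
#'   `cap`, `normalizer`.
#' @seealso [drinker_density()], [band_mass()]
#' @export
gamma_spec <- function(mean_drinker, kappa, cap = 150) {
  if (!is.finite(mean_drinker) || mean_drinker <= 0)
    stop("mean_drinker must be > 0", call. = FALSE)
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (!is.finite(cap) || cap <= 0) stop("cap must be > 0", call. = FALSE)
  theta <- mean_drinker / kappa
  mass <- stats::pgamma(cap, shape = kappa, scale = theta)
  if (mass <= 0)
    stop("gamma distribution has no mass below the cap", call. = FALSE)
  structure(list(kappa = kappa, theta = theta, cap = cap,
                 normalizer = 1 / mass),
            class = "gamma_spec")
}

#' @export
print.gamma_spec <- function(x, ...) {
  cat(sprintf(
    "Truncated gamma: shape %.4f, scale %.4f g/day, cap %g g/day, normalizer %.6f\n",
    x$kappa, x$theta, x$cap, x$normalizer))
  invisible(x)
}

#' Drinker consumption density
#'
#' Evaluates the truncated-normalized gamma density of consumption among
#' current drinkers: `normalizer * dgamma(x, kappa, scale = theta)` on
#' \[0, cap\], zero outside.
#'
#' @param x Consumption level(s), g/day.
#' @param spec A [gamma_spec()].
#' @return Density value(s), per g/day.
#' @export
drinker_density <- function(x, spec) {
  out <- numeric(length(x))
  inside <- x >= 0 & x <= spec$cap
  out[inside] <- spec$normalizer *
    stats::dgamma(x[inside], shape = spec$kappa, scale = spec$theta)
  out
}

#' Probability mass of a consumption band
#'
#' Probability that a current drinker's consumption falls in `[lo, hi)`
#' under the truncated gamma model. Bands are half-open so printed category
#' bounds like 0--39.9 / 40--59.9 / 60--150 tile the support exactly; for
#' the continuous model the open/closed distinction carries no mass.
#'
#' @param spec A [gamma_spec()].
#' @param lo,hi Band bounds, g/day, with `0 <= lo <= hi <= cap`.
#' @return Probability mass in `[lo, hi)`.
#' @export
band_mass <- function(spec, lo, hi) {
  if (any(lo > hi)) stop("band bounds are reversed (lo > hi)", call. = FALSE)
  if (any(lo < 0) || any(hi > spec$cap))
    stop("band must lie within [0, cap]", call. = FALSE)
  spec$normalizer *
    (stats::pgamma(hi, shape = spec$kappa, scale = spec$theta) -
       stats::pgamma(lo, shape = spec$kappa, scale = spec$theta))
}
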