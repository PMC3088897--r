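# Self-contained test inputs: the five published male exposure strata for
# the Asian regions, synthetic exposure profiles in the same magnitude
# ranges, synthetic relative-risk curves in the three canonical shapes
# (exponential, linear, J-shaped), and a brute-force Riemann-sum AAF oracle
# used to validate the quadrature-based computation.

#' Published exposure strata: men aged 15-34 in five Asian regions
#'
#' The five male exposure strata used throughout the examples: adult
#' per-capita consumption with its standard error, and the prevalences of
#' lifetime abstainers and former drinkers, for the regions Asia Pacific
#' (high income), Asia Central, Asia East, Asia South and Asia Southeast.
#' Effective survey size 1000 and coverage factor 0.8 apply to all strata.
#'
#' @return A list of five [exposure_profile()] objects.
#' @seealso [asian_male_survey()]
#' @export
asian_male_exposure <- function() {
  tab <- asian_male_survey()
  lapply(seq_len(nrow(tab)), function(i) {
    exposure_profile(region_label = tab$region_label[i], sex = "male",
                     age_group = "15-34",
                     per_capita_mean = tab$per_capita_mean[i],
                     per_capita_se = tab$per_capita_se[i],
                     p_abstainer = tab$p_abstainer[i],
                     p_former = tab$p_former[i],
                     effective_n = 1000, coverage_factor = 0.8)
  })
}

#' Published survey table: men aged 15-34 in five Asian regions
#'
#' The published per-capita and prevalence values together with their
#' published standard errors (prevalence SEs rounded to two decimals as
#' printed). The prevalence SEs derive from binomial sampling at an
#' effective survey size of 1000, see [prevalence_se()].
#'
#' @return A data frame with one row per region: `region_label`,
#'   `per_capita_mean`, `per_capita_se`, `p_abstainer`, `se_abstainer`,
#'   `p_former`, `se_former`, `p_current`, `se_current`.
#' @export
asian_male_survey <- function() {
  data.frame(
    region_label = c("Asia, Pacific (high income)", "Asia, Central",
                     "Asia, East", "Asia, South", "Asia, Southeast"),
    per_capita_mean = c(13.51, 10.62, 9.88, 3.80, 5.21),
    per_capita_se = c(1.57, 1.73, 1.42, 0.80, 0.79),
    p_abstainer = c(0.05, 0.23, 0.13, 0.73, 0.56),
    se_abstainer = c(0.01, 0.01, 0.01, 0.01, 0.02),
    p_former = c(0.07, 0.13, 0.15, 0.11, 0.17),
    se_former = c(0.01, 0.01, 0.01, 0.01, 0.01),
    p_current = c(0.87, 0.64, 0.72, 0.17, 0.27),
    se_current = c(0.01, 0.02, 0.01, 0.01, 0.01),
    stringsAsFactors = FALSE)
}

#' Default mean-SD coefficients for the consumption model
#'
#' Stylized sex-specific values of the coefficient linking the standard
#' deviation of drinker consumption to its mean (1.171 for men, 1.258 for
#' women), supplied as fixture defaults for examples and tests; analyses of
#' real data should supply their own estimated coefficient and standard
#' error.
#'
#' @param sex `"male"` or `"female"`.
#' @param beta_se Standard error to attach (default 0).
#' @return A [mean_sd_relation()].
#' @export
default_relation <- function(sex = c("male", "female"), beta_se = 0) {
  sex <- match.arg(sex)
  mean_sd_relation(if (sex == "male") 1.171 else 1.258, beta_se)
}

#' Generate a synthetic exposure profile
#'
#' `"high_income"` mirrors the magnitudes of the Asia Pacific (high income)
#' stratum (per-capita about 13.5 g/day, few abstainers); `"low_income"`
#' mirrors Asia South (per-capita about 3.8 g/day, abstainer majority);
#' `"custom"` draws a random but always-valid profile, reproducible under
#' `seed`.
#'
#' @param style `"high_income"`, `"low_income"` or `"custom"`.
#' @param seed Optional integer seed for the `"custom"` style.
#' @return An [exposure_profile()].
#' @export
make_exposure_fixture <- function(style = c("high_income", "low_income",
                                            "custom"),
                                  seed = NULL) {
  style <- match.arg(style)
  if (style == "high_income") {
    return(exposure_profile("synthetic high income", "male", "15-34",
                            per_capita_mean = 13.51, per_capita_se = 1.57,
                            p_abstainer = 0.05, p_former = 0.07))
  }
  if (style == "low_income") {
    return(exposure_profile("synthetic low income", "male", "15-34",
                            per_capita_mean = 3.80, per_capita_se = 0.80,
                            p_abstainer = 0.73, p_former = 0.11))
  }
  if (!is.null(seed)) set.seed(seed)
  pc <- stats::runif(1, 1, 20)
  pa <- stats::runif(1, 0.02, 0.8)
  pf <- stats::runif(1, 0.02, min(0.3, 0.95 - pa))
  exposure_profile("synthetic custom", "male", "15-34",
                   per_capita_mean = pc,
                   per_capita_se = stats::runif(1, 0.05, 0.2) * pc,
                   p_abstainer = pa, p_former = pf)
}

#' Generate a synthetic relative-risk curve
#'
#' Produces a curve of one of the three canonical dose-response shapes:
#' `"exponential"` (log link, single positive power, e.g. liver cirrhosis),
#' `"linear"` (identity link, power 1, e.g. hemorrhagic stroke mortality)
#' or `"jshaped"` (log link, two terms of opposing sign with an interior
#' minimum, e.g. coronary heart disease). Coefficient magnitudes are
#' stylized so resulting AAFs fall in a plausible range (roughly -15% to
#' 60% on typical strata); they are not estimates of any real disease.
#'
#' @param shape `"exponential"`, `"linear"` or `"jshaped"`.
#' @param effect_scale Multiplies the coefficients (default 1).
#' @param uncertainty_scale Multiplies the coefficient standard deviations
#'   (default 1; 0 gives a degenerate covariance).
#' @return An [rr_curve()].
#' @export
make_curve_fixture <- function(shape = c("exponential", "linear", "jshaped"),
                               effect_scale = 1, uncertainty_scale = 1) {
  shape <- match.arg(shape)
  if (shape == "exponential") {
    sd <- 0.0015 * uncertainty_scale
    rr_curve("synthetic exponential", powers = 1,
             betas = 0.01 * effect_scale,
             beta_cov = matrix(sd^2, 1, 1),
             rr_former = 1.2, link = "log")
  } else if (shape == "linear") {
    sd <- 0.002 * uncertainty_scale
    rr_curve("synthetic linear", powers = 1,
             betas = 0.012 * effect_scale,
             beta_cov = matrix(sd^2, 1, 1),
             rr_former = 1, link = "identity")
  } else {
    sds <- c(0.02, 0.003) * uncertainty_scale
    cov <- diag(sds^2)
    cov[1, 2] <- cov[2, 1] <- -0.5 * sds[1] * sds[2]
    rr_curve("synthetic jshaped", powers = c(0.5, 1),
             betas = c(-0.15, 0.022) * effect_scale,
             beta_cov = cov, rr_former = 1.1, link = "log")
  }
}

#' Brute-force AAF oracle by trapezoidal Riemann sum
#'
#' Independent fixed-step computation of the AAF, used to validate the
#' adaptive-quadrature implementation: the drinker excess integral is a
#' trapezoid sum over (0, cap\] at the given step (the integrand is taken
#' as 0 at x = 0, its limit whenever the smallest fractional-polynomial
#' power exceeds `1 - kappa`).
#'
#' @param state A [population_state()].
#' @param curve An [rr_curve()].
#' @param step Grid step, g/day (default 0.001).
#' @return The AAF computed from the Riemann sum.
#' @export
oracle_aaf <- function(state, curve, step = 0.001) {
  cap <- state$spec$cap
  x <- seq(0, cap, by = step)
  if (x[length(x)] < cap) x <- c(x, cap)
  f <- drinker_density(x, state$spec) * (rr_evaluate(curve, x) - 1)
  f[1L] <- 0
  widths <- diff(x)
  integral <- sum(widths * (f[-1L] + f[-length(f)]) / 2)
  E <- state$p_former * (curve$rr_former - 1) + state$p_drinker * integral
  E / (1 + E)
}

#' Classify the shape of a relative-risk curve numerically
#'
#' Uses the sign of a central-difference derivative at 1 and 100 g/day:
#' increasing at both points is `"monotone increasing"`; decreasing then
#' increasing is `"jshaped"`; decreasing at both is
#' `"monotone decreasing"`.
#'
#' @param curve An [rr_curve()].
#' @param h Step for the central difference (default 1e-4).
#' @return A character scalar.
#' @export
classify_curve_shape <- function(curve, h = 1e-4) {
  d <- function(x) {
    (rr_evaluate(curve, x + h) - rr_evaluate(curve, x - h)) / (2 * h)
  }
  lo <- d(1)
  hi <- d(100)
  if (lo > 0 && hi > 0) "monotone increasing"
  else if (lo < 0 && hi > 0) "jshaped"
  else if (lo < 0 && hi < 0) "monotone decreasing"
  else "flat"
}
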