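# Deterministic AAF computation for one parameter set. The population is
# partitioned into lifetime abstainers (reference, RR = 1), former drinkers
# (RR = rr_former) and current drinkers whose consumption follows a
# truncated gamma density P(x). The attributable fraction takes the
# standard Levin form with an excess-risk term
#   E = p_former * (RR_form - 1) + p_drinker * int_0^cap P(x) (RR(x) - 1) dx
# and AAF = E / (1 + E), algebraically identical to (D - 1)/D with
# D = p_abs + p_former * RR_form + p_drinker * int P(x) RR(x) dx.

#' Create a population state
#'
#' Bundles the drinking-status composition of a stratum with the gamma model
#' of consumption among its current drinkers. The drinker proportion is
#' derived as `1 - p_abstainer - p_former`.
#'
#' @param p_abstainer Proportion of lifetime abstainers, in \[0, 1\].
#' @param p_former Proportion of former drinkers, in \[0, 1\].
#' @param spec A [gamma_spec()] for consumption among current drinkers.
#' @return An object of class `"population_state"` with fields
#'   `p_abstainer`, `p_former`, `p_drinker` and `spec`.
#' @seealso [state_from_profile()], [compute_aaf()]
#' @export
population_state <- function(p_abstainer, p_former, spec) {
  if (p_abstainer < 0 || p_abstainer > 1 || p_former < 0 || p_former > 1)
    stop("proportions must be in [0, 1]", call. = FALSE)
  p_drinker <- 1 - p_abstainer - p_former
  if (p_drinker <= 0)
    stop("p_abstainer + p_former must be < 1", call. = FALSE)
  if (!inherits(spec, "gamma_spec"))
    stop("spec must be a gamma_spec", call. = FALSE)
  structure(list(p_abstainer = p_abstainer, p_former = p_former,
                 p_drinker = p_drinker, spec = spec),
            class = "population_state")
}

#' Build a population state from an exposure profile
#'
#' Convenience wrapper: derives the per-drinker mean via [drinker_mean()],
#' the gamma shape via [kappa_from_beta()], and assembles the truncated
#' [gamma_spec()] and [population_state()].
#'
#' @param profile An [exposure_profile()].
#' @param relation A [mean_sd_relation()] (or bare `beta`).
#' @param cap Truncation point, g/day (default 150).
#' @return A `"population_state"`.
#' @export
state_from_profile <- function(profile, relation, cap = 150) {
  kappa <- kappa_from_beta(relation)
  spec <- gamma_spec(drinker_mean(profile), kappa, cap = cap)
  population_state(profile$p_abstainer, profile$p_former, spec)
}

# Excess-risk integral p_drinker * int_lo^hi P(x) (RR(x) - 1) dx for a
# continuous curve, by adaptive quadrature. Tolerances are kept well below
# reporting precision so numerical error is negligible rather than
# propagated.
excess_integral <- function(state, curve, lo, hi, betas = curve$betas,
                            rel_tol = 1e-11, abs_tol = 1e-12) {
  if (hi <= lo) return(0)
  spec <- state$spec
  integrand <- function(x) {
    out <- drinker_density(x, spec) * (rr_evaluate(curve, x, betas) - 1)
    out[x == 0] <- 0  # density may be infinite at 0 but RR(0) - 1 = 0
    out
  }
  val <- stats::integrate(integrand, lo, hi, rel.tol = rel_tol,
                          abs.tol = abs_tol, subdivisions = 1000L,
                          stop.on.error = TRUE)$value
  state$p_drinker * val
}

#' Compute the alcohol-attributable fraction
#'
#' Computes the AAF of one disease for one population state. For a
#' continuous [rr_curve()] the drinker term integrates
#' `P(x) * (RR(x) - 1)` over \[0, cap\] by adaptive quadrature; for a
#' [categorical_risk()] it is the exact sum of band masses times category
#' excess risks. The AAF can be negative where the risk curve dips below 1
#' (protective ranges), and is always < 1.
#'
#' @param state A [population_state()].
#' @param curve An [rr_curve()] or [categorical_risk()].
#' @param betas Optional replacement coefficients for a continuous curve.
#' @return The AAF (dimensionless).
#' @export
#' @examples
#' st <- population_state(0.05, 0.07, gamma_spec(12, 0.73, cap = 150))
#' cv <- rr_curve("synthetic exponential", powers = 1, betas = 0.01)
#' compute_aaf(st, cv)
compute_aaf <- function(state, curve, betas = NULL) {
  E <- excess_term(state, curve, betas)
  E / (1 + E)
}

excess_term <- function(state, curve, betas = NULL) {
  former <- state$p_former * (curve$rr_former - 1)
  drinker <- if (inherits(curve, "categorical_risk")) {
    check_bands_tile(curve$band_bounds, state$spec$cap)
    masses <- band_mass(state$spec, curve$band_bounds[-length(curve$band_bounds)],
                        curve$band_bounds[-1L])
    state$p_drinker * sum(masses * (curve$rrs - 1))
  } else if (inherits(curve, "rr_curve")) {
    if (is.null(betas)) betas <- curve$betas
    excess_integral(state, curve, 0, state$spec$cap, betas)
  } else {
    stop("curve must be an rr_curve or categorical_risk", call. = FALSE)
  }
  former + drinker
}

check_bands_tile <- function(bounds, cap) {
  if (abs(bounds[1L]) > 1e-9 || abs(bounds[length(bounds)] - cap) > 1e-9)
    stop(sprintf("category bounds must tile (0, %g]: got [%g, %g]",
                 cap, bounds[1L], bounds[length(bounds)]), call. = FALSE)
  invisible(TRUE)
}

#' Partial AAF of a consumption band
#'
#' Contribution of drinkers in the band `[lo, hi)` to the full AAF: the
#' band-restricted numerator divided by the same full-population denominator
#' used by [compute_aaf()], so band partials plus the former-drinker partial
#' add up to the full AAF.
#'
#' @param state A [population_state()].
#' @param curve An [rr_curve()].
#' @param lo,hi Band bounds, g/day, `0 <= lo < hi <= cap`.
#' @param betas Optional replacement coefficients.
#' @return The band's partial AAF.
#' @seealso [aaf_partials()]
#' @export
compute_partial_aaf <- function(state, curve, lo, hi, betas = NULL) {
  if (lo > hi) stop("band bounds are reversed (lo > hi)", call. = FALSE)
  if (is.null(betas)) betas <- curve$betas
  E <- excess_term(state, curve, betas)
  excess_integral(state, curve, lo, hi, betas) / (1 + E)
}

#' Partial AAFs over a partition of the consumption range
#'
#' Decomposes the full AAF into the former-drinker contribution and one
#' partial per consumption band defined by `breaks` (e.g. low/moderate/heavy
#' drinking at 0, 40, 60, 150 g/day). All partials share the
#' full-population denominator and sum to the full AAF.
#'
#' @param state A [population_state()].
#' @param curve An [rr_curve()].
#' @param breaks Increasing g/day cut points from 0 to the cap.
#' @return A data frame with columns `component`, `lo`, `hi`, `partial_aaf`,
#'   plus attribute `total_aaf`.
#' @export
aaf_partials <- function(state, curve, breaks = c(0, 40, 60, state$spec$cap)) {
  breaks <- as.numeric(breaks)
  if (any(diff(breaks) <= 0)) stop("breaks must be increasing", call. = FALSE)
  check_bands_tile(breaks, state$spec$cap)
  E <- excess_term(state, curve)
  denom <- 1 + E
  nb <- length(breaks) - 1L
  band_num <- vapply(seq_len(nb), function(i) {
    excess_integral(state, curve, breaks[i], breaks[i + 1L], curve$betas)
  }, numeric(1))
  former_num <- state$p_former * (curve$rr_former - 1)
  out <- data.frame(
    component = c("former_drinkers",
                  sprintf("drinkers_%g_%g", breaks[-length(breaks)],
                          breaks[-1L])),
    lo = c(NA, breaks[-length(breaks)]),
    hi = c(NA, breaks[-1L]),
    partial_aaf = c(former_num, band_num) / denom,
    stringsAsFactors = FALSE)
  attr(out, "total_aaf") <- E / denom
  out
}

#' Categorical (old-method) AAF
#'
#' Classic categorical attributable fraction: category prevalences are the
#' truncated-gamma band masses times the drinker proportion, and
#' `AAF = sum(p_i * (RR_i - 1)) / (1 + sum(p_i * (RR_i - 1)))` including the
#' former-drinker term. Per-category partials share the full denominator.
#'
#' @param state A [population_state()].
#' @param risk A [categorical_risk()] whose bounds tile `(0, cap]`.
#' @return A list with `aaf`, and a data frame `partials` (component,
#'   prevalence, rr, partial_aaf).
#' @export
compute_categorical_aaf <- function(state, risk) {
  if (!inherits(risk, "categorical_risk"))
    stop("risk must be a categorical_risk", call. = FALSE)
  check_bands_tile(risk$band_bounds, state$spec$cap)
  bounds <- risk$band_bounds
  masses <- band_mass(state$spec, bounds[-length(bounds)], bounds[-1L])
  prev <- state$p_drinker * masses
  former_num <- state$p_former * (risk$rr_former - 1)
  E <- former_num + sum(prev * (risk$rrs - 1))
  denom <- 1 + E
  partials <- data.frame(
    component = c("former_drinkers",
                  sprintf("category_%g_%g", bounds[-length(bounds)],
                          bounds[-1L])),
    prevalence = c(state$p_former, prev),
    rr = c(risk$rr_former, risk$rrs),
    partial_aaf = c(former_num, prev * (risk$rrs - 1)) / denom,
    stringsAsFactors = FALSE)
  list(aaf = E / denom, partials = partials)
}

#' Degenerate-consumption fallback test
#'
#' When a Monte Carlo replicate draws an (effectively) zero per-drinker
#' consumption, the gamma density collapses towards a spike at the origin
#' and numerical integration is unreliable; by convention the AAF of such a
#' replicate is set to 0, which also zeroes the former-drinker excess (the
#' convention assumes former drinkers carry no elevated risk in this
#' branch). The threshold boundary itself triggers the fallback.
#'
#' @param mean_drinker Per-drinker mean consumption, g/day.
#' @param threshold Degeneracy threshold, g/day (default 0.01).
#' @return Logical: does the fallback apply?
#' @export
is_degenerate <- function(mean_drinker, threshold = 0.01) {
  mean_drinker <= threshold
}
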