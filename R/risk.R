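# Relative-risk curves: continuous fractional-polynomial dose-response
# functions (with a covariance matrix for their coefficients) and
# categorical relative risks for the old-method comparison. Lifetime
# abstainers are the reference category, RR(0) = 1.

#' Fractional-polynomial basis
#'
#' Evaluates the fractional-polynomial basis terms at consumption levels
#' `x > 0`. Term `i` is `x^p[i]`, with the usual conventions: a power of 0
#' denotes `ln(x)`, and the m-th repetition of a power multiplies the base
#' term by `ln(x)^(m-1)` (so powers `(0.5, 0.5)` give `x^0.5` and
#' `x^0.5 * ln(x)`).
#'
#' @param x Consumption level(s), g/day, strictly positive.
#' @param powers Numeric vector of fractional-polynomial powers.
#' @return A `length(x)` by `length(powers)` matrix of basis values.
#' @export
#' @examples
#' fp_basis(4, c(0.5, 0.5))  # 2 and 2*log(4)
fp_basis <- function(x, powers) {
  if (any(x <= 0)) stop("fp_basis requires x > 0", call. = FALSE)
  k <- length(powers)
  out <- matrix(0, nrow = length(x), ncol = k)
  lx <- log(x)
  for (j in seq_len(k)) {
    p <- powers[j]
    base <- if (p == 0) lx else x^p
    reps <- if (j > 1L) sum(abs(powers[seq_len(j - 1L)] - p) < 1e-12) else 0L
    out[, j] <- if (reps > 0L) base * lx^reps else base
  }
  out
}

check_psd <- function(m, tol = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-6))
    return("beta_cov must be symmetric")
  if (nrow(m) == 0L) return(NULL)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (any(ev < -tol * scale))
    return("beta_cov must be positive semi-definite")
  NULL
}

#' Create a continuous relative-risk curve
#'
#' A fractional-polynomial relative-risk function for one disease (and,
#' where applicable, one endpoint, e.g. separate morbidity and mortality
#' curves). With the log link (the standard for fractional-polynomial RR
#' meta-analysis), `RR(x) = exp(sum(betas * basis(x)))`; with the identity
#' link, `RR(x) = 1 + sum(betas * basis(x))`. The reference category is
#' lifetime abstention, so `RR(0) = 1` by construction. The uncertainty of
#' the coefficients is carried by a covariance matrix from the underlying
#' meta-analysis; the former-drinker relative risk is treated as fixed (no
#' variance is available for it).
#'
#' @param label Disease name.
#' @param powers Fractional-polynomial powers, see [fp_basis()].
#' @param betas Coefficient vector, one per basis term.
#' @param beta_cov Covariance matrix of `betas` (symmetric positive
#'   semi-definite); defaults to the zero matrix (no uncertainty).
#' @param rr_former Relative risk of former drinkers vs lifetime abstainers
#'   (>= 0); defaults to 1.
#' @param link `"log"` (default) or `"identity"`.
#' @return An object of class `"rr_curve"`.
#' @seealso [rr_evaluate()], [sample_beta_sets()], [read_curve_spec()]
#' @export
rr_curve <- function(label, powers, betas,
                     beta_cov = matrix(0, length(betas), length(betas)),
                     rr_former = 1, link = c("log", "identity")) {
  link <- match.arg(link)
  powers <- as.numeric(powers)
  betas <- as.numeric(betas)
  beta_cov <- as.matrix(beta_cov)
  if (length(powers) != length(betas))
    stop("powers and betas must have the same length", call. = FALSE)
  if (nrow(beta_cov) != length(betas) || ncol(beta_cov) != length(betas))
    stop("beta_cov dimensions must match betas", call. = FALSE)
  psd_problem <- check_psd(beta_cov)
  if (!is.null(psd_problem)) stop(psd_problem, call. = FALSE)
  if (!is.finite(rr_former) || rr_former < 0)
    stop("rr_former must be >= 0", call. = FALSE)
  structure(list(label = as.character(label), powers = powers, betas = betas,
                 beta_cov = (beta_cov + t(beta_cov)) / 2,
                 rr_former = rr_former, link = link),
            class = "rr_curve")
}

#' @export
print.rr_curve <- function(x, ...) {
  cat(sprintf("Relative-risk curve: %s\n", x$label))
  cat(sprintf("  link %s, powers (%s), betas (%s)\n", x$link,
              paste(format(x$powers), collapse = ", "),
              paste(format(x$betas), collapse = ", ")))
  cat(sprintf("  former-drinker RR %.3f\n", x$rr_former))
  invisible(x)
}

#' Create a categorical relative-risk specification
#'
#' Piecewise-constant relative risks by drinking category, used for the
#' old-method (categorical) AAF comparison. Category `i` covers
#' `[band_bounds[i], band_bounds[i+1])`.
#'
#' @param band_bounds Strictly increasing g/day cut points (length one more
#'   than `rrs`).
#' @param rrs Relative risk per category (> 0).
#' @param rr_former Former-drinker relative risk (>= 0); defaults to 1.
#' @param label Disease name.
#' @return An object of class `"categorical_risk"`.
#' @seealso [compute_categorical_aaf()]
#' @export
categorical_risk <- function(band_bounds, rrs, rr_former = 1,
                             label = "categorical") {
  band_bounds <- as.numeric(band_bounds)
  rrs <- as.numeric(rrs)
  if (length(band_bounds) != length(rrs) + 1L)
    stop("band_bounds must have length(rrs) + 1 entries", call. = FALSE)
  if (any(diff(band_bounds) <= 0))
    stop("band_bounds must be strictly increasing", call. = FALSE)
  if (any(!is.finite(rrs)) || any(rrs <= 0))
    stop("category relative risks must be > 0", call. = FALSE)
  if (!is.finite(rr_former) || rr_former < 0)
    stop("rr_former must be >= 0", call. = FALSE)
  structure(list(label = as.character(label), band_bounds = band_bounds,
                 rrs = rrs, rr_former = rr_former),
            class = "categorical_risk")
}

#' Evaluate a relative-risk curve
#'
#' Evaluates `RR(x)` for a continuous curve. `RR(0)` is 1 by the
#' reference-category definition (lifetime abstainers), without taking
#' limits of the basis terms.
#'
#' @param curve An [rr_curve()].
#' @param x Consumption level(s), g/day, >= 0.
#' @param betas Optional replacement coefficient vector (e.g. one draw from
#'   [sample_beta_sets()]); defaults to the curve's own coefficients.
#' @return Relative risk(s), dimensionless.
#' @export
rr_evaluate <- function(curve, x, betas = curve$betas) {
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  out <- numeric(length(x))
  pos <- x > 0
  out[!pos] <- 1
  if (any(pos)) {
    eta <- drop(fp_basis(x[pos], curve$powers) %*% betas)
    out[pos] <- if (curve$link == "log") exp(eta) else 1 + eta
  }
  if (any(!is.finite(out)))
    stop("relative-risk curve evaluated to a non-finite value (malformed curve)",
         call. = FALSE)
  out
}

#' Sample coefficient vectors from a curve's covariance
#'
#' Draws `n` coefficient vectors from the multivariate normal distribution
#' centred at the curve's coefficients with its covariance matrix. Within
#' one Monte Carlo run the same draws are reused across all strata, since
#' the risk curves are common to all regions and age groups.
#'
#' @param curve An [rr_curve()].
#' @param n Number of draws (>= 1).
#' @return An `n` by `length(betas)` matrix, one draw per row.
#' @export
sample_beta_sets <- function(curve, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  k <- length(curve$betas)
  if (k == 0L) return(matrix(0, nrow = n, ncol = 0L))
  draws <- MASS::mvrnorm(n, mu = curve$betas, Sigma = curve$beta_cov)
  if (n == 1L) draws <- matrix(draws, nrow = 1L)
  unname(draws)
}

#' Read a relative-risk curve specification from JSON
#'
#' Parses the curve JSON format: an object with fields `label`, `type`
#' (`"fractional_polynomial"` or `"categorical"`), and, for continuous
#' curves, `link`, `powers`, `betas`, `beta_cov` (row-major flat vector) and
#' `rr_former`; for categorical risks, `band_bounds`, `rrs` and
#' `rr_former`. All invariants are validated with field-level messages.
#'
#' @param path Path to a JSON file.
#' @return An [rr_curve()] or [categorical_risk()].
#' @seealso [write_curve_spec()]
#' @export
read_curve_spec <- function(path) {
  if (!file.exists(path))
    stop(sprintf("curve spec '%s' does not exist", path), call. = FALSE)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- function(field) {
    if (is.null(spec[[field]]))
      stop(sprintf("curve spec is missing field '%s'", field), call. = FALSE)
    spec[[field]]
  }
  type <- need("type")
  label <- need("label")
  rr_former <- if (is.null(spec$rr_former)) 1 else spec$rr_former
  if (identical(type, "fractional_polynomial")) {
    powers <- as.numeric(need("powers"))
    betas <- as.numeric(need("betas"))
    link <- if (is.null(spec$link)) "log" else spec$link
    if (!link %in% c("log", "identity"))
      stop(sprintf("unknown link '%s' (must be 'log' or 'identity')", link),
           call. = FALSE)
    k <- length(betas)
    cov_flat <- as.numeric(need("beta_cov"))
    if (length(cov_flat) != k * k)
      stop(sprintf("beta_cov has %d entries; expected %d (= %d^2)",
                   length(cov_flat), k * k, k), call. = FALSE)
    beta_cov <- matrix(cov_flat, nrow = k, byrow = TRUE)
    rr_curve(label, powers, betas, beta_cov, rr_former = rr_former,
             link = link)
  } else if (identical(type, "categorical")) {
    categorical_risk(as.numeric(need("band_bounds")),
                     as.numeric(need("rrs")),
                     rr_former = rr_former, label = label)
  } else {
    stop(sprintf("unknown curve type '%s'", type), call. = FALSE)
  }
}

#' Write a relative-risk specification to JSON
#'
#' @param curve An [rr_curve()] or [categorical_risk()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_curve_spec <- function(curve, path) {
  obj <- if (inherits(curve, "rr_curve")) {
    list(label = curve$label, type = "fractional_polynomial",
         link = curve$link, powers = curve$powers, betas = curve$betas,
         beta_cov = as.numeric(t(curve$beta_cov)),
         rr_former = curve$rr_former)
  } else if (inherits(curve, "categorical_risk")) {
    list(label = curve$label, type = "categorical",
         band_bounds = curve$band_bounds, rrs = curve$rrs,
         rr_former = curve$rr_former)
  } else {
    stop("curve must be an rr_curve or categorical_risk", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
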