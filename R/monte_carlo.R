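# Monte Carlo uncertainty engine. Each replicate draws the lowest-level
# parameters (relative-risk coefficients, adult per-capita consumption,
# abstainer and former-drinker prevalences, and optionally the gamma shape
# kappa), rebuilds the consumption model, and yields one AAF. The variance
# of the N replicate AAFs estimates the AAF variance; confidence intervals
# follow from the normal approximation or from empirical percentiles.
#
# Fixed draw order per run: beta coefficients, per-capita consumption,
# p_abstainer, p_former, kappa. Replicate AAFs are evaluated in batches on
# a graded consumption grid: bin masses come from exact gamma CDF
# differences (so the integrable density singularity at 0 costs nothing)
# and the relative risk is evaluated at bin midpoints.

#' Monte Carlo configuration
#'
#' @param n_samples Total number of replicates N; defaults to 150000, which
#'   gives confidence intervals stable to two decimal places.
#' @param batch_size Replicates per batch (default 1000); batches structure
#'   the convergence trace as 150 sets of 1000.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param ci_level Confidence level (default 0.95).
#' @param sample_kappa Should the gamma shape be sampled using its
#'   delta-method variance? Default `TRUE`.
#' @param ci_method `"normal_approx"` (point estimate plus/minus z times the
#'   Monte Carlo standard deviation; default) or `"percentile"` (empirical
#'   quantiles of the replicate AAFs, for skewed sampling distributions).
#' @param cap Consumption truncation point, g/day (default 150).
#' @param n_grid Number of consumption bins for the vectorized replicate
#'   evaluation (default 200, quadratically graded towards 0).
#' @param degenerate_threshold Per-drinker mean (g/day) at or below which a
#'   replicate's AAF is set to 0 (default 0.01).
#' @return An object of class `"mc_config"`.
#' @export
mc_config <- function(n_samples = 150000L, batch_size = 1000L, seed = NULL,
                      ci_level = 0.95, sample_kappa = TRUE,
                      ci_method = c("normal_approx", "percentile"),
                      cap = 150, n_grid = 200L, degenerate_threshold = 0.01) {
  ci_method <- match.arg(ci_method)
  n_samples <- as.integer(n_samples)
  batch_size <- as.integer(batch_size)
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1)
    stop("ci_level must be in (0, 1)", call. = FALSE)
  structure(list(n_samples = n_samples, batch_size = batch_size,
                 n_batches = ceiling(n_samples / batch_size),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 ci_level = ci_level, sample_kappa = isTRUE(sample_kappa),
                 ci_method = ci_method, cap = cap,
                 n_grid = as.integer(n_grid),
                 degenerate_threshold = degenerate_threshold),
            class = "mc_config")
}

mc_parameter_groups <- c("rr_betas", "per_capita", "p_abstainer", "p_former",
                         "kappa")

# Draw all random components once, in the documented order. beta_draws may
# be supplied (shared across strata in a multi-stratum run), in which case
# no beta draws are consumed from the RNG stream.
mc_make_draws <- function(profile, relation, curve, config,
                          beta_draws = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_samples
  if (is.null(beta_draws)) {
    beta_draws <- if (inherits(curve, "rr_curve"))
      sample_beta_sets(curve, n) else matrix(0, n, 0L)
  } else {
    if (nrow(beta_draws) != n)
      stop("beta_draws must have n_samples rows", call. = FALSE)
  }
  split <- !is.na(profile$recorded_mean) && !is.na(profile$recorded_se) &&
    !is.na(profile$unrecorded_mean)
  if (split) {
    u_se <- unrecorded_se(profile$recorded_se, profile$recorded_mean,
                          profile$unrecorded_mean)
    pc <- stats::rnorm(n, profile$recorded_mean, profile$recorded_se) +
      stats::rnorm(n, profile$unrecorded_mean, u_se)
  } else {
    pc <- stats::rnorm(n, profile$per_capita_mean, profile$per_capita_se)
  }
  se_abs <- prevalence_se(profile$p_abstainer, profile$effective_n)
  se_form <- prevalence_se(profile$p_former, profile$effective_n)
  pa <- stats::rnorm(n, profile$p_abstainer, se_abs)
  pf <- stats::rnorm(n, profile$p_former, se_form)
  kappa0 <- kappa_from_beta(relation)
  kv <- kappa_variance(relation)
  kap <- if (config$sample_kappa && kv > 0)
    stats::rnorm(n, kappa0, sqrt(kv)) else rep(kappa0, n)
  list(betas = beta_draws, per_capita = pc, p_abstainer = pa, p_former = pf,
       kappa = kap, kappa0 = kappa0,
       profile = profile, relation = relation, curve = curve, config = config)
}

# Assemble replicate parameter sets from the draws, using the drawn values
# only for the groups in `active` and the point values otherwise (the
# one-at-a-time arrangements of the variance decomposition reuse the same
# draws with different `active` sets). Applies the 0.001 g/day floor to
# non-positive per-capita draws, clips prevalences to [0, 1] and rescales
# pairs summing to >= 1, floors kappa at a tiny positive value, and flags
# degenerate replicates.
mc_assemble <- function(draws, active = mc_parameter_groups) {
  profile <- draws$profile
  config <- draws$config
  n <- config$n_samples
  pc <- if ("per_capita" %in% active) draws$per_capita
        else rep(profile$per_capita_mean, n)
  floored <- pc <= 0
  pc[floored] <- 0.001
  pa <- if ("p_abstainer" %in% active) pmin(pmax(draws$p_abstainer, 0), 1)
        else rep(profile$p_abstainer, n)
  pf <- if ("p_former" %in% active) pmin(pmax(draws$p_former, 0), 1)
        else rep(profile$p_former, n)
  s <- pa + pf
  renormalized <- s >= 1
  if (any(renormalized)) {
    scale <- (1 - 1e-6) / s[renormalized]
    pa[renormalized] <- pa[renormalized] * scale
    pf[renormalized] <- pf[renormalized] * scale
  }
  pd <- 1 - pa - pf
  kap <- if ("kappa" %in% active) pmax(draws$kappa, 1e-6)
         else rep(draws$kappa0, n)
  point_betas <- if (inherits(draws$curve, "rr_curve"))
    draws$curve$betas else numeric(0)
  betas <- if ("rr_betas" %in% active) draws$betas
           else matrix(rep(point_betas, each = n), nrow = n,
                       ncol = length(point_betas))
  dm <- profile$coverage_factor * pc / pd
  degenerate <- dm <= config$degenerate_threshold
  list(betas = betas,
       params = data.frame(per_capita = pc, p_abstainer = pa, p_former = pf,
                           p_drinker = pd, kappa = kap, drinker_mean = dm,
                           theta = dm / kap, floored = floored,
                           renormalized = renormalized,
                           degenerate = degenerate))
}

#' Sample replicate parameter sets
#'
#' Generates the full stream of lowest-level parameter replicates for one
#' stratum: relative-risk coefficients from the curve's covariance matrix,
#' per-capita consumption from a normal distribution (non-positive draws
#' floored at 0.001 g/day), abstainer and former-drinker prevalences from
#' normal approximations to their binomial sampling distributions (clipped
#' to \[0, 1\] and jointly rescaled when their sum reaches 1), and the gamma
#' shape from its delta-method variance. The per-drinker mean and scale
#' theta are recomputed per replicate. The draw order (betas, per-capita,
#' p_abstainer, p_former, kappa) is fixed, so a seed makes the stream fully
#' reproducible.
#'
#' @param profile An [exposure_profile()].
#' @param relation A [mean_sd_relation()].
#' @param curve An [rr_curve()] or [categorical_risk()].
#' @param config An [mc_config()].
#' @param beta_draws Optional precomputed coefficient draws (matrix with
#'   `n_samples` rows), e.g. to share one set of curve draws across strata.
#' @return A list with `betas` (matrix) and `params` (data frame with one
#'   row per replicate: `per_capita`, `p_abstainer`, `p_former`,
#'   `p_drinker`, `kappa`, `drinker_mean`, `theta`, and logical flags
#'   `floored`, `renormalized`, `degenerate`).
#' @export
sample_parameter_sets <- function(profile, relation, curve, config,
                                  beta_draws = NULL) {
  mc_assemble(mc_make_draws(profile, relation, curve, config, beta_draws))
}

mc_grid <- function(cap, n_grid) {
  edges <- cap * (seq(0, n_grid) / n_grid)^2
  list(edges = edges, mids = (edges[-1L] + edges[-length(edges)]) / 2)
}

# Vectorized AAF evaluation for assembled replicates, batched to bound
# memory. Bin masses are exact truncated-gamma CDF increments; RR is
# evaluated at bin midpoints (continuous curves) or constant per category.
mc_aaf_replicates <- function(assembled, curve, config) {
  params <- assembled$params
  n <- nrow(params)
  rrf <- curve$rr_former
  continuous <- inherits(curve, "rr_curve")
  if (continuous) {
    grid <- mc_grid(config$cap, config$n_grid)
    edges <- grid$edges
    basis <- fp_basis(grid$mids, curve$powers)
  } else {
    check_bands_tile(curve$band_bounds, config$cap)
    edges <- curve$band_bounds
    rr_cat <- curve$rrs
  }
  m1 <- length(edges)
  aaf <- numeric(n)
  starts <- seq(1L, n, by = config$batch_size)
  for (s in starts) {
    idx <- s:min(s + config$batch_size - 1L, n)
    ni <- length(idx)
    live <- !params$degenerate[idx]
    if (!any(live)) next
    li <- idx[live]
    nl <- length(li)
    em <- matrix(edges, nrow = nl, ncol = m1, byrow = TRUE)
    ff <- stats::pgamma(em, shape = params$kappa[li],
                        scale = params$theta[li])
    tot <- ff[, m1]
    w <- ff[, -1L, drop = FALSE] - ff[, -m1, drop = FALSE]
    if (continuous) {
      eta <- tcrossprod(assembled$betas[li, , drop = FALSE], basis)
      rr <- if (curve$link == "log") exp(eta) else 1 + eta
      integral <- rowSums(w * (rr - 1)) / tot
    } else {
      integral <- drop(w %*% (rr_cat - 1)) / tot
    }
    e_term <- params$p_former[li] * (rrf - 1) +
      params$p_drinker[li] * integral
    bad <- !is.finite(e_term) | tot <= 0
    a <- e_term / (1 + e_term)
    a[bad] <- 0
    aaf_batch <- numeric(ni)
    aaf_batch[live] <- a
    aaf[idx] <- aaf_batch
  }
  aaf
}

#' Run the Monte Carlo uncertainty engine for one stratum
#'
#' Draws `n_samples` replicate parameter sets, computes one AAF per
#' replicate (degenerate replicates contribute 0), and summarizes: the
#' point estimate is the AAF at the input means (the replicate sample mean
#' is also reported), the variance is the sample variance of the replicate
#' AAFs, and the confidence interval follows the configured method.
#'
#' @inheritParams sample_parameter_sets
#' @return An object of class `"aaf_result"`: `point_estimate`,
#'   `sample_mean`, `samples`, `variance`, `ci_low`, `ci_high`,
#'   `ci_method`, `ci_level`, `n_samples`, `batch_size`, `n_degenerate`,
#'   `n_floored`, `n_renormalized`, `seed`, `label`.
#' @seealso [convergence_analysis()], [decompose_variance()]
#' @export
mc_run <- function(profile, relation, curve, config = mc_config(),
                   beta_draws = NULL) {
  assembled <- sample_parameter_sets(profile, relation, curve, config,
                                     beta_draws)
  samples <- mc_aaf_replicates(assembled, curve, config)

  point_state_mean <- drinker_mean(profile)
  point <- if (is_degenerate(point_state_mean, config$degenerate_threshold)) {
    0
  } else {
    compute_aaf(state_from_profile(profile, relation, cap = config$cap), curve)
  }
  v <- if (length(samples) > 1L) stats::var(samples) else 0
  alpha <- 1 - config$ci_level
  if (config$ci_method == "normal_approx") {
    z <- stats::qnorm(1 - alpha / 2)
    ci <- point + c(-1, 1) * z * sqrt(v)
  } else {
    ci <- unname(stats::quantile(samples, c(alpha / 2, 1 - alpha / 2)))
  }
  n_floored <- sum(assembled$params$floored)
  n_degenerate <- sum(assembled$params$degenerate)
  if (n_degenerate > 0.01 * config$n_samples)
    warning(sprintf("%d of %d replicates hit the degenerate-consumption fallback",
                    n_degenerate, config$n_samples), call. = FALSE)
  structure(list(point_estimate = point, sample_mean = mean(samples),
                 samples = samples, variance = v,
                 ci_low = ci[1L], ci_high = ci[2L],
                 ci_method = config$ci_method, ci_level = config$ci_level,
                 n_samples = config$n_samples,
                 batch_size = config$batch_size,
                 n_degenerate = n_degenerate, n_floored = n_floored,
                 n_renormalized = sum(assembled$params$renormalized),
                 seed = config$seed,
                 label = sprintf("%s | %s", profile$region_label,
                                 curve$label)),
            class = "aaf_result")
}

#' @export
print.aaf_result <- function(x, digits = 4, ...) {
  cat(sprintf("AAF result: %s\n", x$label))
  cat(sprintf("  point estimate %s (replicate mean %s)\n",
              format(x$point_estimate, digits = digits),
              format(x$sample_mean, digits = digits)))
  cat(sprintf("  variance %s, %g%% CI [%s, %s] (%s)\n",
              format(x$variance, digits = digits), 100 * x$ci_level,
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits), x$ci_method))
  cat(sprintf("  N = %d replicates; %d degenerate, %d floored, %d prevalence-rescaled\n",
              x$n_samples, x$n_degenerate, x$n_floored, x$n_renormalized))
  invisible(x)
}

#' Run the engine for several strata with shared curve draws
#'
#' The relative-risk curves are common to all regions and age groups, so
#' within one Monte Carlo replicate the same coefficient draw must be used
#' for every stratum. This wrapper draws the coefficient sets once (under
#' `config$seed`) and reuses them for each stratum, whose remaining
#' parameters are drawn under per-stratum seeds `seed + stratum index`.
#'
#' @param profiles A list of [exposure_profile()] objects.
#' @param relation A [mean_sd_relation()].
#' @param curve An [rr_curve()] or [categorical_risk()].
#' @param config An [mc_config()]; its seed governs the shared draws.
#' @return A list of `"aaf_result"` objects, one per stratum, with the
#'   shared coefficient draws attached as attribute `"beta_draws"`.
#' @export
mc_run_table <- function(profiles, relation, curve, config = mc_config()) {
  if (inherits(profiles, "exposure_profile")) profiles <- list(profiles)
  if (!is.null(config$seed)) set.seed(config$seed)
  betas <- if (inherits(curve, "rr_curve"))
    sample_beta_sets(curve, config$n_samples)
  else matrix(0, config$n_samples, 0L)
  results <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    cfg_i <- config
    if (!is.null(config$seed)) cfg_i$seed <- config$seed + i
    results[[i]] <- mc_run(profiles[[i]], relation, curve, cfg_i,
                           beta_draws = betas)
  }
  attr(results, "beta_draws") <- betas
  results
}

#' Convergence trace of the batch-averaged variance
#'
#' Splits the replicate AAFs into consecutive batches, computes the
#' variance within each batch, and the running average of batch variances
#' after k batches (k = 1, ..., n_batches). The running average stabilizes
#' as the sample size grows; its terminal behaviour indicates how many
#' samples are needed for a variance estimate of given precision.
#'
#' @param profile,relation,curve,config As in [mc_run()]; alternatively
#'   pass an existing `"aaf_result"` as `profile` to reuse its samples.
#' @return An object of class `"convergence_trace"`: a data frame with
#'   columns `batch`, `n_cumulative`, `batch_variance`,
#'   `cumulative_variance`, with the batch size as attribute.
#' @seealso [required_samples()]
#' @export
convergence_analysis <- function(profile, relation = NULL, curve = NULL,
                                 config = mc_config()) {
  result <- if (inherits(profile, "aaf_result")) profile
            else mc_run(profile, relation, curve, config)
  batch_size <- result$batch_size
  n_batches <- floor(result$n_samples / batch_size)
  if (n_batches < 2L)
    stop("need at least 2 complete batches for a convergence trace",
         call. = FALSE)
  idx <- rep(seq_len(n_batches), each = batch_size)
  use <- seq_len(n_batches * batch_size)
  batch_var <- tapply(result$samples[use], idx[use], stats::var)
  trace <- data.frame(batch = seq_len(n_batches),
                      n_cumulative = seq_len(n_batches) * batch_size,
                      batch_variance = as.numeric(batch_var),
                      cumulative_variance = cumsum(batch_var) /
                        seq_len(n_batches))
  attr(trace, "batch_size") <- batch_size
  class(trace) <- c("convergence_trace", "data.frame")
  trace
}

#' Samples required for the variance to settle
#'
#' Smallest cumulative sample count after which every subsequent running
#' average of the batch variances stays within `tolerance` of the final
#' value.
#'
#' @param trace A `"convergence_trace"` from [convergence_analysis()].
#' @param tolerance Absolute tolerance on the variance (> 0); see
#'   [variance_precision_for_ci()] for the tolerance implied by a CI
#'   precision goal.
#' @return Required number of samples (a multiple of the batch size).
#' @export
required_samples <- function(trace, tolerance) {
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be > 0", call. = FALSE)
  cum <- trace$cumulative_variance
  final <- cum[length(cum)]
  ok <- abs(cum - final) <= tolerance
  # last index before which some later value still strays outside tolerance
  settled <- rev(cumprod(rev(ok))) > 0
  k <- which(settled)[1L]
  trace$n_cumulative[k]
}

#' Variance precision needed for a CI precision goal
#'
#' Under the normal approximation the CI half-width is `z * sqrt(V)`. An
#' absolute error `e` in the estimated variance perturbs a CI bound by at
#' most `z * sqrt(e)`, so bounds accurate to within `ci_error` require the
#' variance to be estimated within `(ci_error / z)^2`. For bounds accurate
#' to plus/minus 0.01 at the 95% level this is 2.6e-5.
#'
#' @param ci_error Maximum tolerated error in a CI bound (default 0.01,
#'   i.e. one unit in the second decimal).
#' @param level Confidence level (default 0.95).
#' @return Required precision (absolute tolerance) of the variance.
#' @export
variance_precision_for_ci <- function(ci_error = 0.01, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  (ci_error / z)^2
}

#' One-at-a-time variance decomposition
#'
#' Attributes the total Monte Carlo variance of an AAF to the parameter
#' groups (`rr_betas`, `per_capita`, `p_abstainer`, `p_former`, `kappa`).
#' For each group, the replicate AAFs are recomputed with only that group's
#' draws active and the other parameters held at their point values,
#' reusing the same underlying random draws in every arrangement. Because
#' the AAF is non-linear the raw one-at-a-time variances do not add up to
#' the all-random total, so the shares are rescaled to sum to it.
#'
#' @inheritParams sample_parameter_sets
#' @param config An [mc_config()]; 1000 replicates are typically enough
#'   here.
#' @return An object of class `"decomposition_result"`: a data frame with
#'   columns `group`, `raw_variance`, `normalized_share`, and attribute
#'   `total_variance`.
#' @export
decompose_variance <- function(profile, relation, curve,
                               config = mc_config(n_samples = 1000L)) {
  draws <- mc_make_draws(profile, relation, curve, config)
  has_unc <- c(
    rr_betas = inherits(curve, "rr_curve") && any(curve$beta_cov != 0),
    per_capita = (if (!is.na(profile$recorded_se))
                    profile$recorded_se else profile$per_capita_se) > 0,
    p_abstainer = prevalence_se(profile$p_abstainer,
                                profile$effective_n) > 0,
    p_former = prevalence_se(profile$p_former, profile$effective_n) > 0,
    kappa = config$sample_kappa && kappa_variance(relation) > 0)
  raw <- vapply(mc_parameter_groups, function(g) {
    if (!has_unc[[g]]) return(0)
    stats::var(mc_aaf_replicates(mc_assemble(draws, active = g), curve,
                                 config))
  }, numeric(1))
  total <- stats::var(
    mc_aaf_replicates(mc_assemble(draws,
                                  active = mc_parameter_groups[has_unc]),
                      curve, config))
  if (sum(raw) <= 0)
    stop("no parameter group has nonzero uncertainty (total variance is 0)",
         call. = FALSE)
  out <- data.frame(group = mc_parameter_groups,
                    raw_variance = unname(raw),
                    normalized_share = unname(raw / sum(raw) * total),
                    stringsAsFactors = FALSE)
  attr(out, "total_variance") <- total
  class(out) <- c("decomposition_result", "data.frame")
  out
}
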