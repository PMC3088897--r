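test_that("zero input uncertainty collapses the engine to the point estimate", {
  prof <- exposure_profile("r", "male", "15-34", 10, 0,
                           p_abstainer = 0, p_former = 0)
  rel <- mean_sd_relation(1.171, 0)
  cv <- rr_curve("exp", powers = 1, betas = 0.01, rr_former = 1.2)
  cfg <- mc_config(n_samples = 500, batch_size = 100, seed = 1)
  sets <- sample_parameter_sets(prof, rel, cv, cfg)
  expect_equal(length(unique(sets$params$per_capita)), 1L)
  expect_equal(length(unique(sets$params$theta)), 1L)
  expect_true(all(sets$betas == sets$betas[1, 1]))
  res <- mc_run(prof, rel, cv, cfg)
  expect_equal(res$variance, 0)
  expect_equal(res$ci_low, res$point_estimate)
  expect_equal(res$ci_high, res$point_estimate)
  expect_equal(res$sample_mean, res$point_estimate, tolerance = 1e-3)
})

test_that("the replicate stream is deterministic under a seed and batch-size invariant", {
  prof <- make_exposure_fixture("high_income")
  rel <- default_relation("male", beta_se = 0.02)
  cv <- make_curve_fixture("exponential")
  r1 <- mc_run(prof, rel, cv, mc_config(n_samples = 3000, seed = 9))
  r2 <- mc_run(prof, rel, cv, mc_config(n_samples = 3000, seed = 9))
  expect_identical(r1$samples, r2$samples)
  # a different batch size preserves total N and draw order
  r3 <- mc_run(prof, rel, cv,
               mc_config(n_samples = 3000, seed = 9, batch_size = 500))
  expect_equal(r1$samples, r3$samples, tolerance = 1e-13)
  expect_equal(r1$variance, r3$variance, tolerance = 1e-13)
})

test_that("replicate AAFs from the batched grid match per-replicate quadrature", {
  prof <- make_exposure_fixture("high_income")
  rel <- default_relation("male", beta_se = 0.02)
  for (shape in c("exponential", "jshaped")) {
    cv <- make_curve_fixture(shape)
    cfg <- mc_config(n_samples = 40, batch_size = 40, seed = 5)
    sets <- sample_parameter_sets(prof, rel, cv, cfg)
    grid_aafs <- aafmc:::mc_aaf_replicates(sets, cv, cfg)
    exact <- vapply(seq_len(40), function(i) {
      p <- sets$params[i, ]
      st <- population_state(p$p_abstainer, p$p_former,
                             gamma_spec(p$drinker_mean, p$kappa))
      compute_aaf(st, cv, betas = sets$betas[i, ])
    }, numeric(1))
    expect_equal(grid_aafs, exact, tolerance = 5e-4)
  }
})

test_that("per-capita draws are floored at 0.001 only when the tail demands it", {
  rel <- mean_sd_relation(1.171, 0)
  cv <- make_curve_fixture("exponential")
  # region-4-like inputs: flooring probability ~ pnorm(-3.8/0.8) ~ 1e-6
  south <- make_exposure_fixture("low_income")
  res <- mc_run(south, rel, cv, mc_config(n_samples = 20000, seed = 11))
  expect_lte(res$n_floored, 2)
  expect_equal(res$n_degenerate, 0)
  # an extreme-noise profile must floor and fall back, not crash
  noisy <- exposure_profile("noisy", "male", "15-34", 0.5, 2,
                            p_abstainer = 0.4, p_former = 0.3)
  expect_warning(
    res2 <- mc_run(noisy, rel, cv, mc_config(n_samples = 2000, seed = 12)),
    "degenerate")
  expect_gt(res2$n_floored, 0)
  expect_equal(res2$samples[aafmc:::mc_assemble(
    aafmc:::mc_make_draws(noisy, rel, cv,
                          mc_config(n_samples = 2000, seed = 12)))
    $params$degenerate],
    rep(0, res2$n_degenerate))
})

test_that("healthy inputs never trigger the degenerate fallback", {
  rel <- default_relation("male", beta_se = 0.02)
  cv <- make_curve_fixture("linear")
  for (seed in 1:3) {
    prof <- make_exposure_fixture("custom", seed = seed)
    if (drinker_mean(prof) < 1 ||
          prof$per_capita_se / prof$per_capita_mean >= 0.2) next
    res <- mc_run(prof, rel, cv, mc_config(n_samples = 5000, seed = seed))
    expect_equal(res$n_degenerate, 0)
  }
})

test_that("prevalence draws stay in [0, 1] and pairs are rescaled, not dropped", {
  prof <- exposure_profile("edge", "male", "15-34", 5, 0.5,
                           p_abstainer = 0.73, p_former = 0.25,
                           effective_n = 30)  # huge prevalence noise
  rel <- mean_sd_relation(1.171, 0)
  cv <- make_curve_fixture("exponential")
  cfg <- mc_config(n_samples = 5000, seed = 21)
  sets <- sample_parameter_sets(prof, rel, cv, cfg)
  p <- sets$params
  expect_true(all(p$p_abstainer >= 0 & p$p_abstainer <= 1))
  expect_true(all(p$p_former >= 0 & p$p_former <= 1))
  expect_true(all(p$p_drinker > 0))
  expect_gt(sum(p$renormalized), 0)
  expect_equal(p$p_abstainer + p$p_former + p$p_drinker, rep(1, 5000))
})

test_that("Monte Carlo variance matches the delta method for a constant-RR fixture", {
  # all uncertainty in the drinker proportion; RR constant at 2 over
  # drinkers, so AAF = f(p_d) = p_d / (1 + p_d) and
  # var(AAF) ~ f'(p_d)^2 var(p_d)
  prof <- exposure_profile("delta", "male", "15-34", 10, 0,
                           p_abstainer = 0.3, p_former = 0.1)
  rel <- mean_sd_relation(1.171, 0)
  risk <- categorical_risk(c(0, 150), 2, rr_former = 1)
  res <- mc_run(prof, rel, risk, mc_config(n_samples = 150000, seed = 42))
  var_pd <- 0.3 * 0.7 / 1000 + 0.1 * 0.9 / 1000
  p_d <- 0.6
  delta_var <- (1 / (1 + p_d)^2)^2 * var_pd
  expect_equal(res$variance, delta_var, tolerance = 0.05)
})

test_that("shared beta draws make multi-stratum runs use one curve sample", {
  profiles <- asian_male_exposure()[1:2]
  rel <- default_relation("male", beta_se = 0.02)
  cv <- make_curve_fixture("exponential")
  cfg <- mc_config(n_samples = 2000, seed = 7)
  results <- mc_run_table(profiles, rel, cv, cfg)
  betas <- attr(results, "beta_draws")
  expect_equal(dim(betas), c(2000, 1))
  # running one stratum directly with the shared draws reproduces it
  cfg1 <- cfg
  cfg1$seed <- cfg$seed + 1L
  direct <- mc_run(profiles[[1]], rel, cv, cfg1, beta_draws = betas)
  expect_identical(results[[1]]$samples, direct$samples)
})

test_that("the convergence trace settles and reports required samples", {
  prof <- make_exposure_fixture("high_income")
  rel <- default_relation("male", beta_se = 0.02)
  cv <- make_curve_fixture("exponential")
  res <- mc_run(prof, rel, cv,
                mc_config(n_samples = 30000, batch_size = 1000, seed = 13))
  tr <- convergence_analysis(res)
  expect_equal(nrow(tr), 30)
  expect_equal(tr$cumulative_variance[30], mean(tr$batch_variance))
  expect_equal(tr$cumulative_variance[1], tr$batch_variance[1])
  expect_lte(required_samples(tr, 2.6e-5), 30000)
  expect_error(required_samples(tr, -1), "tolerance")
  # deterministic inputs converge in the first batch
  flat_prof <- exposure_profile("r", "male", "15-34", 10, 0,
                                p_abstainer = 0, p_former = 0)
  flat_res <- mc_run(flat_prof, mean_sd_relation(1.171, 0),
                     rr_curve("e", 1, 0.01),
                     mc_config(n_samples = 3000, batch_size = 1000,
                               seed = 2))
  flat_tr <- convergence_analysis(flat_res)
  expect_equal(required_samples(flat_tr, 1e-12), 1000)
})

test_that("variance decomposition shares are exhaustive and identify dominant groups", {
  prof <- make_exposure_fixture("high_income")
  rel <- default_relation("male", beta_se = 0.02)
  cfg <- mc_config(n_samples = 1000, seed = 31)
  cv <- make_curve_fixture("exponential")
  d <- decompose_variance(prof, rel, cv, cfg)
  expect_setequal(d$group, c("rr_betas", "per_capita", "p_abstainer",
                             "p_former", "kappa"))
  expect_true(all(d$normalized_share >= 0))
  expect_equal(sum(d$normalized_share), attr(d, "total_variance"),
               tolerance = 1e-12)
  # inflating the RR covariance 100x must make rr_betas dominate
  cv_inflated <- make_curve_fixture("exponential", uncertainty_scale = 10)
  d2 <- decompose_variance(prof, rel, cv_inflated, cfg)
  expect_equal(d2$group[which.max(d2$normalized_share)], "rr_betas")
  expect_gt(d2$normalized_share[d2$group == "rr_betas"],
            0.5 * attr(d2, "total_variance"))
  # a single uncertain group carries 100% of the variance
  prof0 <- exposure_profile("only-pc", "male", "15-34", 10, 1,
                            p_abstainer = 0, p_former = 0)
  d3 <- decompose_variance(prof0, mean_sd_relation(1.171, 0),
                           rr_curve("e", 1, 0.01), cfg)
  expect_equal(d3$normalized_share[d3$group == "per_capita"],
               attr(d3, "total_variance"))
  expect_equal(sum(d3$raw_variance > 0), 1)
})

test_that("percentile intervals bracket the replicate distribution", {
  prof <- make_exposure_fixture("high_income")
  rel <- default_relation("male", beta_se = 0.02)
  cv <- make_curve_fixture("exponential")
  res <- mc_run(prof, rel, cv,
                mc_config(n_samples = 4000, seed = 17,
                          ci_method = "percentile"))
  expect_gte(res$point_estimate, min(res$samples))
  expect_lte(res$point_estimate, max(res$samples))
  expect_equal(mean(res$samples >= res$ci_low & res$samples <= res$ci_high),
               0.95, tolerance = 0.01)
})

test_that("the variance precision for two-decimal CI bounds is 2.6e-5", {
  expect_equal(signif(variance_precision_for_ci(0.01, 0.95), 2), 2.6e-5)
  expect_equal(variance_precision_for_ci(0.01, 0.95),
               (0.01 / qnorm(0.975))^2)
})
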