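test_that("no excess risk means zero AAF", {
  st <- make_state()
  flat <- rr_curve("flat", powers = 1, betas = 0, rr_former = 1)
  expect_equal(compute_aaf(st, flat), 0, tolerance = 1e-12)
  cat_flat <- categorical_risk(c(0, 40, 150), c(1, 1), rr_former = 1)
  expect_equal(compute_aaf(st, cat_flat), 0, tolerance = 1e-12)
  # nearly no drinkers, former drinkers at baseline risk
  tiny <- population_state(0.98, 0.0199, gamma_spec(12, 0.73))
  expo_no_former <- rr_curve("exp", powers = 1, betas = 0.01, rr_former = 1)
  expect_lt(abs(compute_aaf(tiny, expo_no_former)), 0.001)
})

test_that("constant drinker RR reproduces the closed-form AAF", {
  for (p_d in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    for (cc in c(0.8, 1, 1.5, 2, 4)) {
      st <- population_state(p_abstainer = 1 - p_d, p_former = 0,
                             spec = gamma_spec(12, 0.73))
      risk <- categorical_risk(c(0, 150), cc, rr_former = 1)
      expect_equal(compute_aaf(st, risk),
                   p_d * (cc - 1) / (1 + p_d * (cc - 1)),
                   tolerance = 1e-9)
    }
  }
})

test_that("the E/(1+E) and numerator/denominator AAF forms agree", {
  st <- make_state()
  cv <- make_curve_fixture("jshaped")
  # D = p_abs + p_form * RR_form + p_drink * int P(x) RR(x) dx
  integral_rr <- integrate(function(x) {
    out <- drinker_density(x, st$spec) * rr_evaluate(cv, x)
    out[x == 0] <- 0
    out
  }, 0, 150, rel.tol = 1e-11)$value
  D <- st$p_abstainer + st$p_former * cv$rr_former +
    st$p_drinker * integral_rr
  expect_equal(compute_aaf(st, cv), (D - 1) / D, tolerance = 1e-8)
})

test_that("quadrature agrees with the Riemann-sum oracle on all fixture shapes", {
  for (combo in fixture_combinations()) {
    a <- compute_aaf(combo$state, combo$curve)
    o <- oracle_aaf(combo$state, combo$curve, step = 0.0005)
    expect_lt(abs(a - o), 1e-5,
              label = sprintf("|AAF - oracle| (%s, mean %.1f)",
                              combo$curve$label,
                              combo$state$spec$kappa *
                                combo$state$spec$theta))
    expect_lt(a, 1)
  }
})

test_that("a J-shaped curve with a low-consumption population gives a negative AAF", {
  st <- make_state(mean_drinker = 8, p_abstainer = 0.3, p_former = 0.1)
  cv <- make_curve_fixture("jshaped")
  a <- compute_aaf(st, cv)
  expect_lt(a, 0)
  expect_equal(a, oracle_aaf(st, cv, step = 0.0005), tolerance = 1e-5)
})

test_that("band partials plus the former-drinker partial sum to the full AAF", {
  for (combo in fixture_combinations()[c(2, 5, 9, 14, 20)]) {
    parts <- aaf_partials(combo$state, combo$curve,
                          breaks = c(0, 40, 60, 150))
    expect_equal(sum(parts$partial_aaf),
                 compute_aaf(combo$state, combo$curve), tolerance = 1e-9)
    expect_equal(attr(parts, "total_aaf"), sum(parts$partial_aaf),
                 tolerance = 1e-12)
  }
})

test_that("partials vanish where the curve has no excess risk", {
  st <- make_state()
  flat <- rr_curve("flat", powers = 1, betas = 0, rr_former = 1.5)
  expect_equal(compute_partial_aaf(st, flat, 40, 60), 0, tolerance = 1e-12)
  expect_equal(compute_partial_aaf(st, flat, 10, 10), 0)
  expect_error(compute_partial_aaf(st, flat, 60, 40), "reversed")
})

test_that("J-shaped partials show the protective-low, harmful-heavy pattern", {
  st <- make_state(mean_drinker = 12)
  cv <- make_curve_fixture("jshaped")
  parts <- aaf_partials(st, cv, breaks = c(0, 40, 60, 150))
  low <- parts$partial_aaf[parts$component == "drinkers_0_40"]
  heavy <- parts$partial_aaf[parts$component == "drinkers_60_150"]
  expect_lt(low, 0)
  expect_gt(heavy, 0)
  expect_gt(abs(low), abs(heavy))  # most mass sits in the protective range
})

test_that("categorical AAF matches band-averaged continuous computation", {
  st <- make_state()
  cv <- make_curve_fixture("exponential")
  bounds <- c(0, seq(2.5, 150, by = 2.5))
  masses <- band_mass(st$spec, bounds[-length(bounds)], bounds[-1])
  # mass-weighted mean RR per band from a fine grid: an independent
  # discretization of the same continuous curve
  rr_bands <- vapply(seq_len(length(bounds) - 1L), function(i) {
    xs <- seq(bounds[i], bounds[i + 1], length.out = 200)[-1]
    w <- drinker_density(xs, st$spec)
    sum(w * rr_evaluate(cv, xs)) / sum(w)
  }, numeric(1))
  cat_risk <- categorical_risk(bounds, rr_bands, rr_former = cv$rr_former)
  res <- compute_categorical_aaf(st, cat_risk)
  expect_equal(res$aaf, compute_aaf(st, cv), tolerance = 2e-3)
  expect_equal(sum(res$partials$partial_aaf), res$aaf, tolerance = 1e-12)
})

test_that("categorical AAF handles the classic special cases", {
  st <- population_state(0, 0, gamma_spec(12, 0.73))
  # all drinkers in effect one category at RR 2: AAF = 1/2
  one_band <- categorical_risk(c(0, 150), 2, rr_former = 1)
  expect_equal(compute_categorical_aaf(st, one_band)$aaf, 0.5,
               tolerance = 1e-9)
  bad <- categorical_risk(c(10, 150), 2)
  expect_error(compute_categorical_aaf(st, bad), "tile")
})

test_that("AAF is monotone in the former-drinker relative risk", {
  st <- make_state()
  aafs <- vapply(c(0.8, 1, 1.2, 1.5, 2), function(rrf) {
    cv <- rr_curve("x", powers = 1, betas = 0.01, rr_former = rrf)
    compute_aaf(st, cv)
  }, numeric(1))
  expect_true(all(diff(aafs) > 0))
})

test_that("degenerate-consumption fallback triggers on and below the threshold", {
  expect_true(is_degenerate(0.001))
  expect_true(is_degenerate(0.01))   # closed boundary
  expect_false(is_degenerate(0.0100001))
  expect_false(is_degenerate(10))
})
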