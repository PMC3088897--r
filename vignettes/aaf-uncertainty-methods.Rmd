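---
title: "Methods: attributable-fraction estimation and Monte Carlo uncertainty in aafmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributable-fraction estimation and Monte Carlo uncertainty in aafmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aafmc)
```

## The estimation problem

An alcohol-attributable fraction (AAF) answers: what share of a disease's
burden in a stratum (region × sex × age) would disappear if everyone were a
lifetime abstainer? The population splits into lifetime abstainers (the
relative-risk reference), former drinkers (a fixed relative risk
`rr_former`), and current drinkers, whose individual risk depends on their
average daily consumption through a continuous dose-response curve RR(x).
The AAF is the Levin attributable fraction

$$\mathrm{AAF} = \frac{E}{1+E}, \qquad
E = P_\mathrm{form}\,(\mathrm{RR}_\mathrm{form}-1) +
    P_\mathrm{drink}\int_0^{c} P(x)\,(\mathrm{RR}(x)-1)\,dx,$$

where $P(x)$ is the consumption density among drinkers and $c$ the
truncation cap. This is algebraically identical to the
numerator/denominator form $(D-1)/D$ with
$D = P_\mathrm{abs} + P_\mathrm{form}\mathrm{RR}_\mathrm{form} +
P_\mathrm{drink}\int P(x)\mathrm{RR}(x)dx$ (the package tests assert the
identity). AAFs can be negative where the curve dips below 1 — J-shaped
relations make low-consumption strata net-protective for some outcomes.

The statistical difficulty is that exposure (per-capita statistics plus
surveys) and risk (meta-analyses of epidemiological studies) come from
unrelated sources, so no joint model exists from which to derive the AAF
variance analytically; the AAF is also non-linear in every input. `aafmc`
therefore propagates uncertainty by Monte Carlo: each replicate redraws all
lowest-level parameters from their marginal sampling distributions,
recomputes the whole pipeline, and yields one AAF; the spread of the N
replicate AAFs is the AAF's sampling uncertainty.

## The consumption model

Consumption among current drinkers is gamma. Two empirical facts shape the
parametrization:

* the standard deviation of drinker consumption is close to proportional
  to its mean, SD $= \beta \cdot$ mean, with a sex-specific coefficient
  $\beta$. Since a gamma's SD/mean ratio is $1/\sqrt{\kappa}$, this pins
  the shape at $\kappa = 1/\beta^2$ for *all* strata of one sex — only the
  scale $\theta$ varies by stratum. `var(kappa)` follows by the delta
  method, $4\,\mathrm{var}(\beta)/\beta^6$. These two closed forms are the
  unique ones consistent with SD $=\beta\cdot$mean; both are verified in
  the tests against large-sample simulation oracles.
* surveys undercount; registry-based per-capita consumption is more
  trustworthy in level. The per-drinker mean is therefore the upshifted
  `coverage_factor * per_capita_mean / p_drinker`, with
  `coverage_factor = 0.8` by default — a deliberate discount for wastage
  (spillage, unconsumed stock) and for the undercoverage of consumption in
  the studies behind the risk curves, which would otherwise bias AAFs
  upward.

$\theta$ is computed from the *untruncated* mean ($\theta =$ mean$/\kappa$)
and the density is then truncated at `cap = 150` g/day and renormalized by
the reciprocal gamma CDF at the cap. Sustained consumption above 150 g/day
is not credible, and an untruncated tail would let exponential-shape RR
curves dominate the integral with physiologically meaningless mass. The
order — scale first, then renormalize — was a genuine design choice; the
alternative (solving for $\theta$ so the *truncated* mean matches) changes
little at realistic means (normalizer $\approx 1$) but loses the clean
$\kappa\theta =$ mean identity that the tests rely on.

## Risk curves

Continuous curves are fractional polynomials: basis terms $x^{p}$ with
$p=0$ meaning $\ln x$ and a repeated power contributing an extra $\ln x$
factor (the standard convention). The default link is log
(`RR = exp(η)`) because the source meta-analyses model log-RR and it keeps
sampled curves positive; the identity link (`RR = 1 + η`) is supported for
linear relations. `RR(0) = 1` is imposed by definition of the reference
category rather than by taking basis limits (which for $\ln x$ or negative
powers do not exist). Coefficient uncertainty enters through the
meta-analytic covariance matrix via multivariate-normal draws;
`rr_former` is treated as fixed because no variance is published for it —
a known understatement of total uncertainty. Curves for morbidity and
mortality endpoints of one disease are simply separate specifications.

Categorical (piecewise-constant) risks support the old-method comparison;
their AAF is the classic prevalence-weighted sum, with category prevalences
taken from the same truncated gamma so the two methods differ only in the
dose-response representation.

## The Monte Carlo engine

Per replicate, in fixed draw order (coefficients, per-capita consumption,
abstainer prevalence, former-drinker prevalence, shape):

* RR coefficients ~ MVN(betas, beta_cov); one draw is shared across all
  strata evaluated in one `mc_run_table()` call, since the curves are
  common to all regions and ages — only exposure differs.
* per-capita ~ Normal(mean, se); draws ≤ 0 are set to 0.001 g/day (a
  "very low consumption" token, counted in `n_floored`). When a
  recorded/unrecorded split is supplied the two parts are drawn
  independently, with the unrecorded SD imputed as five times the recorded
  *relative* SD.
* prevalences ~ Normal(p, sqrt(p(1−p)/n)) — the binomial variance with
  effective survey size `effective_n = 1000` — clipped to [0, 1]; if a
  sampled pair sums to ≥ 1 both are rescaled to sum to 1 − 10⁻⁶ so a
  drinker fraction always exists (counted in `n_renormalized`). The
  normal approximation preserves the stated variances; at n = 1000 and the
  prevalences of interest, clipping is essentially never active.
* κ ~ Normal(1/β², delta variance), clipped at 10⁻⁶ (clipping rather than
  rejection keeps one draw per replicate, which is what makes the stream
  batch-size invariant and exactly reproducible; at realistic `beta_se`
  a negative draw has negligible probability). Switch off with
  `sample_kappa = FALSE` to treat the shape as known.

The per-drinker mean and θ are recomputed per replicate. If the replicate
mean is at or below `degenerate_threshold = 0.01` g/day the gamma collapses
towards a spike at zero and integration is meaningless; that replicate's
AAF is set to 0 — including the former-drinker term, i.e. the fallback
assumes former drinkers carry no excess risk — and counted in
`n_degenerate`. The threshold is configurable; 0.01 g/day (one sip per
year) is far below any real consumption estimate, and the engine warns
when more than 1% of replicates fall back.

### Numerical evaluation

Point estimates, oracles and all deterministic entry points use adaptive
quadrature (`stats::integrate`, tolerances 10⁻¹¹/10⁻¹²) on
$P(x)(\mathrm{RR}(x)-1)$, which handles the integrable density singularity
at 0 when κ < 1 (the integrand itself vanishes at 0 whenever the smallest
fractional-polynomial power exceeds 1 − κ). Partial AAFs integrate the
band numerators against the *full* denominator, so the former-drinker
partial plus the band partials reproduce the full AAF to ~10⁻⁹ — additivity
is the invariant the band decomposition exists for.

Replicate AAFs inside the engine use a different scheme, because N
adaptive integrations per stratum would be wasteful: consumption is binned
on a quadratically graded grid (`n_grid = 200` bins, edges
$c\,(j/M)^2$, finer where the density piles up near zero), bin masses are
*exact* truncated-gamma CDF increments (vectorized across replicates), and
RR is evaluated at bin midpoints. The singularity costs nothing since the
CDF absorbs it. Agreement with per-replicate adaptive quadrature is a few
parts in 10⁵ at the default grid — far below Monte Carlo noise — and the
point estimate and CI centre never use the grid, so any residual
discretization bias does not shift reported intervals.

### Intervals, convergence, decomposition

The default interval is the normal approximation, point ± z·SD of the
replicate AAFs; `"percentile"` intervals are available for skewed cases.
Under the normal approximation, a CI bound accurate to ±0.01 needs the
variance known to within $(0.01/z)^2 \approx 2.6\times10^{-5}$
(`variance_precision_for_ci()`), which is the tolerance used by the
convergence diagnostics. `convergence_analysis()` splits the replicates
into batches (default 150 × 1000), computes per-batch variances and their
running average, and `required_samples()` reports the sample count after
which the running average stays within tolerance of its final value. The
batch structure changes neither the draws nor the replicate AAFs
(batch-size invariance is tested exactly); it only structures the trace.

`decompose_variance()` randomizes one parameter group at a time
(`rr_betas`, `per_capita`, `p_abstainer`, `p_former`, `kappa`) while
holding the rest at their point values, reusing the *same* underlying
draws in every arrangement so comparisons are not clouded by fresh Monte
Carlo noise. Because the AAF is non-linear the one-at-a-time variances do
not sum to the all-random total; shares are rescaled to do so, which is an
interpretability convention, not a claim of exact functional decomposition.
1000 replicates suffice here since only relative magnitudes matter.

## Synthetic fixtures, and what the tests do and do not show

The package ships no real meta-analytic curves — coefficient vectors and
covariance matrices are not generally published in reusable form — so
`make_curve_fixture()` generates curves of the three canonical shapes
(exponential, linear via identity link, and J-shaped with an interior
minimum and sign-crossing near 45 g/day), with coefficient magnitudes
stylized so AAFs on the packaged exposure strata land in a plausible
reporting range (roughly −15% to 60%) and a covariance scaled as ~15–20%
relative SD with a −0.5 correlation in the two-term case. The mean–SD
coefficients 1.171 (men) and 1.258 (women) in `default_relation()` are
likewise fixture defaults, not estimates shipped as data. The exposure side
*is* real: the five published male strata for the Asian regions
(`asian_male_exposure()`), plus synthetic profiles in matching magnitude
ranges.

Consequently, passing tests demonstrate the correctness of the machinery —
quadrature against independent Riemann oracles, closed-form limits,
delta-method agreement, exact additivity, near-nominal CI coverage on a
known synthetic truth — but say nothing about any real disease's AAF;
substantive results require real curve specifications supplied by the
user in the documented JSON format. The synthetic covariances are also
simpler (diagonal or single-correlation) than real meta-analytic ones,
which the multivariate-normal sampler handles identically.

Problem sizes in the test-suite were chosen to keep the full run in
minutes while leaving the statistical assertions sharp: the delta-method
cross-check and convergence trace run at the full N = 150 000; the
coverage study uses 500 repetitions at N = 10 000 replicates each (the
binomial noise of a 95% hit rate at 500 repetitions is ±1%, comfortably
inside the asserted 93–97% band); simulation oracles use 10⁶ draws.

## Design choices on genuinely open points

* **rr_former lives on the curve**, not on the population state: it is a
  disease property. It defaults to 1 (no excess), with fixtures
  exercising values > 1.
* **Band conventions** are half-open `[lo, hi)`, so printed category
  labels like "0–39.9 / 40–59.9 / 60–150" tile exactly; for a continuous
  density the boundary convention carries no probability. No canonical
  category set is hard-coded — published category definitions are
  inconsistent — so bands are always explicit arguments.
* **Point estimate**: the AAF at the input means, not the replicate mean
  (both are reported). The replicate mean is biased upward by Jensen-type
  effects under parameter uncertainty, whereas the at-means AAF is the
  deterministic answer to "what is the AAF at the best estimates".
* **Degeneracy boundary is closed** (mean ≤ threshold triggers), so the
  documented 0.001 g/day flooring token always falls in the fallback.
* **The whole-table per-capita SE is combined under independence** when a
  recorded/unrecorded split is given; no covariance between the sources is
  available, and independence is the minimal assumption.

## Limitations

* Former-drinker relative risks carry no uncertainty; total variance is
  understated for diseases where that term matters.
* The engine treats the stratum's exposure parameters as independent
  inputs; any covariance between per-capita level and prevalence structure
  (plausible at the survey level) is not modelled.
* Consumption pattern dimensions (heavy episodic drinking) and injury
  outcomes are out of scope; the machinery covers average-volume chronic
  and infectious disease AAFs.
* Identity-link curves can sample to RR < 0 under extreme coefficient
  draws; the engine does not clamp them, so identity-link covariances
  should be kept realistic.
* Truncation at 150 g/day slightly understates harm where risk keeps
  rising; this is the conservative convention the coverage factor pairs
  with.
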