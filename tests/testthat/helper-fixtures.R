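# Shared helpers for building small states, curves and oracles in tests.

make_state <- function(mean_drinker = 12, kappa = 1 / 1.171^2, cap = 150,
                       p_abstainer = 0.05, p_former = 0.07) {
  population_state(p_abstainer, p_former,
                   gamma_spec(mean_drinker, kappa, cap = cap))
}

# All three canonical curve shapes at a given effect/uncertainty scale.
fixture_curves <- function(effect_scale = 1, uncertainty_scale = 1) {
  lapply(c("exponential", "linear", "jshaped"), make_curve_fixture,
         effect_scale = effect_scale, uncertainty_scale = uncertainty_scale)
}

# A grid of (state, curve) fixture combinations spanning consumption levels
# and the three dose-response shapes.
fixture_combinations <- function() {
  states <- list(
    make_state(mean_drinker = 5, p_abstainer = 0.6, p_former = 0.15),
    make_state(mean_drinker = 12, p_abstainer = 0.05, p_former = 0.07),
    make_state(mean_drinker = 25, p_abstainer = 0.2, p_former = 0.1),
    make_state(mean_drinker = 60, p_abstainer = 0.1, p_former = 0.05),
    make_state(mean_drinker = 12, kappa = 1.5, p_abstainer = 0.3,
               p_former = 0.2),
    make_state(mean_drinker = 3, kappa = 0.6, p_abstainer = 0.7,
               p_former = 0.1),
    make_state(mean_drinker = 40, kappa = 0.9, p_abstainer = 0.15,
               p_former = 0.12))
  curves <- fixture_curves()
  combos <- list()
  for (st in states) for (cv in curves)
    combos[[length(combos) + 1L]] <- list(state = st, curve = cv)
  combos
}
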