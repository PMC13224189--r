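# Shared fixtures: noiseless/noisy series simulated from the scenario
# library, and a closed-form two-state shell composition used as an
# independent oracle (direct evaluation of the exchange equilibrium with no
# intersolvent complex: x2s/x1s = f2/1 (x2/x1)^m, x1s + x2s = 1).

sim_scenario <- function(name, grid = seq(0, 1, by = 0.05), sigma = 0,
                         seed = 1) {
  params <- scenario_library()[[name]]
  simulate_exchange_series(params, grid = grid,
                           noise = noise_spec(sigma, seed),
                           mixture_name = name)
}

two_state_x2s <- function(x2, f2_1, m) {
  r <- f2_1 * (x2 / (1 - x2))^m
  r / (1 + r)
}

free_param_names <- function(params) {
  c("et1", "et2", "et12", "f2_1", "f12_1",
    if (params$variant == "corrected") "k")
}

report_digest <- function(r) {
  list(comparison = r$comparison[, c("variant", "m", "rss", "sd")],
       params = unlist(r$best_fit$params[free_param_names(r$best_fit$params)]),
       shell = r$shell$delta_s2)
}
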