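# Shared fixtures: the packaged calibrated parameter sets and the
# literature-fixed constants used by the calibration steps.

params_yh <- function(Y_h) default_params(Y_h = Y_h)

fixed_constants <- list(K_g = 0.09, K_a = 0.5, l = 0.7, k_deg = 0.0044)

chemostat <- function(D, G_in) reactor_inputs(D = D, G_in = G_in,
                                              mode = "chemostat")

# growth rate of a strain at an equilibrium state, from the state alone
mu_at_state <- function(state, p, cleaner_strain = FALSE) {
  G <- state[["G"]]; A <- state[["A"]]
  if (cleaner_strain) {
    r <- cleaner_rates(G, A, p)
    specific_growth_rate(r, state[["B_C"]], state[["B_C"]], p)
  } else {
    r <- producer_rates(G, A, p)
    B_tot <- state[["B_P"]] + state[["H"]]
    specific_growth_rate(r, state[["B_P"]], B_tot, p)
  }
}
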