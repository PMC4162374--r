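# Shared fixtures for the test suite. Everything is generated in code;
# sizes are kept small so the full suite runs in minutes.

tiny_spec <- function(N = 50, eps = 0.2, w_E = 0.1, w_I = 0.1, ...) {
  update_spec(network_spec(structure = population_structure(N = N, eps = eps)),
              w_E = w_E, w_I = w_I, ...)
}

# single unconnected neuron with a fixed threshold
lone_neuron <- function() {
  network_spec(structure = population_structure(N = 1, gamma = 0.8, eps = 0),
               heterogeneity = heterogeneity_levels(0, 0))
}

quick_config <- function(duration = 1000, n_trials = 1, dt = 0.05,
                         transient = 0, seed = 1L) {
  sim_config(duration = duration, dt = dt, transient = transient,
             n_trials = n_trials, master_seed = seed)
}

# deterministic noiseless LIF period: tau_ref + tau_m log((mu-V_r)/(mu-theta))
noiseless_period <- function(mu, tau_m = 20, V_r = 10, theta = 20,
                             tau_ref = 5) {
  tau_ref + tau_m * log((mu - V_r) / (mu - theta))
}

min_isi <- function(spikes) {
  isis <- unlist(lapply(split(spikes$time, spikes$neuron), function(t)
    if (length(t) > 1) diff(sort(t)) else numeric(0)))
  if (length(isis)) min(isis) else Inf
}
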