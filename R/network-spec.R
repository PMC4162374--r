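#' Neuron constants for the leaky integrate-and-fire model
#'
#' Membrane parameters shared by every neuron. The membrane resistance is
#' absorbed into the input scale, so all drives and synaptic weights are
#' expressed as voltages (mV).
#'
#' @param tau_m Membrane time constant (ms). Must be positive.
#' @param V_r Reset potential (mV). The membrane is clamped here for
#'   `tau_ref` after each spike.
#' @param theta_mean Mean firing threshold (mV). Must exceed `V_r`.
#' @param tau_ref Absolute refractory period (ms). Non-negative.
#'
#' @return A list of class `neuron_constants`.
#' @export
#' @examples
#' neuron_constants()
neuron_constants <- function(tau_m = 20, V_r = 10, theta_mean = 20,
                             tau_ref = 5) {
  stopifnot(tau_m > 0, tau_ref >= 0, theta_mean > V_r)
  structure(list(tau_m = tau_m, V_r = V_r, theta_mean = theta_mean,
                 tau_ref = tau_ref),
            class = "neuron_constants")
}

#' Population structure of the sparse network
#'
#' @param N Total number of neurons.
#' @param gamma Fraction of excitatory neurons, strictly between 0 and 1.
#'   `round(gamma * N)` neurons are labelled excitatory, the rest
#'   inhibitory.
#' @param eps Connection probability between any ordered pair of distinct
#'   neurons; the mean in-degree is `K = eps * N`.
#'
#' @return A list of class `population_structure` with derived fields
#'   `K`, `N_E`, `N_I`.
#' @export
population_structure <- function(N = 1000, gamma = 0.8, eps = 0.2) {
  stopifnot(N >= 1, gamma > 0, gamma < 1, eps >= 0, eps <= 1)
  n_e <- as.integer(round(gamma * N))
  structure(list(N = as.integer(N), gamma = gamma, eps = eps,
                 K = eps * N, N_E = n_e, N_I = as.integer(N) - n_e),
            class = "population_structure")
}

#' Synaptic weight matrix entries
#'
#' Voltage jump (mV) delivered to a postsynaptic neuron per presynaptic
#' spike. First index: postsynaptic population; second: presynaptic.
#' Excitatory weights must be non-negative, inhibitory non-positive.
#'
#' @param J_EE,J_IE Excitatory-to-E and excitatory-to-I weights (mV).
#' @param J_EI,J_II Inhibitory-to-E and inhibitory-to-I weights (mV).
#' @return A list of class `synaptic_weights`.
#' @export
synaptic_weights <- function(J_EE = 0.05, J_IE = 0.05,
                             J_EI = -0.08, J_II = -0.08) {
  stopifnot(J_EE >= 0, J_IE >= 0, J_EI <= 0, J_II <= 0)
  structure(list(J_EE = J_EE, J_IE = J_IE, J_EI = J_EI, J_II = J_II),
            class = "synaptic_weights")
}

#' Quenched threshold heterogeneity levels
#'
#' Standard deviations of the Gaussian firing-threshold distributions of
#' the two populations. `w = 0` gives identical thresholds (homogeneous
#' population); 0.1 mV is an almost-homogeneous baseline.
#'
#' @param w_E,w_I Threshold standard deviation (mV) of the excitatory and
#'   inhibitory populations. Non-negative.
#' @return A list of class `heterogeneity_levels`.
#' @export
heterogeneity_levels <- function(w_E = 0.1, w_I = 0.1) {
  stopifnot(w_E >= 0, w_I >= 0)
  structure(list(w_E = w_E, w_I = w_I), class = "heterogeneity_levels")
}

#' Full static specification of a heterogeneous E/I network
#'
#' Bundles neuron constants, population structure, synaptic weights and
#' heterogeneity levels. Called with no arguments it returns the default
#' parameter set: N = 1000, eps = 0.2 (K = 200), gamma = 0.8, tau_m = 20 ms,
#' V_r = 10 mV, theta = 20 mV, tau_ref = 5 ms, J_EE = J_IE = 0.05 mV,
#' J_EI = J_II = -0.08 mV, w_E = w_I = 0.1 mV.
#'
#' @param constants A [neuron_constants()] object.
#' @param structure A [population_structure()] object.
#' @param weights A [synaptic_weights()] object.
#' @param heterogeneity A [heterogeneity_levels()] object.
#' @return A list of class `network_spec`.
#' @export
#' @examples
#' spec <- network_spec()
#' spec$structure$K  # mean in-degree, 200
network_spec <- function(constants = neuron_constants(),
                         structure = population_structure(),
                         weights = synaptic_weights(),
                         heterogeneity = heterogeneity_levels()) {
  stopifnot(inherits(constants, "neuron_constants"),
            inherits(structure, "population_structure"),
            inherits(weights, "synaptic_weights"),
            inherits(heterogeneity, "heterogeneity_levels"))
  base::structure(list(constants = constants, structure = structure,
                       weights = weights, heterogeneity = heterogeneity),
                  class = "network_spec")
}

#' Default network specification
#'
#' Convenience alias for [network_spec()] with all defaults (the standard
#' cortical-like parameter set used throughout the package). The matching
#' default external drive (mu = mu0 = 15 mV, sigma = 3 mV) lives in
#' [drive_spec()].
#'
#' @return A `network_spec`.
#' @export
default_spec <- function() network_spec()

#' Modify selected fields of a network specification
#'
#' Shallow update helper: any of the flat parameters can be overridden
#' without reconstructing the nested pieces by hand.
#'
#' @param spec A `network_spec`.
#' @param ... Named scalars among `N, gamma, eps, tau_m, V_r, theta_mean,
#'   tau_ref, J_EE, J_IE, J_EI, J_II, w_E, w_I`.
#' @return The updated `network_spec`.
#' @export
#' @examples
#' update_spec(network_spec(), w_I = 2, J_EI = -0.4)
update_spec <- function(spec, ...) {
  stopifnot(inherits(spec, "network_spec"))
  ov <- list(...)
  allowed <- c("N", "gamma", "eps", "tau_m", "V_r", "theta_mean", "tau_ref",
               "J_EE", "J_IE", "J_EI", "J_II", "w_E", "w_I")
  bad <- setdiff(names(ov), allowed)
  if (length(bad)) stop("unknown spec fields: ", paste(bad, collapse = ", "))
  g <- function(name, cur) if (name %in% names(ov)) ov[[name]] else cur
  network_spec(
    constants = neuron_constants(
      tau_m = g("tau_m", spec$constants$tau_m),
      V_r = g("V_r", spec$constants$V_r),
      theta_mean = g("theta_mean", spec$constants$theta_mean),
      tau_ref = g("tau_ref", spec$constants$tau_ref)),
    structure = population_structure(
      N = g("N", spec$structure$N),
      gamma = g("gamma", spec$structure$gamma),
      eps = g("eps", spec$structure$eps)),
    weights = synaptic_weights(
      J_EE = g("J_EE", spec$weights$J_EE),
      J_IE = g("J_IE", spec$weights$J_IE),
      J_EI = g("J_EI", spec$weights$J_EI),
      J_II = g("J_II", spec$weights$J_II)),
    heterogeneity = heterogeneity_levels(
      w_E = g("w_E", spec$heterogeneity$w_E),
      w_I = g("w_I", spec$heterogeneity$w_I)))
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>\n")
  cat(sprintf("  N = %d (E %d / I %d), eps = %g, K = %g\n",
              x$structure$N, x$structure$N_E, x$structure$N_I,
              x$structure$eps, x$structure$K))
  cat(sprintf("  tau_m = %g ms, V_r = %g mV, theta = %g mV, tau_ref = %g ms\n",
              x$constants$tau_m, x$constants$V_r, x$constants$theta_mean,
              x$constants$tau_ref))
  cat(sprintf("  J_EE = %g, J_IE = %g, J_EI = %g, J_II = %g mV\n",
              x$weights$J_EE, x$weights$J_IE, x$weights$J_EI, x$weights$J_II))
  cat(sprintf("  w_E = %g mV, w_I = %g mV\n",
              x$heterogeneity$w_E, x$heterogeneity$w_I))
  invisible(x)
}

#' External drive specification
#'
#' Constant mean drive mu to all excitatory neurons and a constant bias
#' mu0 to all inhibitory neurons, plus Gaussian white noise of intensity
#' sigma (the stationary membrane-potential sd of a free membrane).
#' Optionally a slow sinusoidal signal `S0 * sin(2 pi f_s t)` is added to
#' the excitatory drive only.
#'
#' @param mu Constant drive to excitatory neurons (mV).
#' @param mu0 Constant bias to inhibitory neurons (mV).
#' @param sigma Noise intensity (mV), non-negative.
#' @param S0 Signal amplitude (mV); 0 disables the signal.
#' @param f_s Signal frequency (Hz); required positive when `S0 > 0`.
#' @return A list of class `drive_spec`.
#' @export
drive_spec <- function(mu = 15, mu0 = 15, sigma = 3, S0 = 0, f_s = 2) {
  stopifnot(sigma >= 0, S0 >= 0)
  if (S0 > 0) stopifnot(f_s > 0)
  structure(list(mu = mu, mu0 = mu0, sigma = sigma, S0 = S0, f_s = f_s),
            class = "drive_spec")
}

#' Simulation protocol configuration
#'
#' @param duration Simulated time per trial (ms).
#' @param dt Integration step (ms).
#' @param transient Initial stretch (ms) discarded before statistics.
#' @param n_trials Number of trials; each trial uses a fresh network
#'   realization and fresh noise.
#' @param master_seed Master seed from which per-purpose streams
#'   (thresholds, connectivity, noise, initial conditions) are derived.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 10000, dt = 0.05, transient = 500,
                       n_trials = 10, master_seed = 1L) {
  stopifnot(dt > 0, transient >= 0, transient < duration, n_trials >= 1)
  structure(list(duration = duration, dt = dt, transient = transient,
                 n_trials = n_trials, master_seed = as.integer(master_seed)),
            class = "sim_config")
}

# Per-purpose seed streams derived from one master seed, kept inside the
# 32-bit range R's set.seed accepts. `stream`: 1 thresholds, 2 connectivity,
# 3 noise, 4 initial conditions; `trial` offsets give fresh draws per trial.
derive_seed <- function(master_seed, stream, trial = 1L) {
  s <- (as.double(master_seed) * 7919 + stream * 104729 + trial * 15485863)
  as.integer(s %% 2147483647)
}
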