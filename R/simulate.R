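#' Simulate the stochastic LIF network
#'
#' Integrates the membrane equations of a quenched [build_realization()]
#' under a [drive_spec()] with fixed-step Euler-Maruyama. Each membrane
#' relaxes toward its drive with time constant `tau_m`, receives a
#' Gaussian increment of sd `sigma * sqrt(dt / tau_m)` per step, and an
#' instantaneous jump `J_ij` for every presynaptic spike of the previous
#' step. Crossing the quenched threshold at the end of a step emits a
#' spike, resets the membrane to `V_r` and clamps it there for `tau_ref`
#' (inputs during refractoriness are discarded). Initial potentials are
#' drawn uniformly in `[V_r, theta_i)`.
#'
#' @param realization A `network_realization`.
#' @param drive A `drive_spec`. When `drive$S0 > 0` the sinusoidal signal
#'   enters the excitatory drive only.
#' @param config A `sim_config`; `duration` and `dt` are taken from it.
#' @param seed Integer seed for the noise and initial-condition streams
#'   (defaults to `config$master_seed`). Identical inputs and seed give
#'   identical spike output.
#' @return A tibble of class `spike_data` with columns `time` (ms,
#'   sorted), `neuron` (1-based index) and `population` ("E"/"I");
#'   attributes `duration`, `dt`, `drive`, `n_neurons`, `population_sizes`.
#' @export
#' @examples
#' spec <- network_spec(structure = population_structure(N = 50))
#' r <- build_realization(spec, seed = 1)
#' s <- simulate_network(r, drive_spec(mu = 15, mu0 = 15),
#'                       sim_config(duration = 500, n_trials = 1), seed = 1)
#' nrow(s)
simulate_network <- function(realization, drive, config,
                             seed = config$master_seed) {
  stopifnot(inherits(realization, "network_realization"),
            inherits(drive, "drive_spec"), inherits(config, "sim_config"))
  cst <- realization$spec$constants
  if (config$dt > cst$tau_ref && cst$tau_ref > 0)
    stop("dt larger than the refractory period would alias the bookkeeping")
  if (config$dt > cst$tau_m / 10)
    warning("dt above tau_m/10: integration accuracy not guaranteed")

  set.seed(derive_seed(seed, 4L))
  n <- length(realization$thresholds)
  v0 <- stats::runif(n, cst$V_r, realization$thresholds)

  m <- methods::as(realization$connectivity, "CsparseMatrix")
  res <- lif_integrate_cpp(
    realization$thresholds, realization$population == "E",
    m@p, m@i, m@x, v0,
    drive$mu, drive$mu0, drive$sigma, drive$S0, drive$f_s,
    config$dt, config$duration,
    cst$tau_m, cst$V_r, cst$tau_ref,
    derive_seed(seed, 3L))

  out <- tibble::tibble(time = res$time, neuron = res$neuron,
                        population = realization$population[res$neuron])
  structure(out,
            class = c("spike_data", class(out)),
            duration = config$duration, dt = config$dt, drive = drive,
            n_neurons = n,
            population_sizes = c(E = sum(realization$population == "E"),
                                 I = sum(realization$population == "I")))
}

#' Per-neuron mean firing rates
#'
#' Spike count after the transient divided by the remaining duration.
#' Neurons that never spiked appear with rate 0.
#'
#' @param spikes A `spike_data` tibble.
#' @param transient Time (ms) discarded from the start.
#' @return A tibble with columns `neuron`, `population`, `rate` (Hz), one
#'   row per neuron of the simulated network.
#' @export
mean_rates <- function(spikes, transient = 0) {
  dur <- attr(spikes, "duration")
  stopifnot(transient < dur)
  n <- attr(spikes, "n_neurons")
  sizes <- attr(spikes, "population_sizes")
  pop <- rep(c("E", "I"), sizes)
  counts <- tabulate(spikes$neuron[spikes$time > transient], nbins = n)
  tibble::tibble(neuron = seq_len(n), population = pop,
                 rate = counts / (dur - transient) * 1000)
}

#' Time-binned population firing rate
#'
#' Histograms the spikes of one population in time and normalizes to Hz
#' per neuron (spikes per neuron per second).
#'
#' @param spikes A `spike_data` tibble.
#' @param bin Bin width (ms), positive.
#' @param population "E" or "I".
#' @param transient Time (ms) discarded from the start.
#' @return A tibble of class `rate_series` with columns `time` (bin
#'   centres, ms) and `rate` (Hz); attributes `bin`, `population`,
#'   `n_neurons`.
#' @export
population_rate <- function(spikes, bin = 1, population = "E",
                            transient = 0) {
  stopifnot(bin > 0, population %in% c("E", "I"))
  dur <- attr(spikes, "duration")
  n_pop <- attr(spikes, "population_sizes")[[population]]
  edges <- seq(transient, dur, by = bin)
  if (edges[length(edges)] < dur) edges <- c(edges, dur)
  t <- spikes$time[spikes$population == population & spikes$time > transient]
  counts <- graphics::hist(t, breaks = edges, plot = FALSE)$counts
  widths <- diff(edges)
  out <- tibble::tibble(time = edges[-length(edges)] + widths / 2,
                        rate = counts / (n_pop * widths) * 1000)
  structure(out, class = c("rate_series", class(out)),
            bin = bin, population = population, n_neurons = n_pop)
}

#' Smoothed distribution of individual firing rates
#'
#' Gaussian kernel density of per-neuron rates, reflected at 0 so that no
#' probability mass leaks to negative rates; the result integrates to 1.
#'
#' @param rates Numeric vector of per-neuron rates (Hz), non-empty.
#' @param bandwidth Kernel bandwidth (Hz); default `stats::bw.nrd0`.
#' @return A tibble with columns `rate` and `density`.
#' @export
rate_distribution <- function(rates, bandwidth = NULL) {
  stopifnot(length(rates) >= 1)
  if (is.null(bandwidth)) {
    bandwidth <- tryCatch(stats::bw.nrd0(rates), error = function(e) 1)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  d <- stats::density(rates, bw = bandwidth, from = -max(rates) - 5 * bandwidth,
                      to = max(rates) + 5 * bandwidth, n = 1024)
  keep <- d$x >= 0
  x <- d$x[keep]
  # reflect mass below zero back onto [0, inf)
  refl <- stats::approx(-d$x, d$y, xout = x, yleft = 0, yright = 0)$y
  y <- d$y[keep] + refl
  tibble::tibble(rate = x, density = y)
}

#' Spectral synchrony index of a population rate series
#'
#' Ratio of the maximum to the median power of the mean-subtracted
#' population rate within a frequency band (default 20-500 Hz). An
#' asynchronous series has no dominant spectral peak and an index near 1;
#' population oscillations push the index far above 1.
#'
#' @param series A `rate_series` tibble (at least 50 bins).
#' @param band Frequency band (Hz) searched for a peak.
#' @return A dimensionless scalar.
#' @export
synchrony_index <- function(series, band = c(20, 500)) {
  x <- series$rate
  stopifnot(length(x) > 50)
  dt_s <- (series$time[2] - series$time[1]) / 1000
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2
  freq <- (seq_along(p) - 1) / (length(p) * dt_s)
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) stop("band outside the resolvable frequency range")
  pw <- p[keep]
  med <- stats::median(pw)
  if (med == 0) return(1)
  max(pw) / med
}
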