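#' Trial-averaged synchrony index at one drive point
#'
#' Runs `config$n_trials` simulations (fresh realization and noise per
#' trial) and averages [synchrony_index()] of the excitatory population
#' rate.
#'
#' @param spec A `network_spec`.
#' @param drive A `drive_spec`.
#' @param config A `sim_config`.
#' @param bin Rate-series bin width (ms).
#' @param band Frequency band (Hz) for the spectral peak.
#' @return A list with `index` (mean over trials), `se`, `per_trial`.
#' @export
synchrony_at <- function(spec, drive, config, bin = 1, band = c(20, 500)) {
  idx <- vapply(seq_len(config$n_trials), function(tr) {
    seed <- derive_seed(config$master_seed, 5L, tr)
    r <- build_realization(spec, seed = seed)
    s <- simulate_network(r, drive, config, seed = seed)
    synchrony_index(population_rate(s, bin = bin, population = "E",
                                    transient = config$transient),
                    band = band)
  }, numeric(1))
  list(index = mean(idx),
       se = stats::sd(idx) / sqrt(length(idx)),
       per_trial = idx)
}

#' Calibrate the synchrony classification threshold
#'
#' Geometric mean of the trial-averaged synchrony indices measured at a
#' clearly asynchronous and a clearly synchronous exemplar drive. The
#' result is stored in configuration by callers, never hard-coded.
#'
#' @param spec A `network_spec`.
#' @param drive_async,drive_sync `drive_spec`s for the two exemplars.
#' @param config A `sim_config`.
#' @return A dimensionless threshold.
#' @export
calibrate_synchrony_threshold <- function(spec, drive_async, drive_sync,
                                          config) {
  a <- synchrony_at(spec, drive_async, config)$index
  s <- synchrony_at(spec, drive_sync, config)$index
  if (s <= a)
    warning("synchronous exemplar index not above asynchronous exemplar")
  sqrt(a * s)
}

#' Critical external input for synchronization onset (simulation)
#'
#' Bisects on the external input `mu` for the drive value at which the
#' trial-averaged synchrony index crosses `threshold` - the largest input
#' for which the asynchronous state survives. The bracket must straddle
#' the threshold.
#'
#' @param spec A `network_spec` (carries the heterogeneity point).
#' @param drive A `drive_spec` template; `mu` is overwritten.
#' @param mu_bracket Length-2 numeric `(lo, hi)` in mV with `lo`
#'   asynchronous and `hi` synchronous.
#' @param threshold Synchrony index classification threshold (from
#'   [calibrate_synchrony_threshold()]).
#' @param config A `sim_config`.
#' @param depth Number of bisection steps.
#' @return A one-row tibble of class `stability_result`: `mu_critical`,
#'   `uncertainty` (half final bracket), `method`, `threshold`, plus the
#'   heterogeneity point `w_E`, `w_I`.
#' @export
critical_input_sim <- function(spec, drive, mu_bracket, threshold, config,
                               depth = 6) {
  stopifnot(length(mu_bracket) == 2, diff(mu_bracket) > 0, depth >= 1)
  at <- function(m) {
    d <- drive; d$mu <- m
    synchrony_at(spec, d, config)$index
  }
  lo <- mu_bracket[1]; hi <- mu_bracket[2]
  i_lo <- at(lo); i_hi <- at(hi)
  if (!(i_lo < threshold && i_hi >= threshold))
    stop(sprintf(paste0("bracket does not straddle the synchrony threshold ",
                        "(index %.2f at mu=%g, %.2f at mu=%g, threshold %.2f)"),
                 i_lo, lo, i_hi, hi, threshold))
  for (k in seq_len(depth)) {
    mid <- (lo + hi) / 2
    if (at(mid) >= threshold) hi <- mid else lo <- mid
  }
  out <- tibble::tibble(mu_critical = (lo + hi) / 2,
                        uncertainty = (hi - lo) / 2,
                        method = "simulation", threshold = threshold,
                        w_E = spec$heterogeneity$w_E,
                        w_I = spec$heterogeneity$w_I)
  structure(out, class = c("stability_result", class(out)))
}

#' Linear fit of synchronization onset vs excitatory heterogeneity
#'
#' Least-squares line through `(w_E, mu_critical)` points; the onset is
#' expected to decrease linearly with excitatory heterogeneity, so the
#' slope of interest is negative.
#'
#' @param results A data frame with columns `w_E` and `mu_critical`
#'   (>= 3 rows), e.g. bound rows of [critical_input_sim()] results.
#' @return A one-row tibble: `slope` (mV per mV), `intercept` (mV),
#'   `residual_rms` (mV).
#' @export
linear_onset_fit <- function(results) {
  stopifnot(nrow(results) >= 3)
  fit <- stats::lm(mu_critical ~ w_E, data = results)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)))
}

#' Asynchronous/synchronous phase diagram over heterogeneity space
#'
#' Classifies every `(w_E, w_I)` grid cell at fixed drive by comparing
#' the trial-averaged synchrony index against a threshold.
#'
#' @param spec A `network_spec` template (heterogeneity overwritten per cell).
#' @param w_E_grid,w_I_grid Heterogeneity grids (mV), recommended within
#'   `[0, 2.5]` where onset detection is reliable.
#' @param drive A `drive_spec` (fixed `mu`, `mu0`).
#' @param threshold Synchrony classification threshold.
#' @param config A `sim_config`.
#' @return A tibble of class `phase_diagram` with columns `w_E`, `w_I`,
#'   `index`, `se`, `regime` ("asynchronous"/"synchronous"); attributes
#'   `mu`, `mu0`, `threshold`.
#' @export
phase_diagram <- function(spec, w_E_grid, w_I_grid, drive, threshold,
                          config) {
  cells <- tidyr::expand_grid(w_E = w_E_grid, w_I = w_I_grid)
  rows <- purrr::pmap(cells, function(w_E, w_I) {
    sp <- update_spec(spec, w_E = w_E, w_I = w_I)
    syn <- synchrony_at(sp, drive, config)
    tibble::tibble(w_E = w_E, w_I = w_I, index = syn$index, se = syn$se,
                   regime = if (syn$index >= threshold) "synchronous"
                            else "asynchronous")
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("phase_diagram", class(out)),
            mu = drive$mu, mu0 = drive$mu0, threshold = threshold)
}
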