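# erfcx for arbitrarily large positive arguments: pracma's implementation
# overflows beyond ~26, where the asymptotic series is already accurate to
# ~1e-11.
erfcx_safe <- function(x) {
  out <- numeric(length(x))
  big <- x >= 25
  if (any(!big)) out[!big] <- pracma::erfcx(x[!big])
  if (any(big)) {
    z2 <- x[big]^2
    out[big] <- (1 - 1 / (2 * z2) + 3 / (4 * z2^2) - 15 / (8 * z2^3)) /
      (x[big] * sqrt(pi))
  }
  out
}

#' Siegert first-passage firing rate of an LIF neuron
#'
#' Stationary rate of a leaky integrate-and-fire neuron driven by white
#' noise, under the diffusion approximation:
#' \deqn{\nu = \left[\tau_{ref} + \tau_m \sqrt{\pi}
#'   \int_{(V_r-\mu)/\sigma}^{(\theta-\mu)/\sigma}
#'   e^{u^2}(1+\mathrm{erf}\,u)\,du\right]^{-1}.}
#' The integrand is evaluated as the scaled complementary error function
#' `erfcx(-u)`, which stays finite for arguments down to about -26; when
#' the upper limit exceeds that range the rate is astronomically small
#' and 0 is returned.
#'
#' @param mu_tot Mean input (mV); may be a vector.
#' @param sigma_tot Input fluctuation scale (mV), strictly positive.
#' @param theta Firing threshold (mV).
#' @param constants A [neuron_constants()] object.
#' @return Rate(s) in Hz, in `[0, 1000/tau_ref)`.
#' @export
#' @examples
#' siegert_rate(15, 3, 20)            # fluctuation-driven regime
#' siegert_rate(25, 0.01, 20)         # near the deterministic limit
siegert_rate <- function(mu_tot, sigma_tot, theta,
                         constants = neuron_constants()) {
  stopifnot(sigma_tot > 0)
  vapply(mu_tot, function(m) {
    a <- (constants$V_r - m) / sigma_tot
    b <- (theta - m) / sigma_tot
    if (b >= 25) return(0)
    if (b <= a) return(1000 / (constants$tau_ref + 1e-12))
    f <- function(u) erfcx_safe(-u)
    val <- stats::integrate(f, a, b, rel.tol = 1e-10, abs.tol = 0,
                            subdivisions = 2000L)$value
    r <- 1000 / (constants$tau_ref + constants$tau_m * sqrt(pi) * val)
    if (!is.finite(r)) stop("non-finite Siegert rate (internal error)")
    r
  }, numeric(1))
}

#' Effective input moments from recurrent activity
#'
#' Diffusion-approximation mean and fluctuation scale of the total input
#' to a neuron of one population, given the stationary population rates:
#' \deqn{\mu_{tot} = \mu_{ext} + \tau_m K (\gamma J_{\alpha E}\nu_E +
#'   (1-\gamma) J_{\alpha I}\nu_I)}
#' \deqn{\sigma_{tot}^2 = \sigma^2 + \tau_m K (\gamma J_{\alpha E}^2\nu_E +
#'   (1-\gamma) J_{\alpha I}^2\nu_I)}
#' with rates in spikes/ms inside the formulas. The external mean is
#' `drive$mu` for the excitatory population and `drive$mu0` for the
#' inhibitory one.
#'
#' @param nu_E,nu_I Population rates (Hz), within `[0, 1000/tau_ref]`.
#' @param spec A `network_spec`.
#' @param drive A `drive_spec`.
#' @param population "E" or "I": which population receives the input.
#' @return A list with `mu_tot` and `sigma_tot` (mV).
#' @export
recurrent_moments <- function(nu_E, nu_I, spec, drive, population = "E") {
  stopifnot(population %in% c("E", "I"))
  cap <- 1000 / spec$constants$tau_ref
  stopifnot(nu_E >= 0, nu_I >= 0, nu_E <= cap, nu_I <= cap)
  tau_m <- spec$constants$tau_m
  K <- spec$structure$K
  gam <- spec$structure$gamma
  jE <- if (population == "E") spec$weights$J_EE else spec$weights$J_IE
  jI <- if (population == "E") spec$weights$J_EI else spec$weights$J_II
  mu_ext <- if (population == "E") drive$mu else drive$mu0
  nE <- nu_E / 1000; nI <- nu_I / 1000   # spikes/ms
  list(mu_tot = mu_ext + tau_m * K * (gam * jE * nE + (1 - gam) * jI * nI),
       sigma_tot = sqrt(drive$sigma^2 +
                        tau_m * K * (gam * jE^2 * nE + (1 - gam) * jI^2 * nI)))
}

# Gauss-Hermite / Gauss-Legendre nodes, cached per order (and interval).
gh_cache <- new.env(parent = emptyenv())
gh_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) gh_cache[[key]] <- pracma::gaussHermite(n)
  gh_cache[[key]]
}
gl_nodes <- function(n, lo, hi) {
  key <- sprintf("gl-%d-%.9g-%.9g", n, lo, hi)
  if (is.null(gh_cache[[key]]))
    gh_cache[[key]] <- pracma::gaussLegendre(n, lo, hi)
  gh_cache[[key]]
}

#' Heterogeneity-averaged population transfer function
#'
#' The mean rate of a population whose thresholds are Gaussian with mean
#' `theta` and sd `w`, given the network rates:
#' \deqn{\Phi_\alpha(\nu_E,\nu_I) = \int P_\alpha(\theta')\,
#'   \nu_{Sg}(\mu_{tot}, \sigma_{tot}, \theta')\, d\theta'}
#' evaluated by Gauss-Hermite quadrature. When the distribution is wide
#' enough that quadrature nodes reach below `V_r` (where thresholds are
#' rejection-resampled during network construction), the average is taken
#' over the correspondingly truncated Gaussian with Gauss-Legendre nodes
#' on the admissible range; at the widths of interest the truncated mass
#' is at most ~3e-7, so the two branches agree far below any tolerance
#' used.
#'
#' @inheritParams recurrent_moments
#' @param n_nodes Number of Gauss-Hermite nodes (odd recommended).
#' @return Population rate (Hz).
#' @export
averaged_transfer <- function(nu_E, nu_I, spec, drive, population = "E",
                              n_nodes = 41) {
  w <- if (population == "E") spec$heterogeneity$w_E else spec$heterogeneity$w_I
  mom <- recurrent_moments(nu_E, nu_I, spec, drive, population)
  theta <- spec$constants$theta_mean
  if (w <= 0)
    return(siegert_rate(mom$mu_tot, mom$sigma_tot, theta, spec$constants))
  v_r <- spec$constants$V_r
  gh <- gh_nodes(n_nodes)
  th <- theta + sqrt(2) * w * gh$x
  if (all(th > v_r)) {
    rates <- vapply(th, function(t)
      siegert_rate(mom$mu_tot, mom$sigma_tot, t, spec$constants), numeric(1))
    return(sum(gh$w * rates) / sqrt(pi))
  }
  # wide distributions reach below the reset, where thresholds are
  # rejection-resampled: average over the truncated Gaussian instead,
  # with Gauss-Legendre nodes on the admissible range (the integrand is
  # smooth there, so convergence in n_nodes is retained)
  gl <- gl_nodes(n_nodes, v_r, theta + 10 * w)
  dens <- stats::dnorm(gl$x, theta, w)
  rates <- vapply(gl$x, function(t)
    siegert_rate(mom$mu_tot, mom$sigma_tot, t, spec$constants), numeric(1))
  sum(gl$w * dens * rates) / sum(gl$w * dens)
}

#' Self-consistent mean-field fixed point
#'
#' Solves \eqn{\nu_E = \Phi_E(\nu_E, \nu_I)}, \eqn{\nu_I = \Phi_I(\nu_E,
#' \nu_I)} by damped fixed-point iteration (`nu <- (1-damping) nu +
#' damping Phi(nu)`), falling back to a two-dimensional root finder on
#' `nu - Phi(nu)` if the iteration stalls. Non-convergence is reported
#' honestly via the `converged` flag, never as a silent value.
#'
#' @param spec A `network_spec` (its `w_E`, `w_I` are used).
#' @param drive A `drive_spec`.
#' @param init Initial `(nu_E, nu_I)` guess (Hz).
#' @param tol Convergence tolerance on the residual `max|nu - Phi(nu)|` (Hz).
#' @param max_iter Iteration cap for the damped scheme.
#' @param damping Damping factor in (0, 1].
#' @param n_nodes Gauss-Hermite order passed through.
#' @return A list of class `fixed_point`: `nu_E`, `nu_I` (Hz),
#'   `converged`, `residual` (Hz), `n_iterations`, `method`.
#' @export
#' @examples
#' solve_fixed_point(network_spec(), drive_spec(mu = 15, mu0 = 15))
solve_fixed_point <- function(spec, drive, init = c(5, 5), tol = 1e-6,
                              max_iter = 10000L, damping = 0.3,
                              n_nodes = 41) {
  stopifnot(tol > 0, damping > 0, damping <= 1)
  cap <- 1000 / spec$constants$tau_ref
  phi <- function(nu) {
    nu <- pmin(pmax(nu, 0), cap)   # solver iterates may wander out of range
    c(averaged_transfer(nu[1], nu[2], spec, drive, "E", n_nodes),
      averaged_transfer(nu[1], nu[2], spec, drive, "I", n_nodes))
  }
  nu <- pmax(init, 0)
  res <- Inf; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    f <- phi(nu)
    res <- max(abs(f - nu))
    if (res < tol)
      return(structure(list(nu_E = nu[1], nu_I = nu[2], converged = TRUE,
                            residual = res, n_iterations = it,
                            method = "damped"), class = "fixed_point"))
    nu <- (1 - damping) * nu + damping * f
  }
  # fallback: root of nu - Phi(nu)
  root <- tryCatch(
    pracma::fsolve(function(x) x - phi(x), nu, tol = tol / 10),
    error = function(e) NULL)
  if (!is.null(root)) {
    nu2 <- pmax(root$x, 0)
    res2 <- max(abs(phi(nu2) - nu2))
    if (res2 < tol)
      return(structure(list(nu_E = nu2[1], nu_I = nu2[2], converged = TRUE,
                            residual = res2, n_iterations = it,
                            method = "root"), class = "fixed_point"))
  }
  structure(list(nu_E = nu[1], nu_I = nu[2], converged = FALSE,
                 residual = res, n_iterations = it, method = "damped"),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("<fixed_point> nu_E = %.4f Hz, nu_I = %.4f Hz (%s, %s, residual %.2e Hz)\n",
              x$nu_E, x$nu_I,
              if (x$converged) "converged" else "NOT converged",
              x$method, x$residual))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.fixed_point <- function(x, ...) {
  tibble::tibble(population = c("E", "I"), rate = c(x$nu_E, x$nu_I))
}

#' @export
#' @importFrom generics glance
glance.fixed_point <- function(x, ...) {
  tibble::tibble(nu_E = x$nu_E, nu_I = x$nu_I, converged = x$converged,
                 residual = x$residual, n_iterations = x$n_iterations,
                 method = x$method)
}

#' Mean-field f-I curves of both populations
#'
#' Solves the fixed point at each external input `mu` of an increasing
#' grid, warm-starting each solve from the previous solution
#' (continuation keeps the solver robust near the f-I onset).
#'
#' @param spec A `network_spec`.
#' @param drive A `drive_spec` template; its `mu` is replaced by each
#'   grid value, `mu0` and `sigma` are kept.
#' @param mu_grid Strictly increasing numeric vector of external inputs (mV).
#' @param ... Passed to [solve_fixed_point()].
#' @return A tibble of class `rate_curve` with columns `mu`, `nu_E`,
#'   `nu_I`, `converged`; attribute `spec`.
#' @export
#' @examples
#' fI_curve(network_spec(), drive_spec(mu0 = 15), seq(12, 16, by = 1))
fI_curve <- function(spec, drive, mu_grid, ...) {
  stopifnot(all(diff(mu_grid) > 0))
  nu <- c(1, 1)
  rows <- purrr::map(mu_grid, function(m) {
    d <- drive; d$mu <- m
    fp <- solve_fixed_point(spec, d, init = nu, ...)
    nu <<- c(fp$nu_E, fp$nu_I)
    tibble::tibble(mu = m, nu_E = fp$nu_E, nu_I = fp$nu_I,
                   converged = fp$converged)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("rate_curve", class(out)), spec = spec,
            drive = drive)
}
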