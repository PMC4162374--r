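# Independent brute-force evaluation of the first-passage integral using
# the raw integrand (no scaled-erfc rewriting); valid for moderate limits.
siegert_bruteforce <- function(mu, sigma, theta, tau_m = 20, V_r = 10,
                               tau_ref = 5) {
  f <- function(u) exp(u^2) * (1 + pracma::erf(u))
  v <- stats::integrate(f, (V_r - mu) / sigma, (theta - mu) / sigma,
                        rel.tol = 1e-12)$value
  1000 / (tau_ref + tau_m * sqrt(pi) * v)
}

test_that("Siegert rate obeys its limits and matches brute-force quadrature", {
  # far subthreshold: astronomically small
  expect_lt(siegert_rate(0, 0.5, 20), 1e-10)
  # refractory saturation from below
  expect_lt(siegert_rate(1e4, 3, 20), 200)
  expect_gt(siegert_rate(1e4, 3, 20), 199)
  # noiseless suprathreshold limit: deterministic LIF rate
  expect_equal(siegert_rate(25, 0.01, 20), 1000 / (5 + 20 * log(3)),
               tolerance = 1e-3)
  # independent quadrature oracle at the default operating point
  expect_equal(siegert_rate(15, 3, 20), siegert_bruteforce(15, 3, 20),
               tolerance = 1e-8)
  expect_equal(siegert_rate(12, 1, 20), siegert_bruteforce(12, 1, 20),
               tolerance = 1e-8)
  expect_error(siegert_rate(15, 0, 20))
})

test_that("recurrent moments reproduce hand-computed values", {
  spec <- network_spec()
  drv <- drive_spec(mu = 15, mu0 = 15)
  # silent network: moments are the external drive
  m0 <- recurrent_moments(0, 0, spec, drv, "E")
  expect_equal(m0$mu_tot, 15)
  expect_equal(m0$sigma_tot, 3)
  # tau_m*K*(gamma*J_EE + (1-gamma)*J_EI)*nu = 20*200*(0.8*0.05-0.2*0.08)*0.01
  m <- recurrent_moments(10, 10, spec, drv, "E")
  expect_equal(m$mu_tot - 15, 0.96)
  # fluctuations grow with either rate
  expect_gt(recurrent_moments(20, 10, spec, drv, "E")$sigma_tot, m$sigma_tot)
  expect_gt(recurrent_moments(10, 20, spec, drv, "E")$sigma_tot, m$sigma_tot)
  # inhibitory population sees mu0
  expect_equal(recurrent_moments(0, 0, spec, drive_spec(mu = 15, mu0 = 12),
                                 "I")$mu_tot, 12)
  expect_error(recurrent_moments(-1, 0, spec, drv))
  expect_error(recurrent_moments(0, 300, spec, drv))
})

test_that("heterogeneity averaging is exact at w = 0 and continuous in w", {
  drv <- drive_spec(mu = 15, mu0 = 15)
  s0 <- update_spec(network_spec(), w_E = 0)
  base <- averaged_transfer(5, 5, s0, drv, "E")
  m <- recurrent_moments(5, 5, s0, drv, "E")
  expect_identical(base, siegert_rate(m$mu_tot, m$sigma_tot, 20))
  near0 <- averaged_transfer(5, 5, update_spec(network_spec(), w_E = 1e-4),
                             drv, "E")
  expect_equal(near0, base, tolerance = 1e-6)
})

test_that("Gauss-Hermite averaging matches Monte-Carlo threshold averaging", {
  drv <- drive_spec(mu = 15, mu0 = 15)
  spec <- update_spec(network_spec(), w_E = 2)
  gh <- averaged_transfer(5, 5, spec, drv, "E")
  m <- recurrent_moments(5, 5, spec, drv, "E")
  set.seed(99)
  th <- sample_thresholds(2e4, 20, 2)
  mc <- vapply(th, function(t) siegert_rate(m$mu_tot, m$sigma_tot, t),
               numeric(1))
  expect_lt(abs(gh - mean(mc)), 3 * sd(mc) / sqrt(length(mc)))
})

test_that("quadrature order is converged at 41 nodes", {
  drv <- drive_spec(mu = 15, mu0 = 15)
  for (w in c(0.5, 2.5)) {
    spec <- update_spec(network_spec(), w_E = w)
    a <- averaged_transfer(4, 4, spec, drv, "E", n_nodes = 41)
    b <- averaged_transfer(4, 4, spec, drv, "E", n_nodes = 81)
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("decoupled fixed point equals the external-drive transfer", {
  spec <- network_spec(weights = synaptic_weights(0, 0, 0, 0))
  drv <- drive_spec(mu = 15, mu0 = 15)
  fp <- solve_fixed_point(spec, drv)
  expect_true(fp$converged)
  expect_equal(fp$nu_E, averaged_transfer(0, 0, spec, drv, "E"),
               tolerance = 1e-6)
  expect_equal(fp$nu_I, averaged_transfer(0, 0, spec, drv, "I"),
               tolerance = 1e-6)
})

test_that("homogeneous-limit fixed point matches an independent solver", {
  # straightforward two-population diffusion fixed point, written without
  # the package's transfer machinery
  spec <- update_spec(network_spec(), w_E = 0, w_I = 0)
  drv <- drive_spec(mu = 15, mu0 = 15)
  plain_phi <- function(nu) {
    out <- numeric(2)
    for (k in 1:2) {
      jE <- c(0.05, 0.05)[k]; jI <- c(-0.08, -0.08)[k]
      mu_t <- c(15, 15)[k] + 20 * 200 * (0.8 * jE * nu[1] +
                                         0.2 * jI * nu[2]) / 1000
      s_t <- sqrt(9 + 20 * 200 * (0.8 * jE^2 * nu[1] +
                                  0.2 * jI^2 * nu[2]) / 1000)
      f <- function(u) pracma::erfcx(-u)
      v <- stats::integrate(f, (10 - mu_t) / s_t, (20 - mu_t) / s_t,
                            rel.tol = 1e-10)$value
      out[k] <- 1000 / (5 + 20 * sqrt(pi) * v)
    }
    out
  }
  indep <- pracma::fsolve(function(x) x - plain_phi(x), c(3, 3))$x
  fp <- solve_fixed_point(spec, drv)
  expect_true(fp$converged)
  expect_equal(c(fp$nu_E, fp$nu_I), indep, tolerance = 1e-5)
})

test_that("damped iteration and root solver agree across heterogeneity", {
  drv <- drive_spec(mu = 15, mu0 = 15)
  for (w in list(c(0, 0), c(1, 0.5), c(2.5, 2.5))) {
    spec <- update_spec(network_spec(), w_E = w[1], w_I = w[2])
    fp <- solve_fixed_point(spec, drv)
    expect_true(fp$converged)
    phi <- function(x) c(averaged_transfer(x[1], x[2], spec, drv, "E"),
                         averaged_transfer(x[1], x[2], spec, drv, "I"))
    root <- pracma::fsolve(function(x) x - phi(x),
                           c(fp$nu_E + 0.5, fp$nu_I + 0.5))$x
    expect_equal(c(fp$nu_E, fp$nu_I), root, tolerance = 1e-4)
    expect_true(all(c(fp$nu_E, fp$nu_I) >= 0))
    expect_true(all(c(fp$nu_E, fp$nu_I) <= 200))
  }
})

test_that("f-I curves are monotone in drive and respond to heterogeneity", {
  drv <- drive_spec(mu0 = 15)
  g <- seq(12, 18, by = 1.5)
  hom <- fI_curve(update_spec(network_spec(), w_E = 0, w_I = 0), drv, g)
  expect_true(all(diff(hom$nu_E) >= 0))
  expect_true(all(hom$converged))

  he <- fI_curve(update_spec(network_spec(), w_E = 2, w_I = 0), drv, g)
  expect_true(all(he$nu_E > hom$nu_E))   # w_E raises excitatory activity
  expect_true(all(he$nu_I > hom$nu_I))   # ... and inhibitory activity

  hi <- fI_curve(update_spec(network_spec(), w_E = 0, w_I = 2), drv, g)
  expect_true(all(hi$nu_E < hom$nu_E))   # w_I suppresses excitation
  expect_true(all(hi$nu_I > hom$nu_I))   # ... and boosts inhibition

  expect_error(fI_curve(network_spec(), drv, c(15, 14)))
})

test_that("tidy and glance methods summarize fitted objects", {
  fp <- solve_fixed_point(network_spec(), drive_spec(mu = 15, mu0 = 15))
  td <- tidy(fp)
  expect_equal(td$population, c("E", "I"))
  expect_equal(td$rate, c(fp$nu_E, fp$nu_I))
  gl <- glance(fp)
  expect_true(gl$converged)
  expect_lt(gl$residual, 1e-6)
})
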