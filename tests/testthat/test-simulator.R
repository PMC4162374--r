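test_that("noiseless suprathreshold neuron fires at the closed-form period", {
  r <- build_realization(lone_neuron(), seed = 1)
  drv <- drive_spec(mu = 25, mu0 = 25, sigma = 0)
  s <- simulate_network(r, drv, quick_config(duration = 5000, dt = 0.01),
                        seed = 2)
  period <- noiseless_period(25)         # 5 + 20*log(3) ~ 26.97 ms
  rate_theory <- 1000 / period           # ~ 37.08 Hz
  rate_sim <- mean_rates(s)$rate[1]
  expect_equal(rate_sim, rate_theory, tolerance = 0.01)
  # inter-spike intervals are the period, up to one dt of discretization
  isis <- diff(s$time)
  expect_true(all(abs(isis - period) <= 0.02 + 1e-12))
})

test_that("deterministic subthreshold drive produces no spikes", {
  r <- build_realization(lone_neuron(), seed = 1)
  s <- simulate_network(r, drive_spec(mu = 19, mu0 = 19, sigma = 0),
                        quick_config(duration = 2000), seed = 3)
  expect_equal(nrow(s), 0)
})

test_that("unconnected-neuron rates match the Siegert transfer function", {
  spec <- update_spec(network_spec(structure =
                        population_structure(N = 100, eps = 0)),
                      w_E = 0, w_I = 0)
  r <- build_realization(spec, seed = 4)
  s <- simulate_network(r, drive_spec(mu = 15, mu0 = 15, sigma = 3),
                        quick_config(duration = 10000, transient = 500),
                        seed = 5)
  mr <- mean_rates(s, transient = 500)
  se <- sd(mr$rate) / sqrt(nrow(mr))
  expect_lt(abs(mean(mr$rate) - siegert_rate(15, 3, 20)), 3 * se)
})

test_that("rate accuracy is dt-robust across the usable step range", {
  spec <- update_spec(network_spec(structure =
                        population_structure(N = 200, eps = 0)),
                      w_E = 0, w_I = 0)
  r <- build_realization(spec, seed = 6)
  target <- siegert_rate(15, 3, 20)
  for (dt in c(0.1, 0.05, 0.01)) {
    s <- simulate_network(r, drive_spec(mu = 15, mu0 = 15, sigma = 3),
                          quick_config(duration = 5000, dt = dt,
                                       transient = 500), seed = 7)
    mr <- mean_rates(s, transient = 500)
    se <- sd(mr$rate) / sqrt(nrow(mr))
    expect_lt(abs(mean(mr$rate) - target), 4 * se)
  }
})

test_that("refractoriness bounds inter-spike intervals and rates", {
  spec <- tiny_spec(N = 50, eps = 0.5)
  r <- build_realization(spec, seed = 8)
  s <- simulate_network(r, drive_spec(mu = 40, mu0 = 40, sigma = 5),
                        quick_config(duration = 2000), seed = 9)
  expect_gt(nrow(s), 0)
  expect_gte(min_isi(s), 5)
  expect_true(all(mean_rates(s)$rate <= 200))
})

test_that("simulation is deterministic under a fixed seed", {
  r <- build_realization(tiny_spec(), seed = 10)
  drv <- drive_spec(mu = 18, mu0 = 15)
  a <- simulate_network(r, drv, quick_config(), seed = 11)
  b <- simulate_network(r, drv, quick_config(), seed = 11)
  expect_identical(a$time, b$time)
  expect_identical(a$neuron, b$neuron)
  c <- simulate_network(r, drv, quick_config(), seed = 12)
  expect_false(identical(a$time, c$time))
})

test_that("simulate_network rejects aliasing steps and warns on coarse dt", {
  r <- build_realization(tiny_spec(), seed = 1)
  expect_error(simulate_network(r, drive_spec(), quick_config(dt = 6)),
               "refractory")
  expect_warning(simulate_network(r, drive_spec(),
                                  quick_config(duration = 100, dt = 2.5)),
                 "accuracy")
})

test_that("mean_rates divides post-transient counts by the window", {
  r <- build_realization(tiny_spec(N = 30), seed = 13)
  s <- simulate_network(r, drive_spec(mu = 18, mu0 = 18),
                        quick_config(duration = 2000), seed = 14)
  mr <- mean_rates(s, transient = 400)
  counts <- tabulate(s$neuron[s$time > 400], nbins = 30)
  expect_equal(mr$rate, counts / 1600 * 1000)
  expect_equal(nrow(mr), 30)   # silent neurons present with rate 0
})

test_that("population rate conserves spike counts and handles empty input", {
  r <- build_realization(tiny_spec(N = 40), seed = 15)
  s <- simulate_network(r, drive_spec(mu = 18, mu0 = 18),
                        quick_config(duration = 2000), seed = 16)
  rs <- population_rate(s, bin = 10, population = "E")
  n_e <- attr(s, "population_sizes")[["E"]]
  expect_equal(sum(rs$rate) * 10 / 1000 * n_e,
               sum(s$population == "E"))
  # time-mean equals the mean of per-neuron rates for that population
  mr <- mean_rates(s)
  expect_equal(mean(rs$rate), mean(mr$rate[mr$population == "E"]),
               tolerance = 1e-10)

  empty <- simulate_network(r, drive_spec(mu = 12, mu0 = 12, sigma = 0),
                            quick_config(duration = 1000), seed = 1)
  expect_true(all(population_rate(empty, bin = 5)$rate == 0))
})

test_that("rate distribution integrates to one and concentrates correctly", {
  d <- rate_distribution(rep(7, 100), bandwidth = 0.5)
  expect_equal(d$rate[which.max(d$density)], 7, tolerance = 0.05)
  expect_equal(sum(d$density) * diff(d$rate[1:2]), 1, tolerance = 1e-3)

  set.seed(1)
  d2 <- rate_distribution(abs(rnorm(500, 3, 2)))
  expect_equal(sum(d2$density) * diff(d2$rate[1:2]), 1, tolerance = 1e-3)
  expect_true(all(d2$rate >= 0))
})

test_that("heterogeneity broadens and skews the excitatory rate distribution", {
  drv <- drive_spec(mu = 15, mu0 = 15)
  cfg <- quick_config(duration = 3000, transient = 500)
  skews <- vapply(c(0.1, 2), function(w) {
    r <- build_realization(update_spec(network_spec(), w_E = w), seed = 20)
    s <- simulate_network(r, drv, cfg, seed = 21)
    rates <- mean_rates(s, transient = 500)
    x <- rates$rate[rates$population == "E"]
    mean((x - mean(x))^3) / sd(x)^3
  }, numeric(1))
  expect_gt(skews[2], skews[1])
})

test_that("synchrony index separates flat, noisy and oscillatory series", {
  mk <- function(x) structure(tibble::tibble(
    time = seq(0.5, by = 1, length.out = length(x)), rate = x),
    class = c("rate_series", "tbl_df", "tbl", "data.frame"))
  set.seed(2)
  noise <- mk(rnorm(1000))
  # white-noise surrogate: max/median of an exponential periodogram over
  # ~500 band bins sits around log(m)/log(2) ~ 9, far below oscillatory values
  expect_lt(synchrony_index(noise), 30)
  sine <- mk(10 + 5 * sin(2 * pi * 100 * seq(0.5, by = 1,
                                             length.out = 1000) / 1000) +
               rnorm(1000, 0, 0.3))
  expect_gt(synchrony_index(sine), 10)
  expect_gt(synchrony_index(sine), 10 * synchrony_index(noise))
  expect_error(synchrony_index(mk(rnorm(30))))
})
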