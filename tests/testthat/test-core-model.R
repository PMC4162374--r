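test_that("default specification carries the standard parameter set", {
  spec <- default_spec()
  expect_equal(spec$structure$K, 200)
  expect_equal(spec$structure$N_E, 800L)
  expect_equal(spec$structure$N_I, 200L)
  expect_equal(spec$weights$J_EE, spec$weights$J_IE)
  expect_equal(spec$weights$J_EI, spec$weights$J_II)
  expect_equal(spec$constants$tau_m, 20)
  expect_equal(spec$constants$V_r, 10)
  expect_equal(spec$constants$theta_mean, 20)
  expect_equal(spec$constants$tau_ref, 5)
  expect_equal(drive_spec()$sigma, 3)
})

test_that("spec constructors validate their invariants", {
  expect_error(neuron_constants(theta_mean = 9, V_r = 10))
  expect_error(neuron_constants(tau_m = 0))
  expect_error(population_structure(gamma = 1))
  expect_error(population_structure(eps = 1.2))
  expect_error(synaptic_weights(J_EE = -0.1))
  expect_error(synaptic_weights(J_EI = 0.1))
  expect_error(heterogeneity_levels(w_E = -1))
  expect_error(update_spec(network_spec(), nonsense = 1))
  up <- update_spec(network_spec(), w_I = 2, J_EI = -0.4)
  expect_equal(up$heterogeneity$w_I, 2)
  expect_equal(up$weights$J_EI, -0.4)
  expect_equal(up$weights$J_II, -0.08)  # untouched fields keep defaults
})

test_that("threshold sampling is Gaussian, truncated above reset, reproducible", {
  expect_equal(sample_thresholds(5, 20, 0), rep(20, 5))
  expect_error(sample_thresholds(5, 9, 1, V_r = 10))

  th <- sample_thresholds(1e5, 20, 2, seed = 42)
  expect_equal(mean(th), 20, tolerance = 0.05 / 20)
  expect_equal(sd(th), 2, tolerance = 0.05 / 2)
  expect_true(all(th > 10))

  th2 <- sample_thresholds(1e5, 20, 2, seed = 42)
  expect_identical(th, th2)

  # heavy-rejection regime still respects the lower bound
  low <- sample_thresholds(2e4, 11, 2, V_r = 10, seed = 1)
  expect_true(all(low > 10))
})

test_that("realization has independent edges with label-determined weights", {
  expect_equal(Matrix::nnzero(
    build_realization(tiny_spec(N = 20, eps = 0), seed = 1)$connectivity), 0)

  full <- build_realization(tiny_spec(N = 10, eps = 1), seed = 1)
  expect_equal(Matrix::nnzero(full$connectivity), 90)  # no self-edges
  expect_true(all(Matrix::diag(full$connectivity) == 0))

  m <- as.matrix(full$connectivity)
  pop <- full$population
  expect_true(all(m[pop == "E", pop == "E"][upper.tri(diag(sum(pop == "E")))
                                            | lower.tri(diag(sum(pop == "E")))] == 0.05))
  expect_true(all(m[pop == "E", pop == "I"] == -0.08))
  expect_true(all(m[pop == "I", pop == "E"] == 0.05))

  # edge count follows Binomial(N(N-1), eps): exact test at level 1e-3
  r <- build_realization(network_spec(), seed = 7)
  n_edges <- Matrix::nnzero(r$connectivity)
  p <- stats::binom.test(n_edges, 1000 * 999, 0.2)$p.value
  expect_gt(p, 1e-3)
  expect_equal(mean(in_degrees(r)), 200, tolerance = 3 * sqrt(200 * 0.8) /
                 sqrt(1000) / 200)
})

test_that("realization is a pure function of spec and seed", {
  a <- build_realization(tiny_spec(), seed = 11)
  b <- build_realization(tiny_spec(), seed = 11)
  expect_identical(a$thresholds, b$thresholds)
  expect_true(all(a$connectivity == b$connectivity))
  c <- build_realization(tiny_spec(), seed = 12)
  expect_false(identical(a$thresholds, c$thresholds))
})

test_that("E and I threshold draws are independent across populations", {
  spec <- tiny_spec(N = 400, w_E = 2, w_I = 2)
  r <- build_realization(spec, seed = 3)
  e <- r$thresholds[r$population == "E"]
  i <- r$thresholds[r$population == "I"]
  k <- min(length(e), length(i))
  expect_lt(abs(cor(e[seq_len(k)], i[seq_len(k)])), 0.15)
})
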