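test_that("bell_rate matches its closed form and boundary behaviour", {
  # zero-force limit returns k0 exactly
  expect_identical(bell_rate(0, k0 = 0.1, x = 0.5), 0.1)
  # unit exponent when F = kBT / x
  expect_equal(bell_rate(4.114, k0 = 1, x = 1, kBT = 4.114), exp(1))
  # frozen scalar evaluation of k0 * exp(F x / kBT)
  expect_equal(bell_rate(20, k0 = 0.05, x = 0.3, kBT = 4.114),
               0.214961215523935, tolerance = 1e-12)
  # monotone non-decreasing in F
  F <- seq(0, 100, by = 5)
  expect_true(all(diff(bell_rate(F, 0.2, 0.4)) >= 0))
  expect_error(bell_rate(-1, 1, 1), "non-negative")
  expect_error(bell_rate(1, 1, 1, kBT = 0), "positive")
})

test_that("step_probability is a proper hazard with the semigroup property", {
  expect_identical(step_probability(0, 1e-3), 0)
  expect_lt(abs(step_probability(1e9, 1) - 1), 1e-12)
  # composing n substeps equals one step over n*dt at constant rate
  p1 <- step_probability(3.7, 0.08)
  p_sub <- step_probability(3.7, 0.08 / 16)
  expect_equal(1 - (1 - p_sub)^16, p1, tolerance = 1e-12)
  expect_error(step_probability(-1, 0.1), "non-negative")
  expect_error(step_probability(1, 0), "positive")
})

test_that("fixed-step survival agrees with exponential-clock sampling", {
  # survival of a constant-rate transition over T: fixed-step Monte Carlo
  # versus direct exponential draws (the Gillespie clock for one channel)
  set.seed(11)
  rate <- 10; dt <- 0.01; nsteps <- 10; n <- 2e5
  # fixed-step: bond survives a step with prob exp(-rate dt)
  p_step <- step_probability(rate, dt)
  surv_fixed <- rowSums(matrix(runif(n * nsteps) < p_step, n)) == 0
  # exponential clocks
  surv_exp <- rexp(n, rate) > nsteps * dt
  p_hat_f <- mean(surv_fixed); p_hat_e <- mean(surv_exp)
  se <- sqrt(p_hat_e * (1 - p_hat_e) / n) * sqrt(2)
  expect_lt(abs(p_hat_f - p_hat_e), 3 * se + 1e-12)
  # and both agree with the analytic survival exp(-rate T)
  expect_lt(abs(p_hat_e - exp(-rate * nsteps * dt)), 3 * se)
})

test_that("network_force reduces series and parallel springs exactly", {
  # single protofilament of n identical springs: F = (k/n) * extension
  ns <- 5; k <- 2
  lat <- filament_lattice(ns, 2, spring_k = k, rest = 40, bond_k = 0,
                         bond_state = matrix(FALSE, ns - 1, 1))
  d <- ns * 40 + 30
  expect_equal(network_force(lat, d), 2 * (k / ns) * 30, tolerance = 1e-12)
  # m parallel protofilaments: F = m * (k/n) * extension
  lat4 <- filament_lattice(ns, 4, spring_k = k, rest = 40, bond_k = 5)
  expect_equal(network_force(lat4, d), 4 * (k / ns) * 30, tolerance = 1e-12)
  # zero at the rest length
  expect_equal(network_force(lat4, ns * 40), 0, tolerance = 1e-12)
})

test_that("network_force matches a dense node-by-node solve on a mixed lattice", {
  # 3 serial x 2 parallel with one open lateral bond and unequal rests
  bond_state <- matrix(c(TRUE, FALSE), 2, 1)
  lat <- filament_lattice(3, 2,
                          spring_k = matrix(c(1, 2, 1.5, 0.8, 1.2, 2.5), 3, 2),
                          rest = matrix(c(40, 45, 50, 42, 38, 55), 3, 2),
                          bond_k = 7, bond_state = bond_state)
  for (d in c(120, 160, 220))
    expect_equal(network_force(lat, d), dense_network_force(lat, d),
                 tolerance = 1e-9)
})

test_that("equivalent-network force agrees with the dense solve on random lattices", {
  set.seed(42)
  n_ok <- 0
  while (n_ok < 100) {
    ns <- sample(2:10, 1); np <- sample(2:10, 1)
    lat <- random_lattice(ns, np)
    d <- sum(colMeans(lat$rest)) * runif(1, 0.9, 1.6)
    f_ref <- tryCatch(dense_network_force(lat, d), error = function(e) NULL)
    if (is.null(f_ref) || !is.finite(f_ref)) next
    f <- network_force(lat, d)
    expect_equal(f, f_ref, tolerance = 1e-9)
    n_ok <- n_ok + 1
  }
})

test_that("network_force is continuous and non-decreasing in distance", {
  set.seed(7)
  lat <- random_lattice(6, 4, p_broken = 0)
  d <- seq(100, 500, by = 5)
  f <- vapply(d, function(dd) network_force(lat, dd), 0)
  expect_true(all(diff(f) >= -1e-9))
})

test_that("a fully broken cross-section signals rupture, not a number", {
  ok <- matrix(TRUE, 3, 2); ok[2, ] <- FALSE
  lat <- filament_lattice(3, 2, spring_k = 1, rest = 40, spring_ok = ok)
  expect_error(network_force(lat, 150), class = "ifmech_rupture")
})

test_that("mechanical_params validates its domain", {
  p <- mechanical_params()
  expect_equal(p$kBT, 4.114)
  expect_error(mechanical_params(kBT = -1))
  expect_error(mechanical_params(dt = 0))
  expect_error(mechanical_params(pulling_speed = 0))
})
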