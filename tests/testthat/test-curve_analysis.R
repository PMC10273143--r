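test_that("reference_length inverts a linear trace and enforces preconditions", {
  # F = 0.05 * d crosses 5 pN at d = 100
  tr <- data.frame(cycle = 1, branch = "stretch", t_s = 1:50,
                   d_nm = seq(2, 100, by = 2),
                   F_pN = 0.05 * seq(2, 100, by = 2))
  expect_equal(reference_length(tr), 100, tolerance = 1e-12)
  # starting above the threshold is a pre-tension error
  tr_hi <- tr; tr_hi$F_pN <- tr_hi$F_pN + 10
  expect_error(reference_length(tr_hi), "pre-tension")
  # never reaching the threshold is an error
  tr_lo <- tr; tr_lo$F_pN <- tr_lo$F_pN * 0.01
  expect_error(reference_length(tr_lo), "never reaches")
})

test_that("force-window fit recovers slope and intercept exactly on clean lines", {
  eps <- seq(0, 0.6, by = 0.002)
  # F = 500 * eps: kappa = 500, eps_e = 0
  f1 <- fit_force_window(eps, 500 * eps)
  expect_equal(f1$kappa_f, 500, tolerance = 1e-9)
  expect_equal(f1$eps_e, 0, tolerance = 1e-9)
  # shifted line F = 500 * (eps - 0.2)
  f2 <- fit_force_window(eps, 500 * (eps - 0.2))
  expect_equal(f2$kappa_f, 500, tolerance = 1e-9)
  expect_equal(f2$eps_e, 0.2, tolerance = 1e-9)
  # too few in-window samples yields NA, not an error
  f3 <- fit_force_window(c(0.1, 0.5), c(10, 250))
  expect_true(is.na(f3$kappa_f) && is.na(f3$eps_e))
})

test_that("force-window fit is unbiased on noisy lines", {
  set.seed(5)
  eps <- seq(0, 0.6, by = 0.004)
  ests <- replicate(400, {
    F <- 500 * (eps - 0.2) + rnorm(length(eps), 0, 5)
    fit <- fit_force_window(eps, F)
    c(fit$kappa_f, fit$eps_e)
  })
  expect_lt(abs(mean(ests[1, ]) - 500) / 500, 0.02)
  expect_lt(abs(mean(ests[2, ]) - 0.2), 0.005)
})

test_that("strain-window fit equals the force-window slope on a line and honours correction", {
  eps <- seq(0, 0.6, by = 0.002)
  F <- 500 * eps
  expect_equal(fit_strain_window(eps, F),
               fit_force_window(eps, F)$kappa_f, tolerance = 1e-9)
  # corrected strain re-zeros a shifted curve
  Fs <- 500 * (eps - 0.15)
  k_corr <- fit_strain_window(eps, Fs, corrected = TRUE, eps_e = 0.15)
  expect_equal(k_corr, 500, tolerance = 1e-9)
  expect_true(is.na(fit_strain_window(eps[eps < 0.05], F[eps < 0.05])))
})

test_that("hysteresis energies follow trapezoid geometry", {
  tc <- triangle_cycle(relax_fraction = 0.5)
  st <- tc[tc$branch == "stretch", ]; rx <- tc[tc$branch == "relax", ]
  # identical branches dissipate nothing
  rx0 <- st[rev(seq_len(nrow(st))), ]; rx0$branch <- "relax"
  e0 <- hysteresis_energy(st, rx0, L0 = 900)
  expect_equal(e0$E_dis, 0, tolerance = 1e-9)
  expect_equal(e0$E_rel, 0, tolerance = 1e-9)
  # zero-force relax dissipates everything
  rxz <- rx0; rxz$F_pN <- 0
  expect_equal(hysteresis_energy(st, rxz, L0 = 900)$E_rel, 1,
               tolerance = 1e-12)
  # relax at half the force dissipates exactly half
  eh <- hysteresis_energy(st, rx, L0 = 900)
  expect_equal(eh$E_rel, 0.5, tolerance = 1e-9)
  # absolute energy per length in kBT/um
  expect_equal(eh$E_abs_per_len, eh$E_dis / 4.114 / 0.9, tolerance = 1e-12)
})

test_that("metrics are stable under uniform resampling of the trace", {
  tc <- triangle_cycle(n = 150)
  tc_dense <- triangle_cycle(n = 1500)
  m1 <- cycle_metrics(tc); m2 <- cycle_metrics(tc_dense)
  expect_lt(abs(m1$kappa_f - m2$kappa_f) / m2$kappa_f, 1e-3)
  expect_lt(abs(m1$E_rel - m2$E_rel), 1e-3)
  expect_lt(abs(m1$eps_e - m2$eps_e), 1e-3)
})

test_that("elongation-vs-maxstrain regression recovers an exact line", {
  met <- data.frame(cycle = rep(4:9, 4),
                    eps_max = rep(seq(0.5, 1.1, length.out = 6), 4),
                    eps_e = NA)
  met$eps_e <- 0.45 * met$eps_max - 0.1
  fit <- elongation_vs_maxstrain(met)
  expect_equal(fit$slope, 0.45, tolerance = 1e-9)
  expect_equal(fit$intercept, -0.1, tolerance = 1e-9)
  # threshold excludes shallow cycles
  met$eps_e[met$eps_max <= 0.4] <- 99
  expect_equal(elongation_vs_maxstrain(met)$slope, 0.45, tolerance = 1e-9)
  expect_true(is.na(elongation_vs_maxstrain(met[1:2, ])$slope))
})

test_that("cohort summary uses linear-interpolation order statistics", {
  met <- data.frame(cycle = rep(1, 100), eps_e = sample(1:100))
  sm <- cohort_summary(met, "eps_e")
  expect_equal(sm$median, 50.5)
  expect_equal(sm$q25, 25.75)
  expect_equal(sm$q75, 75.25)
  # single value: all three equal it
  sm1 <- cohort_summary(data.frame(cycle = 2, eps_e = 7), "eps_e")
  expect_true(all(unlist(sm1[, c("median", "q25", "q75")]) == 7))
  # permutation invariance
  met2 <- met[sample(nrow(met)), ]
  expect_equal(cohort_summary(met2, "eps_e"), sm)
})

test_that("Freedman-Diaconis width follows the formula and scales homogeneously", {
  expect_equal(fd_binwidth(1:8), 3.5, tolerance = 1e-12)
  v <- rnorm(200)
  expect_equal(fd_binwidth(v * 3.7), 3.7 * fd_binwidth(v), tolerance = 1e-12)
  # width shrinks with n at fixed IQR
  w1 <- 2 * IQR(1:8) * 8^(-1 / 3)
  expect_equal(fd_binwidth(1:8), w1)
  # zero IQR falls back and flags it
  wf <- fd_binwidth(c(1, 1, 1, 1, 5))
  expect_true(isTRUE(attr(wf, "fallback")))
  expect_error(fd_binwidth(3), "at least two")
})

test_that("dissipation-elongation pairing reports exact monotone association", {
  met <- data.frame(cycle = 1:10,
                    delta_eps_e = c(NA, sort(runif(9))),
                    E_rel = NA)
  met$E_rel <- met$delta_eps_e^2 + 0.1  # monotone transform
  out <- dissipation_vs_delta_eps(met)
  expect_equal(nrow(out$pairs), 9)
  expect_equal(out$rank_correlation, 1)
})
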