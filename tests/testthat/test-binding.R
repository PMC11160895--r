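conc_series <- function(kd) kd * 2^seq(-3, 4)  # 8 concentrations, 128-fold

test_that("steady-state 1:1 fits recover exact and noisy parameters", {
  kd <- 62e-6; rmax <- 100
  iso <- simulate_isotherm(kd, rmax, conc_series(kd))
  fit <- fit_steady_state(iso)
  expect_equal(unname(fit$parameters["K_D"]), kd, tolerance = 1e-6)
  expect_equal(unname(fit$parameters["R_max"]), rmax, tolerance = 1e-6)
  # half-saturation identity: predicted response at C = K_D is R_max / 2
  kd_hat <- fit$parameters[["K_D"]]; rmax_hat <- fit$parameters[["R_max"]]
  expect_equal(rmax_hat * kd_hat / (kd_hat + kd_hat), rmax_hat / 2)
  # 2% noise: K_D recovered within 10%
  noisy <- simulate_isotherm(kd, rmax, conc_series(kd), sigma = 0.02,
                             seed = 271)
  fit2 <- fit_steady_state(noisy)
  expect_equal(unname(fit2$parameters["K_D"]), kd, tolerance = 0.10)
  expect_error(fit_steady_state(binding_isotherm(c(1, 2, 3) * 1e-6,
                                                 c(1, 2, 3))),
               "4 concentrations")
})

test_that("steady-state fitting is scale-equivariant in the response", {
  kd <- 5e-6
  iso <- simulate_isotherm(kd, 50, conc_series(kd), sigma = 0.01, seed = 7)
  f1 <- fit_steady_state(iso)
  iso2 <- iso; iso2$response <- iso2$response * 3
  f2 <- fit_steady_state(iso2)
  expect_equal(f2$parameters[["K_D"]], f1$parameters[["K_D"]],
               tolerance = 1e-6)
  expect_equal(f2$parameters[["R_max"]], 3 * f1$parameters[["R_max"]],
               tolerance = 1e-6)
})

test_that("steady-state K_D estimates are unbiased across noise realizations", {
  kd <- 62e-6
  kds <- vapply(1:200, function(i) {
    iso <- simulate_isotherm(kd, 100, conc_series(kd), sigma = 0.02,
                             seed = 1000 + i)
    fit_steady_state(iso)$parameters[["K_D"]]
  }, numeric(1))
  expect_equal(median(kds), kd, tolerance = 0.03)
})

test_that("an extrapolated K_D beyond the tested range is flagged", {
  conc <- c(1, 2, 5, 10, 20, 50) * 1e-6
  iso <- simulate_isotherm(500e-6, 100, conc)
  expect_warning(fit_steady_state(iso), "extrapolated")
})

test_that("dissociation fits recover k_off exactly and obey closed forms", {
  tr <- simulate_decay(0.039, 100, offset = 0, duration = 120)
  fit <- fit_dissociation(tr)
  expect_equal(unname(fit$parameters["k_off"]), 0.039, tolerance = 1e-6)
  expect_equal(unname(fit$parameters["amplitude"]), 100, tolerance = 1e-4)
  # half-life closed form
  tr2 <- simulate_decay(0.0693, 50, duration = 60)
  k <- fit_dissociation(tr2)$parameters[["k_off"]]
  expect_equal(log(2) / k, 10.0, tolerance = 1e-3)
  # biphasic with f -> 1 degenerates to the single-exponential rate
  tr3 <- simulate_decay(c(0.05, 0.005), c(80, 0), duration = 200)
  fit3 <- fit_dissociation(tr3, phases = 2)
  expect_equal(unname(fit3$parameters["k_off"] * fit3$parameters["fraction"] +
                        fit3$parameters["k2"] * (1 - fit3$parameters["fraction"])),
               0.05, tolerance = 0.02)
  # genuine biphasic recovery
  tr4 <- simulate_decay(c(0.08, 0.008), c(60, 40), duration = 400,
                        n_points = 400)
  fit4 <- fit_dissociation(tr4, phases = 2)
  expect_equal(unname(fit4$parameters["k_off"]), 0.08, tolerance = 1e-3)
  expect_equal(unname(fit4$parameters["k2"]), 0.008, tolerance = 1e-3)
  expect_equal(unname(fit4$parameters["fraction"]), 0.6, tolerance = 1e-3)
})

test_that("dissociation rates are invariant to the time origin", {
  tr <- simulate_decay(0.02, 30, offset = 2, duration = 250)
  f1 <- fit_dissociation(tr)
  shifted <- kinetic_trace(tr$time + 37, tr$response)
  f2 <- fit_dissociation(shifted)
  expect_equal(f2$parameters[["k_off"]], f1$parameters[["k_off"]],
               tolerance = 1e-6)
})

test_that("association rates follow k_on = k_off / K_D with propagation", {
  # the TCR4 numbers: k_off 0.039 1/s, K_D 62 uM -> 629 1/(M s) at 3 s.f.
  r <- association_rate(0.039, 62e-6, k_off_se = 0.006, K_D_se = 6e-6)
  expect_equal(signif(r$k_on, 3), 629)
  expect_gt(r$k_on_se, 0)
  expect_equal(association_rate(1, 1)$k_on, 1)
  # inverse check on the control: printed k_on and K_D imply k_off
  expect_equal(1.5e4 * 1.7e-6, 0.0255, tolerance = 1e-3)
  expect_equal(association_rate(0.0255, 1.7e-6)$k_on, 1.5e4,
               tolerance = 1e-3)
  # round trip to 1e-12 relative error
  k_on <- association_rate(0.039, 62e-6)$k_on
  expect_equal(k_on * 62e-6, 0.039, tolerance = 1e-12)
  expect_error(association_rate(-1, 1), "positive")
})

test_that("electrostatic destabilization evaluates the pKa-shift formula", {
  expect_equal(round(electrostatic_destabilization(4.9, 6.1), 1), 1.6)
  expect_equal(electrostatic_destabilization(5.5, 5.5), 0)
  expect_equal(electrostatic_destabilization(5.0, 6.0),
               2.303 * 1.987 * 298.15 / 1000, tolerance = 1e-12)
})

test_that("melt-derivative fits recover single and double transitions", {
  single <- simulate_melt(55, 3, 1)
  f1 <- fit_melt_derivative(single, components = 1)
  expect_equal(unname(f1$parameters["T_m"]), 55, tolerance = 1e-3)
  double <- simulate_melt(c(48, 62), c(3, 3.5), c(1, 0.7), sigma = 0.03,
                          seed = 41)
  f2 <- fit_melt_derivative(double, components = 2)
  expect_equal(unname(f2$parameters["T_m"]), 48, tolerance = 0.3 / 48)
  expect_equal(unname(f2$parameters["T_m_2"]), 62, tolerance = 0.3 / 62)
  expect_lt(f2$parameters[["T_m"]], f2$parameters[["T_m_2"]])
  # amplitude-zero second component degenerates to the single-Gaussian T_m
  degen <- simulate_melt(c(55, 70), c(3, 3), c(1, 0))
  f3 <- fit_melt_derivative(degen, components = 2)
  dominant <- if (f3$parameters[["amplitude"]] >= f3$parameters[["amplitude_2"]])
    f3$parameters[["T_m"]] else f3$parameters[["T_m_2"]]
  expect_equal(dominant, 55, tolerance = 1e-2)
  # overlapping components are flagged
  close <- simulate_melt(c(54, 56), c(4, 4), c(1, 0.9))
  f4 <- fit_melt_derivative(close, components = 2)
  expect_true(length(f4$notes) > 0)
})
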