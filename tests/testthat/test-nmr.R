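trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

test_that("a single noiseless Lorentzian is recovered to high precision", {
  pk <- data.frame(center = -125.0, fwhm = 0.2, area = 3)
  # window wide relative to the linewidth so tail truncation is negligible
  spec <- simulate_spectrum(pk, ppm_range = c(-160, -90), n_points = 8192)
  fit <- fit_lorentzians(spec, 1)
  expect_equal(fit$peaks$center, -125.0, tolerance = 1e-6)
  expect_equal(fit$peaks$fwhm, 0.2, tolerance = 1e-5)
  expect_equal(fit$peaks$area, 3, tolerance = 1e-4)
  expect_equal(fit$peaks$fraction, 1)
  # noiseless integral sanity: spectrum integral matches the area closely
  x <- rev(spec$ppm); y <- rev(spec$intensity)
  expect_equal(trapz(x, y), 3, tolerance = 0.005 * 3)
})

test_that("the three-state 15/77/8 deconvolution is recovered under noise", {
  centers <- c(-123.09, -125.18, -126.90)
  pk <- data.frame(center = centers, fwhm = c(0.35, 0.30, 0.35),
                   area = c(15, 77, 8))
  spec <- simulate_spectrum(pk, sigma = 0.01, ppm_range = c(-129, -121),
                            seed = 88)
  fit <- fit_lorentzians(spec, 3)
  expect_equal(fit$peaks$center, centers, tolerance = 0.01)
  expect_equal(100 * fit$peaks$fraction, c(15, 77, 8), tolerance = 0.15)
  expect_true(all(abs(100 * fit$peaks$fraction - c(15, 77, 8)) < 2))
  expect_equal(sum(fit$peaks$fraction), 1, tolerance = 1e-6)
})

test_that("heavily overlapped peaks still conserve total fitted area", {
  pk <- data.frame(center = c(-125.0, -125.1), fwhm = c(0.2, 0.2),
                   area = c(2, 1))
  spec <- simulate_spectrum(pk, ppm_range = c(-160, -90), n_points = 8192)
  fit <- suppressWarnings(
    fit_lorentzians(spec, 2, init = c(-125.0, -125.1)))
  x <- rev(spec$ppm); y <- rev(spec$intensity)
  expect_equal(sum(fit$peaks$area), trapz(x, y), tolerance = 0.01 * 3)
})

test_that("peak centers are recovered within FWHM/10 across noise seeds", {
  pk <- data.frame(center = c(-124.0, -126.0), fwhm = c(0.3, 0.3),
                   area = c(2, 1))
  errs <- vapply(1:25, function(i) {
    spec <- simulate_spectrum(pk, sigma = 0.02, ppm_range = c(-128, -122),
                              n_points = 1024, seed = 500 + i)
    fit <- fit_lorentzians(spec, 2, init = pk$center)
    max(abs(sort(fit$peaks$center) - sort(pk$center)))
  }, numeric(1))
  expect_true(all(errs < 0.3 / 10))
})

test_that("area fractions normalize and reject degenerate input", {
  expect_equal(area_fractions(c(1, 1)), c(0.5, 0.5))
  expect_equal(area_fractions(c(15, 77, 8)), c(0.15, 0.77, 0.08))
  expect_equal(area_fractions(5), 1)
  expect_error(area_fractions(c(0, 0)), "zero")
})

test_that("exchange models enforce detailed balance at construction", {
  m <- exchange_model(c(0.6, 0.4), c(-123, -125), rates = 2)
  expect_equal(m$p[1] * m$k[1, 2], m$p[2] * m$k[2, 1], tolerance = 1e-12)
  expect_equal(sum(m$p), 1)
})

test_that("saturation transfer reproduces the two-state closed form", {
  # no exchange: no transfer
  m0 <- exchange_model(c(0.5, 0.5), c(-123, -125), rates = 0)
  expect_equal(simulate_saturation_transfer(m0, 1, t_sat = 0.4),
               c(0, 1))
  # symmetric two-state, k = 2/s, t_sat = 0.4 s: residual exp(-k t)
  m <- exchange_model(c(0.5, 0.5), c(-123, -125), rates = 2)
  res <- simulate_saturation_transfer(m, 1, t_sat = 0.4)
  expect_equal(res[2], exp(-2 * 0.4), tolerance = 1e-9)
  expect_equal(round(res[2], 3), 0.449)
  # three-state fully connected slow exchange: all residuals drop below 1
  m3 <- exchange_model(c(0.15, 0.77, 0.08),
                       c(-123.09, -125.18, -126.90),
                       rates = rbind(c(0, 2, 1), c(0, 0, 5), c(0, 0, 0)))
  r3 <- simulate_saturation_transfer(m3, 2, t_sat = 0.5)
  expect_true(all(r3[c(1, 3)] < 1))
  expect_true(all(r3 >= 0))
})

test_that("saturation-transfer residuals are monotone in time and rate", {
  m <- function(k) exchange_model(c(0.5, 0.5), c(-123, -125), rates = k)
  ts <- c(0.1, 0.3, 0.6, 1.2)
  res_t <- vapply(ts, function(t)
    simulate_saturation_transfer(m(2), 1, t)[2], numeric(1))
  expect_true(all(diff(res_t) < 0))
  ks <- c(0.5, 1, 2, 4)
  res_k <- vapply(ks, function(k)
    simulate_saturation_transfer(m(k), 1, 0.4)[2], numeric(1))
  expect_true(all(diff(res_k) < 0))
})

test_that("EXSY matrices conserve magnetization and match closed forms", {
  # zero exchange: identity (no cross-peaks), as for a non-exchanging peak
  m0 <- exchange_model(c(0.7, 0.3), c(-125.05, -125.9), rates = 0)
  expect_equal(predict_exsy_crosspeaks(m0, 0.05), diag(2),
               tolerance = 1e-12)
  # rows sum to 1 for any valid model
  m3 <- exchange_model(c(0.15, 0.77, 0.08), c(-123, -125, -127),
                       rates = rbind(c(0, 3, 1), c(0, 0, 2), c(0, 0, 0)))
  P <- predict_exsy_crosspeaks(m3, 0.05)
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-9)
  expect_true(all(P >= 0))
  # two-state closed form: P12 = p2 (1 - exp(-(k12 + k21) tau))
  m2 <- exchange_model(c(0.6, 0.4), c(-123, -125),
                       rates = rbind(c(0, 2), c(0, 0)))
  k12 <- m2$k[1, 2]; k21 <- m2$k[2, 1]
  tau <- 0.05
  P2 <- predict_exsy_crosspeaks(m2, tau)
  expect_equal(P2[1, 2], 0.4 * (1 - exp(-(k12 + k21) * tau)),
               tolerance = 1e-9)
  expect_equal(P2[2, 1], 0.6 * (1 - exp(-(k12 + k21) * tau)),
               tolerance = 1e-9)
})
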