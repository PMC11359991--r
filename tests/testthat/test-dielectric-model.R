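test_that("Fricke shape factor matches hand arithmetic", {
  expect_equal(fricke_K(2, 5, 78), 3 / (2 + 5 / 78), tolerance = 1e-12)
  expect_equal(fricke_K(2, 5, 78), 1.4534, tolerance = 1e-4)
  expect_equal(fricke_K(1.5, 5, 78), 2.5 / (1.5 + 5 / 78), tolerance = 1e-12)
  expect_equal(fricke_K(3, 78, 78), 1)
})

test_that("mixture formulas are anchored at pure water and decrease with solids", {
  expect_equal(fricke_static_permittivity(0), 78)
  expect_equal(maxwell_static_permittivity(0), 78)
  # matched phases leave the Maxwell mixture unchanged
  for (P in c(0, 0.3, 0.948))
    expect_equal(maxwell_static_permittivity(mixture_inputs(P, eps_p = 78)), 78)
  # monotone decreasing in P when inclusions are less polar than water
  P <- seq(0, 1, by = 0.01)
  expect_true(all(diff(sapply(P, fricke_static_permittivity)) < 0))
  expect_true(all(diff(sapply(P, maxwell_static_permittivity)) < 0))
  expect_error(mixture_inputs(1.1), "P")
})

test_that("mixture formulas reproduce the published static permittivities", {
  # high-water tissues through Fricke (eps_w 78, eps_p 5, x 2)
  wc_vol <- c(muscle = 0.752, liver = 0.701, heart = 0.879, kidney = 0.731)
  eps_pub <- c(muscle = 51.47, liver = 46.99, heart = 64.02, kidney = 49.59)
  eps_hat <- sapply(1 - wc_vol, fricke_static_permittivity)
  expect_true(all(abs(eps_hat - eps_pub) / eps_pub < 0.015))
  # fat through Maxwell (eps_p 2.5)
  fat_hat <- maxwell_static_permittivity(1 - 0.052)
  expect_lt(abs(fat_hat - 3.930) / 3.930, 0.02)
})

test_that("parameter assignment follows the water-content branching rules", {
  p <- assign_parameters(0.752)
  expect_equal(p$eps_inf, 4)
  expect_equal(p$eps_s, 51.47, tolerance = 0.015)
  expect_equal(p$tau, 6.36e-12)
  expect_equal(p$alpha, 0.1)
  expect_equal(p$sigma_s, 0)

  p <- assign_parameters(0.052)
  expect_equal(p$eps_inf, 2.5)
  expect_equal(p$eps_s, 3.930, tolerance = 0.02)

  # 50% exactly maps to the high-water branch
  expect_equal(assign_parameters(0.5)$eps_inf, 4)
  expect_equal(assign_parameters(0.4999)$eps_inf, 2.5)
  expect_error(assign_parameters(1.2), "wc_volume")
})

test_that("closed-form real/imag decomposition equals the complex form", {
  set.seed(99)
  n <- 2000
  for (i in seq_len(n)) {
    eps_inf <- runif(1, 1, 10)
    p <- cole_cole_params(eps_inf, eps_inf + runif(1, 0, 80),
                          tau = 10^runif(1, -12, -10.5),
                          alpha = runif(1, 0, 0.5))
    f <- 10^runif(1, 8, 11)
    z <- cole_cole_complex(p, f)
    expect_equal(cole_cole_real(p, f), Re(z), tolerance = 1e-12)
    expect_equal(cole_cole_imag(p, f), abs(Im(z)), tolerance = 1e-12)
  }
})

test_that("limits recover the static and high-frequency permittivities", {
  p <- cole_cole_params(4, 51.47)
  expect_equal(cole_cole_real(p, 1), 51.47, tolerance = 1e-6)
  expect_equal(cole_cole_imag(p, 1), 0, tolerance = 1e-6)
  expect_equal(cole_cole_real(p, 1e15) / 4, 1, tolerance = 0.01)
  # degenerate pole: flat lossless spectrum
  flat <- cole_cole_params(4, 4)
  expect_equal(cole_cole_real(flat, c(1e9, 1e10)), c(4, 4))
  expect_equal(cole_cole_imag(flat, c(1e9, 1e10)), c(0, 0))
})

test_that("static conductivity adds exactly its 1/omega loss term", {
  f <- c(1e9, 5e9, 2e10)
  p0 <- cole_cole_params(4, 51.47, sigma_s = 0)
  p1 <- cole_cole_params(4, 51.47, sigma_s = 0.1)
  expect_equal(cole_cole_real(p1, f), cole_cole_real(p0, f))
  expect_equal(cole_cole_imag(p1, f) - cole_cole_imag(p0, f),
               0.1 / (2 * pi * f * eps_vacuum()), tolerance = 1e-12)
  # hand value of the conductivity term alone
  lossless <- cole_cole_params(4, 4, sigma_s = 0.1)
  expect_equal(cole_cole_imag(lossless, 1e9), 1.798, tolerance = 1e-3)
})

test_that("model values match the published spot checks", {
  muscle <- cole_cole_params(4, 51.47)
  expect_equal(cole_cole_real(muscle, 1e9), 50.98, tolerance = 0.005)
  expect_equal(cole_cole_imag(muscle, 1e9), 2.560, tolerance = 0.02)
  heart <- cole_cole_params(4, 64.02)
  expect_equal(cole_cole_real(heart, 10e9), 52.24, tolerance = 0.005)
  fat <- cole_cole_params(2.5, 3.930)
  expect_equal(cole_cole_imag(fat, 5e9), 0.290, tolerance = 0.02)
})

test_that("spectra are well-formed and monotone over the band", {
  grid <- default_frequency_grid()
  expect_length(grid, 191)
  expect_equal(range(grid), c(1e9, 20e9))

  sp <- cole_cole_spectrum(cole_cole_params(4, 51.47), grid)
  expect_s3_class(sp, "permittivity_spectrum")
  expect_true(all(diff(sp$eps_real) < 0))
  expect_true(all(sp$eps_imag >= 0))
  # element-wise evaluation agrees with a dense brute-force loop
  dense <- vapply(grid, function(f)
    cole_cole_real(cole_cole_params(4, 51.47), f), 0)
  expect_equal(sp$eps_real, dense)
  expect_error(cole_cole_spectrum(cole_cole_params(4, 51.47), numeric(0)),
               "empty")
  expect_error(cole_cole_spectrum(cole_cole_params(4, 51.47), c(2e9, 1e9)),
               "increasing")
})
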