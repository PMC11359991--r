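test_that("dryness rule fires at the first sub-threshold weight change", {
  r <- check_dryness(c(0, 24), c(10, 10))
  expect_true(r$is_dry)
  expect_equal(r$end_index, 2L)
  expect_equal(r$dry_weight, 10)

  r <- check_dryness(c(0, 24, 48), c(10, 5, 3))
  expect_false(r$is_dry)
  expect_equal(r$last_relative_change, 0.4)

  r <- check_dryness(c(0, 24, 48, 72), c(10, 5, 3, 2.99))
  expect_true(r$is_dry)
  expect_equal(r$end_index, 4L)
  expect_equal(r$dry_weight, 2.99)
  expect_equal(r$last_relative_change, 0.01 / 3)

  expect_error(check_dryness(0, 10), "two weighings")
  expect_error(check_dryness(c(0, 24), c(10, -1)), "positive")
})

test_that("dryness rule is invariant to uniform weight rescaling", {
  t <- c(0, 24, 48, 96, 120)
  w <- c(12, 6.1, 4.2, 4.01, 4.005)
  base <- check_dryness(t, w)
  for (k in c(1e-3, 0.5, 7, 1e4)) {
    r <- check_dryness(t, k * w)
    expect_equal(r$end_index, base$end_index)
    expect_equal(r$last_relative_change, base$last_relative_change)
  }
})

test_that("mass-basis water content matches the gravimetric formula", {
  expect_equal(mass_water_content(10, 10), 0)
  expect_equal(mass_water_content(10, 0), 1)
  expect_equal(mass_water_content(10, 2.92), 0.708)
  expect_error(mass_water_content(10, 11), "evaporation")
  # in [0,1] and decreasing in Wd at fixed Ww
  Wd <- seq(0, 10, by = 0.5)
  wc <- mass_water_content(10, Wd)
  expect_true(all(wc >= 0 & wc <= 1))
  expect_true(all(diff(wc) < 0))
})

test_that("volume-basis water content uses the density of water", {
  expect_equal(volume_water_content(10, 10, 9.44), 0)
  expect_equal(volume_water_content(10, 2.92, 9.44),
               7.08 / (0.997 * 9.44), tolerance = 1e-12)
  expect_error(volume_water_content(10, 3, 0), "Vw")
  # algebraic identity: wc_volume = wc_mass * (Ww/Vw) / rho_water
  set.seed(42)
  for (i in 1:20) {
    Ww <- runif(1, 5, 30)
    Wd <- runif(1, 0, Ww)
    Vw <- runif(1, 5, 30)
    expect_equal(suppressWarnings(volume_water_content(Ww, Wd, Vw)),
                 mass_water_content(Ww, Wd) * (Ww / Vw) / 0.997,
                 tolerance = 1e-12)
  }
  # values above 1 are flagged, not clipped
  expect_warning(wc <- volume_water_content(10, 0, 8), "exceeds 1")
  expect_gt(wc, 1)
})

test_that("tissue aggregation reports mean, sd and combined uncertainty", {
  # build Ww/Wd pairs whose mass-basis water contents are 0.70, 0.71, 0.72
  s <- data.frame(Ww = c(10, 10, 10), Wd = c(3.0, 2.9, 2.8),
                  Vw = c(9.4, 9.4, 9.4))
  out <- aggregate_tissue(s, tissue = "muscle")
  expect_equal(out$wc_mass_mean, 0.71)
  expect_equal(out$wc_mass_sd, 0.01)
  expect_equal(out$n_samples, 3L)
  expect_false(out$single_sample)
  # volume-basis combined uncertainty dominates the across-sample sd
  expect_gte(out$wc_volume_uncertainty, sd(out$per_sample$wc_volume))

  expect_warning(one <- aggregate_tissue(s[1, ], tissue = "m"), "single sample")
  expect_equal(one$wc_mass_sd, 0)
  expect_true(one$single_sample)
})

test_that("percentage weight series is normalized to the initial weighing", {
  ps <- percent_weight_series(data.frame(time_h = c(0, 24), weight_g = c(10, 5)))
  expect_equal(ps$percent, c(100, 50))
  cfg <- noise_free_presets()$fat
  camp <- simulate_campaigns(cfg)
  s1 <- camp[camp$sample_id == camp$sample_id[1], ]
  ps <- percent_weight_series(s1)
  expect_equal(ps$percent[1], 100)
  # fat-like kinetics: constant within 0.5% from 48 h onward
  from48 <- ps$percent[ps$time_h >= 48]
  expect_lt(max(from48) - min(from48), 0.5)
  expect_error(percent_weight_series(data.frame(time_h = 1, weight_g = 2)),
               "t = 0")
})

test_that("estimator recovers the generator truth across noisy campaigns", {
  # modest Monte-Carlo here; the full per-tissue study runs in the
  # acceptance suite
  cfg <- tissue_presets("muscle")
  est <- vapply(1:30, function(s) {
    cfg$seed <- 500L + s
    suppressWarnings(estimate_water_content(simulate_campaigns(cfg)))$wc_mass_mean
  }, 0)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - cfg$true_wc_mass), 3 * se)
})

test_that("water-content estimation rejects malformed campaigns", {
  expect_error(estimate_water_content(data.frame()), "non-empty")
  one <- data.frame(tissue = "m", sample_id = "m_01", time_h = 0,
                    weight_g = 10, volume_cm3 = 9)
  expect_error(estimate_water_content(one), "two weighings")
})
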