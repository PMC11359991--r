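test_that("drying curve follows the closed-form exponential decay", {
  expect_equal(drying_curve(0, Ww = 10, Wd = 3, tau_d = 20), 10)
  expect_equal(drying_curve(1e6, Ww = 10, Wd = 3, tau_d = 20), 3)
  expect_equal(drying_curve(20, Ww = 10, Wd = 3, tau_d = 20),
               3 + 7 * exp(-1), tolerance = 1e-12)
  # vectorized and monotone non-increasing
  w <- drying_curve(seq(0, 300, by = 1), Ww = 10, Wd = 3, tau_d = 20)
  expect_true(all(diff(w) <= 0))
  expect_error(drying_curve(1, Ww = -1, Wd = 3, tau_d = 20), "Ww")
  expect_error(drying_curve(1, Ww = 10, Wd = 0, tau_d = 20), "Wd")
  expect_error(drying_curve(1, Ww = 10, Wd = 3, tau_d = 0), "tau_d")
  expect_error(drying_curve(1, Ww = 3, Wd = 10, tau_d = 20), "exceed")
})

test_that("weight quantization rounds to the balance readability", {
  expect_equal(quantize_weight(5.3449, 0.01), 5.34)
  expect_equal(quantize_weight(0, 0.01), 0)
  # exact tie rounds away from zero
  expect_equal(quantize_weight(2.5, 1), 3)
  # idempotent on a grid of random weights
  w <- quantize_weight(runif(50, 0, 30), 0.01)
  expect_equal(quantize_weight(w, 0.01), w)
  expect_error(quantize_weight(-1), "non-negative")
  expect_error(quantize_weight(1, 0), "readability")
})

test_that("campaign configuration validates its invariants", {
  expect_s3_class(campaign_config("muscle", 0.7), "campaign_config")
  expect_error(campaign_config("m", 1.2), "true_wc_mass")
  expect_error(campaign_config("m", 0.7, n_samples = 0), "n_samples")
  expect_error(campaign_config("m", 0.7, schedule = c(0, 24, 24)),
               "strictly increasing")
  expect_error(campaign_config("m", 0.7, schedule = c(5, 24)), "start at 0")
  expect_error(campaign_config("m", 0.7, schedule = 0), "two weighing times")
})

test_that("identical seeds reproduce identical campaigns bit-for-bit", {
  cfg <- tissue_presets("muscle", seed = 7L)
  expect_identical(simulate_campaigns(cfg), simulate_campaigns(cfg))
  cfg2 <- cfg
  cfg2$seed <- 8L
  expect_false(identical(simulate_campaigns(cfg), simulate_campaigns(cfg2)))
})

test_that("noise-free weighing series are monotone and recover the truth", {
  for (cfg in noise_free_presets()) {
    camp <- simulate_campaigns(cfg)
    for (s in split(camp, camp$sample_id))
      expect_true(all(diff(s$weight_g[order(s$time_h)]) <= 0))
    truth <- attr(camp, "truth")
    wc <- estimate_water_content(camp)
    # recovery to within quantization of Ww and Wd plus the stopping rule
    bound <- cfg$readability / min(truth$Wd_true) + 0.005
    expect_lt(abs(wc$wc_mass_mean - cfg$true_wc_mass) / cfg$true_wc_mass,
              bound)
  }
})

test_that("campaign CSV and YAML round-trip preserves the data", {
  cfg <- tissue_presets("fat", seed = 11L)
  camp <- simulate_campaigns(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_campaigns(camp, csv)
  back <- read_campaigns(csv)
  expect_equal(back$weight_g, camp$weight_g)
  expect_equal(back$volume_cm3, camp$volume_cm3, tolerance = 1e-12)
  yml <- paste0(sub("\\.csv$", "", csv), ".yaml")
  expect_true(file.exists(yml))
  cfg_back <- read_campaign_config(yml)
  expect_equal(cfg_back$seed, cfg$seed)
  expect_equal(cfg_back$schedule, cfg$schedule)
  # regenerating from the recorded config reproduces the campaign
  expect_equal(simulate_campaigns(cfg_back)$weight_g, camp$weight_g)
})
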