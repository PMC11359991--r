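test_that("percentage difference is taken relative to the reference", {
  expect_equal(percent_difference(50.98, 53.91), 5.435, tolerance = 1e-4)
  expect_equal(percent_difference(0.0760, 0.250), 69.6, tolerance = 1e-4)
  expect_equal(percent_difference(7, 7), 0)
  expect_error(percent_difference(1, 0), "non-zero")
})

test_that("embedded fixtures are complete and internally consistent", {
  wc <- tissue_water_reference()
  pars <- tissue_model_parameters()
  refs <- reference_permittivity()
  tissues <- c("muscle", "liver", "heart", "kidney", "fat")
  expect_setequal(wc$tissue, tissues)
  expect_setequal(pars$tissue, tissues)
  expect_equal(nrow(refs), 25L)
  expect_true(all(refs$eps_real_ref > 0 & refs$eps_imag_ref > 0))
  expect_true(all(table(refs$tissue) == 5L))
})

test_that("spectra comparison joins model and reference rows", {
  refs <- reference_permittivity()
  # a model identical to the reference gives all-zero deltas
  fake <- data.frame(tissue = refs$tissue,
                     frequency_hz = refs$frequency_ghz * 1e9,
                     eps_real = refs$eps_real_ref,
                     eps_imag = refs$eps_imag_ref)
  comp <- compare_spectra(fake, refs)
  expect_equal(comp$delta_real_pct, rep(0, 25))
  expect_equal(comp$delta_imag_pct, rep(0, 25))

  # single-tissue spectrum path with the published kidney spot value
  sp <- cole_cole_spectrum(cole_cole_params(4, 49.59), c(1, 3, 5, 10, 20) * 1e9)
  comp <- compare_spectra(sp, tissue = "kidney")
  expect_equal(comp$eps_real_model[comp$frequency_ghz == 5], 45.88,
               tolerance = 1e-3)

  # unknown tissue names the offender
  bad <- transform(fake, tissue = "spleen")
  expect_error(compare_spectra(bad, refs), "spleen")
  # missing frequency on the model grid
  expect_error(compare_spectra(cole_cole_spectrum(cole_cole_params(4, 49.59),
                                                  c(1, 3) * 1e9),
                               tissue = "kidney"), "GHz")
})

test_that("per-tissue maxima summarize the comparison table", {
  refs <- reference_permittivity()
  rows <- data.frame(tissue = refs$tissue, frequency_ghz = refs$frequency_ghz,
                     delta_real_pct = refs$delta_real_pct,
                     delta_imag_pct = refs$delta_imag_pct)
  mx <- max_difference_summary(rows)
  expect_equal(mx$max_delta_real_pct[mx$tissue == "heart"], 34.13)
  expect_equal(mx$max_delta_imag_pct[mx$tissue == "muscle"], 13.35)
  # single row passes through
  one <- max_difference_summary(rows[1, ])
  expect_equal(one$max_delta_real_pct, rows$delta_real_pct[1])
})

test_that("variability band brackets the central spectrum", {
  f <- c(1, 5, 10, 20) * 1e9
  vb0 <- variability_band(0.752, 0, f)
  expect_equal(vb0$half_width_real, rep(0, 4))
  expect_equal(vb0$half_width_imag, rep(0, 4))

  vb <- variability_band(0.752, 0.0522, f)
  expect_true(all(vb$lower$eps_real <= vb$central$eps_real + 1e-12))
  expect_true(all(vb$central$eps_real <= vb$upper$eps_real + 1e-12))
  # independent re-evaluation of the chain at the band edges
  up <- cole_cole_spectrum(assign_parameters(0.752 + 0.0522), f)
  lo <- cole_cole_spectrum(assign_parameters(0.752 - 0.0522), f)
  expect_equal(vb$half_width_real,
               pmax(abs(up$eps_real - vb$central$eps_real),
                    abs(lo$eps_real - vb$central$eps_real)))
  expect_equal(vb$half_width_imag,
               pmax(abs(up$eps_imag - vb$central$eps_imag),
                    abs(lo$eps_imag - vb$central$eps_imag)))

  # width is monotone non-decreasing in the uncertainty
  u <- c(0, 0.01, 0.03, 0.0522, 0.09)
  widths <- sapply(u, function(ui)
    max(variability_band(0.752, ui, f)$half_width_real))
  expect_true(all(diff(widths) >= 0))

  expect_warning(variability_band(0.052, 0.109, f), "clipped")
})
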