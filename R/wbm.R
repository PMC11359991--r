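#' Water-based dielectric model of tissue permittivity
#'
#' Builds the water-based one-pole Cole-Cole model for one or more tissues
#' directly from their water volume fractions.  Each tissue's parameters
#' follow the assignment rules of [assign_parameters()]; the resulting
#' object supports `print`, `summary`, `coef`, `predict`, `plot`,
#' `simulate` and `residuals`.
#'
#' @param wc_volume Named numeric vector of water volume fractions in
#'   `[0, 1]` (names are the tissue labels), or an unnamed vector together
#'   with `tissue`.
#' @param tissue Tissue labels, if `wc_volume` is unnamed.
#' @param wc_uncertainty Optional uncertainties of the water volume
#'   fractions (same length), used for variability bands in [plot.wbm()]
#'   and [summary.wbm()].
#' @return An object of class `"wbm"`: a list with elements `water` (the
#'   per-tissue water-content table), `params` (named list of
#'   [cole_cole_params()]) and `call`.
#' @seealso [fit_wbm()] to estimate the water content from weighing
#'   campaigns first.
#' @export
#' @examples
#' m <- wbm(c(muscle = 0.752, fat = 0.052))
#' coef(m)
#' predict(m, frequencies = c(1e9, 1e10))
wbm <- function(wc_volume, tissue = names(wc_volume), wc_uncertainty = NULL) {
  if (is.null(tissue) || any(!nzchar(tissue)))
    abort_validation("tissue labels are required (name `wc_volume` or pass `tissue`)")
  if (length(tissue) != length(wc_volume))
    abort_validation("`tissue` and `wc_volume` lengths differ")
  if (anyDuplicated(tissue))
    abort_validation("duplicated tissue labels")
  for (w in wc_volume) check_number(w, "wc_volume", lower = 0, upper = 1)
  if (is.null(wc_uncertainty)) wc_uncertainty <- rep(NA_real_, length(wc_volume))
  if (length(wc_uncertainty) != length(wc_volume))
    abort_validation("`wc_uncertainty` and `wc_volume` lengths differ")

  params <- lapply(as.numeric(wc_volume), assign_parameters)
  names(params) <- tissue
  water <- data.frame(tissue = tissue,
                      wc_vol_mean = as.numeric(wc_volume),
                      wc_vol_unc = as.numeric(wc_uncertainty),
                      stringsAsFactors = FALSE)
  structure(list(water = water, params = params, call = match.call()),
            class = "wbm")
}

#' Fit the water-based dielectric model to weighing campaigns
#'
#' Runs the complete analysis chain on dehydration weighing data: the
#' dryness stopping rule determines each sample's dry weight, per-sample
#' water contents are aggregated per tissue ([estimate_water_content()]),
#' and the per-tissue mean water volume fraction selects the Cole-Cole
#' parameters of the water-based model ([assign_parameters()]).
#'
#' @param data Campaign data frame with columns `tissue`, `sample_id`,
#'   `time_h`, `weight_g`, `volume_cm3` (the dialect written by
#'   [write_campaigns()]).
#' @inheritParams estimate_water_content
#' @return An object of class `"wbm"` whose `water` element carries the
#'   full per-tissue summary (mass and volume basis with uncertainties)
#'   and whose `params` element holds one [cole_cole_params()] per tissue.
#' @export
#' @examples
#' cfg <- campaign_config("muscle", true_wc_mass = 0.708, noise_sd = 0, seed = 1)
#' fit <- fit_wbm(simulate_campaigns(cfg))
#' summary(fit)
fit_wbm <- function(data, threshold = 0.005, readability = 0.01,
                    volume_rel_uncertainty = 0.07, rho_water = RHO_WATER) {
  water <- estimate_water_content(data, threshold = threshold,
                                  readability = readability,
                                  volume_rel_uncertainty = volume_rel_uncertainty,
                                  rho_water = rho_water)
  params <- lapply(water$wc_vol_mean, function(w)
    assign_parameters(min(max(w, 0), 1)))
  names(params) <- water$tissue
  structure(list(water = water, params = params, call = match.call(),
                 details = attr(water, "details")),
            class = "wbm")
}

#' @export
print.wbm <- function(x, ...) {
  cat("Water-based tissue permittivity model (1-pole Cole-Cole)\n")
  cat(sprintf("  tissues: %s\n", paste(x$water$tissue, collapse = ", ")))
  cc <- coef(x)
  print(cc, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.wbm <- function(object, ...) {
  data.frame(tissue = names(object$params),
             eps_inf = vapply(object$params, `[[`, 0, "eps_inf"),
             eps_s = vapply(object$params, `[[`, 0, "eps_s"),
             tau_ps = vapply(object$params, `[[`, 0, "tau") * 1e12,
             alpha = vapply(object$params, `[[`, 0, "alpha"),
             sigma_s = vapply(object$params, `[[`, 0, "sigma_s"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Predict permittivity spectra from a water-based model
#'
#' @param object A `"wbm"` object.
#' @param frequencies Frequency grid in Hz.
#' @param tissue Optional subset of tissues.
#' @param ... Unused.
#' @return A data frame with columns `tissue`, `frequency_hz`,
#'   `eps_real`, `eps_imag`.
#' @export
predict.wbm <- function(object, frequencies = default_frequency_grid(),
                        tissue = NULL, ...) {
  tissues <- tissue %||% names(object$params)
  bad <- setdiff(tissues, names(object$params))
  if (length(bad))
    abort_validation("model has no tissue(s): %s", paste(bad, collapse = ", "))
  out <- do.call(rbind, lapply(tissues, function(tt) {
    sp <- cole_cole_spectrum(object$params[[tt]], frequencies)
    cbind(tissue = tt, as.data.frame(sp))
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.wbm <- function(object, refs = NULL, ...) {
  refs <- refs %||% tryCatch(reference_permittivity(), error = function(e) NULL)
  comp <- NULL
  if (!is.null(refs) && any(object$water$tissue %in% refs$tissue)) {
    pred <- predict(object,
                    frequencies = sort(unique(refs$frequency_ghz)) * 1e9,
                    tissue = intersect(object$water$tissue, refs$tissue))
    comp <- max_difference_summary(compare_spectra(pred, refs))
  }
  structure(list(water = object$water, coef = coef(object),
                 comparison = comp, call = object$call),
            class = "summary.wbm")
}

#' @export
print.summary.wbm <- function(x, ...) {
  cat("Water-based tissue permittivity model\n\nWater content:\n")
  print(x$water, row.names = FALSE, digits = 4)
  cat("\nCole-Cole parameters:\n")
  print(x$coef, row.names = FALSE, digits = 4)
  if (!is.null(x$comparison)) {
    cat("\nMax |difference| vs literature reference (%):\n")
    print(x$comparison, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Residuals of the model against the embedded references
#'
#' Differences (model minus reference) of the real and imaginary
#' permittivity at the tabulated reference frequencies, for the tissues
#' present in both the model and the reference table.
#'
#' @param object A `"wbm"` object.
#' @param refs Reference table (default: embedded values).
#' @param ... Unused.
#' @return A data frame with columns `tissue`, `frequency_ghz`,
#'   `resid_real`, `resid_imag`, `delta_real_pct`, `delta_imag_pct`.
#' @export
residuals.wbm <- function(object, refs = reference_permittivity(), ...) {
  tissues <- intersect(object$water$tissue, refs$tissue)
  if (!length(tissues))
    abort_validation("no model tissue has reference values")
  pred <- predict(object, frequencies = sort(unique(refs$frequency_ghz)) * 1e9,
                  tissue = tissues)
  comp <- compare_spectra(pred, refs)
  data.frame(tissue = comp$tissue, frequency_ghz = comp$frequency_ghz,
             resid_real = comp$eps_real_model - comp$eps_real_ref,
             resid_imag = comp$eps_imag_model - comp$eps_imag_ref,
             delta_real_pct = comp$delta_real_pct,
             delta_imag_pct = comp$delta_imag_pct,
             stringsAsFactors = FALSE)
}

#' Simulate weighing campaigns from a fitted model
#'
#' Parametric regeneration of the dehydration experiment: for each tissue
#' of a model fitted with [fit_wbm()], a synthetic campaign is generated
#' with the tissue preset (or default configuration) whose true mass-basis
#' water content is the fitted one.
#'
#' @param object A `"wbm"` object from [fit_wbm()].
#' @param nsim Number of replicate campaign sets.
#' @param seed Integer seed; replicate `i` of tissue `k` uses
#'   `seed + i - 1` (plus a per-tissue offset).
#' @param ... Unused.
#' @return A list of `nsim` campaign data frames (rows of all tissues
#'   bound together).
#' @export
simulate.wbm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!"wc_mass_mean" %in% names(object$water))
    abort_validation(
      "simulate() needs a model fitted from weighing data (mass-basis water content)")
  presets <- tissue_presets()
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    sets <- lapply(seq_len(nrow(object$water)), function(k) {
      tt <- object$water$tissue[k]
      cfg <- if (tt %in% names(presets)) presets[[tt]]
             else campaign_config(tt, true_wc_mass = object$water$wc_mass_mean[k])
      cfg$true_wc_mass <- object$water$wc_mass_mean[k]
      if (!is.null(seed)) cfg$seed <- as.integer(seed + (i - 1L) + 1000L * k)
      simulate_campaigns(cfg)
    })
    out[[i]] <- do.call(rbind, sets)
  }
  out
}

#' Plot reconstructed permittivity spectra
#'
#' Plots the real and/or imaginary part of the reconstructed permittivity
#' over a frequency grid, one curve per tissue, with vertical uncertainty
#' bars from the water-content variability band where the model carries a
#' water-content uncertainty.
#'
#' @param x A `"wbm"` object.
#' @param part `"both"` (two panels), `"real"` or `"imag"`.
#' @param frequencies Frequency grid in Hz.
#' @param tissue Optional subset of tissues.
#' @param n_bars Number of uncertainty bars per curve.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.wbm <- function(x, part = c("both", "real", "imag"),
                     frequencies = default_frequency_grid(),
                     tissue = NULL, n_bars = 10, ...) {
  part <- match.arg(part)
  tissues <- tissue %||% names(x$params)
  pred <- predict(x, frequencies, tissue = tissues)
  f_ghz <- frequencies / 1e9
  cols <- grDevices::hcl.colors(max(3L, length(tissues)), "Dark 3")[seq_along(tissues)]

  panel <- function(col_name, ylab) {
    mat <- sapply(tissues, function(tt)
      pred[pred$tissue == tt, col_name])
    graphics::matplot(f_ghz, mat, type = "l", lty = 1, col = cols,
                      xlab = "frequency (GHz)", ylab = ylab, ...)
    has_unc <- "wc_vol_unc" %in% names(x$water)
    if (has_unc) {
      bar_f <- frequencies[unique(pmax(1, round(seq(1, length(frequencies),
                                                    length.out = n_bars))))]
      for (k in seq_along(tissues)) {
        u <- x$water$wc_vol_unc[x$water$tissue == tissues[k]]
        if (!length(u) || is.na(u) || u == 0) next
        vb <- suppressWarnings(
          variability_band(x$water$wc_vol_mean[x$water$tissue == tissues[k]],
                           u, bar_f))
        ctr <- if (col_name == "eps_real") vb$central$eps_real else vb$central$eps_imag
        hw <- if (col_name == "eps_real") vb$half_width_real else vb$half_width_imag
        graphics::arrows(bar_f / 1e9, ctr - hw, bar_f / 1e9, ctr + hw,
                         angle = 90, code = 3, length = 0.02, col = cols[k])
      }
    }
    graphics::legend("topright", legend = tissues, col = cols, lty = 1,
                     bty = "n", cex = 0.8)
  }

  if (part == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
    panel("eps_real", expression(epsilon * minute))
    panel("eps_imag", expression(epsilon * second))
  } else {
    panel(if (part == "real") "eps_real" else "eps_imag",
          if (part == "real") expression(epsilon * minute) else expression(epsilon * second))
  }
  invisible(x)
}
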