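read_fixture <- function(name, printed = FALSE) {
  path <- system.file("extdata", name, package = "aquaperm", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = if (printed) "character" else NA)
}

#' Embedded tissue water-content summary
#'
#' The measured per-tissue water contents (mass and volume basis, in %)
#' with their uncertainties and the literature volume-basis ranges, as
#' shipped with the package.  These are experimental summaries used as
#' model inputs; the package does not claim to reproduce their
#' uncertainties.
#'
#' @return A data frame with columns `tissue`, `wc_mass_pct`,
#'   `wc_mass_sd_pct`, `wc_vol_pct`, `wc_vol_unc_pct`,
#'   `literature_vol_pct`.
#' @export
tissue_water_reference <- function() read_fixture("tissue_water_content.csv")

#' Embedded water-based model parameters per tissue
#'
#' Published Cole-Cole parameters of the water-based model for the five
#' tissues (`eps_inf`, `eps_s`, `tau` in ps, `alpha`); the static
#' conductivity is zero for all of them.
#'
#' @return A data frame with one row per tissue.
#' @export
tissue_model_parameters <- function() read_fixture("tissue_model_parameters.csv")

#' Embedded reference permittivity values
#'
#' Literature reference permittivities (one-pole Cole-Cole fits evaluated
#' without the static-conductivity term) at 1, 3, 5, 10 and 20 GHz for the
#' five tissues, together with the published water-based model values and
#' percentage differences.  The without-conductivity variant is the
#' comparison baseline; full multi-pole literature fit parameters are not
#' embedded, so with-conductivity curves are only supported if the user
#' supplies parameters.
#'
#' @param printed If `TRUE`, return all numeric columns as character
#'   strings exactly as published (useful to recover the printed decimal
#'   precision).
#' @return A data frame with columns `tissue`, `frequency_ghz`,
#'   `eps_real_model`, `eps_real_ref`, `delta_real_pct`,
#'   `eps_imag_model`, `eps_imag_ref`, `delta_imag_pct`.
#' @export
reference_permittivity <- function(printed = FALSE)
  read_fixture("reference_permittivity.csv", printed = printed)

#' Percentage difference relative to a reference value
#'
#' `100 * |model - reference| / reference`, the comparison metric used in
#' the model-versus-literature tables.
#'
#' @param model_value Model value(s).
#' @param reference_value Non-zero reference value(s).
#' @return Percentage difference(s), >= 0.
#' @export
#' @examples
#' percent_difference(50.98, 53.91)  # 5.435
percent_difference <- function(model_value, reference_value) {
  if (any(reference_value == 0))
    abort_validation("`reference_value` must be non-zero")
  100 * abs(model_value - reference_value) / reference_value
}

#' Compare model spectra against reference values
#'
#' Joins model permittivity values with reference values at the tabulated
#' frequencies and computes the percentage differences for the real and
#' imaginary parts.
#'
#' @param model Either a `"permittivity_spectrum"` for a single tissue
#'   (then `tissue` must name it) or a data frame with columns `tissue`,
#'   `frequency_hz`, `eps_real`, `eps_imag` as returned by
#'   [predict.wbm()].
#' @param refs Reference table with columns `tissue`, `frequency_ghz`,
#'   `eps_real_ref`, `eps_imag_ref`; defaults to the embedded
#'   [reference_permittivity()] values.
#' @param tissue Tissue label for a single-tissue spectrum.
#' @return A data frame with one row per (tissue, frequency) and columns
#'   `tissue`, `frequency_ghz`, `eps_real_model`, `eps_real_ref`,
#'   `delta_real_pct`, `eps_imag_model`, `eps_imag_ref`,
#'   `delta_imag_pct`.  Reference frequencies must be present in the
#'   model grid (within a relative tolerance of 1e-6); a tissue present
#'   in the model but absent from the references raises an error naming
#'   it.
#' @export
compare_spectra <- function(model, refs = reference_permittivity(),
                            tissue = NULL) {
  if (inherits(model, "permittivity_spectrum")) {
    if (is.null(tissue))
      abort_validation("`tissue` must be given for a single-tissue spectrum")
    model <- cbind(tissue = tissue, as.data.frame(model))
  }
  need <- c("tissue", "frequency_hz", "eps_real", "eps_imag")
  if (!all(need %in% names(model)))
    abort_validation("`model` must have columns %s", paste(need, collapse = ", "))
  missing <- setdiff(unique(model$tissue), unique(refs$tissue))
  if (length(missing))
    abort_validation("no reference values for tissue(s): %s",
                     paste(missing, collapse = ", "))

  rows <- lapply(seq_len(nrow(refs)), function(i) {
    r <- refs[i, ]
    if (!r$tissue %in% model$tissue) return(NULL)
    sub <- model[model$tissue == r$tissue, ]
    f <- r$frequency_ghz * 1e9
    j <- which(abs(sub$frequency_hz - f) <= 1e-6 * f)
    if (!length(j))
      abort_validation("model grid for '%s' lacks the %g GHz reference frequency",
                       r$tissue, r$frequency_ghz)
    j <- j[1L]
    data.frame(tissue = r$tissue, frequency_ghz = r$frequency_ghz,
               eps_real_model = sub$eps_real[j], eps_real_ref = r$eps_real_ref,
               delta_real_pct = percent_difference(sub$eps_real[j], r$eps_real_ref),
               eps_imag_model = sub$eps_imag[j], eps_imag_ref = r$eps_imag_ref,
               delta_imag_pct = percent_difference(sub$eps_imag[j], r$eps_imag_ref),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-tissue maxima of the percentage differences
#'
#' Summarizes a comparison table to the per-tissue maximum percentage
#' difference of the real and imaginary parts over the tabulated
#' frequencies.  Note: for fat, the published running-text maximum of the
#' imaginary part (69.3%) disagrees with the published table (69.6% at
#' 1 GHz); the table is treated as authoritative here.
#'
#' @param rows A comparison table from [compare_spectra()].
#' @return A data frame with columns `tissue`, `max_delta_real_pct`,
#'   `max_delta_imag_pct`.
#' @export
max_difference_summary <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) < 1L)
    abort_validation("`rows` must be a non-empty comparison table")
  agg <- lapply(split(rows, rows$tissue), function(s)
    data.frame(tissue = s$tissue[1L],
               max_delta_real_pct = max(s$delta_real_pct),
               max_delta_imag_pct = max(s$delta_imag_pct),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg[unique(rows$tissue)])
  rownames(out) <- NULL
  out
}

#' Variability band of the reconstructed spectrum
#'
#' Propagates the uncertainty of the water volume fraction through the
#' whole reconstruction chain: the spectrum is evaluated at the mean
#' water fraction and at the mean plus/minus its uncertainty, and the
#' per-frequency band half-width is the maximum deviation from the
#' central curve, separately for the real and imaginary parts.  Bounds
#' falling outside `[0, 1]` are clipped with a warning.
#'
#' @param wc_mean Mean water volume fraction.
#' @param wc_uncertainty Uncertainty (one standard uncertainty) of the
#'   water volume fraction, >= 0.
#' @param frequencies Frequency grid in Hz.
#' @return A list of class `"variability_band"` with elements
#'   `frequencies`, `central`, `lower`, `upper` (spectra evaluated at
#'   `wc_mean`, `wc_mean - u`, `wc_mean + u`), `half_width_real`,
#'   `half_width_imag` and `wc` (the inputs).
#' @export
#' @examples
#' vb <- variability_band(0.752, 0.0522, c(1, 10, 20) * 1e9)
#' vb$half_width_real
variability_band <- function(wc_mean, wc_uncertainty,
                             frequencies = default_frequency_grid()) {
  check_number(wc_mean, "wc_mean", lower = 0, upper = 1)
  check_number(wc_uncertainty, "wc_uncertainty", lower = 0)
  lo <- wc_mean - wc_uncertainty
  hi <- wc_mean + wc_uncertainty
  if (lo < 0 || hi > 1) {
    warning("wc_mean +/- wc_uncertainty clipped to [0, 1]")
    lo <- max(lo, 0)
    hi <- min(hi, 1)
  }
  eval_at <- function(wc) cole_cole_spectrum(assign_parameters(wc), frequencies)
  central <- eval_at(wc_mean)
  lower <- eval_at(lo)
  upper <- eval_at(hi)
  structure(
    list(frequencies = frequencies, central = central,
         lower = lower, upper = upper,
         half_width_real = pmax(abs(upper$eps_real - central$eps_real),
                                abs(lower$eps_real - central$eps_real)),
         half_width_imag = pmax(abs(upper$eps_imag - central$eps_imag),
                                abs(lower$eps_imag - central$eps_imag)),
         wc = c(mean = wc_mean, uncertainty = wc_uncertainty)),
    class = "variability_band")
}

#' @export
print.variability_band <- function(x, ...) {
  cat(sprintf(
    "Variability band for wc = %.3f +/- %.3f over %d frequencies (%.3g-%.3g GHz)\n",
    x$wc["mean"], x$wc["uncertainty"], length(x$frequencies),
    min(x$frequencies) / 1e9, max(x$frequencies) / 1e9))
  cat(sprintf("  max half-width: %.3g (real), %.3g (imag)\n",
              max(x$half_width_real), max(x$half_width_imag)))
  invisible(x)
}
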