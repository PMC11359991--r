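# File-to-file pipeline stages.  Each run_* function wraps one analysis
# stage with CSV input/output so the chain can be driven from scripts or
# from the thin command-line wrapper in inst/cli/aquaperm.  Results go to
# files; progress messages go to stderr.

log_msg <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Pipeline: simulate weighing campaigns to CSV
#'
#' @param config A [campaign_config()], a list of them (e.g.
#'   [tissue_presets()]), or the path of a YAML configuration file.
#' @param out Output CSV path.
#' @param seed Optional seed overriding the configuration's.
#' @param verbose Emit progress messages to stderr.
#' @return `out`, invisibly.
#' @export
run_simulate <- function(config = tissue_presets(), out = "campaigns.csv",
                         seed = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_campaign_config(config)
  if (inherits(config, "campaign_config")) config <- list(config)
  if (!length(config) || !all(vapply(config, inherits, TRUE, "campaign_config")))
    abort_validation("`config` must be one or more campaign_config objects")
  sets <- lapply(seq_along(config), function(k) {
    cfg <- config[[k]]
    if (!is.null(seed)) cfg$seed <- as.integer(seed + k - 1L)
    log_msg(verbose, "simulating %d sample(s) of %s (seed %s)",
            cfg$n_samples, cfg$tissue_name, format(cfg$seed))
    simulate_campaigns(cfg)
  })
  all <- do.call(rbind, sets)
  attr(all, "config") <- if (length(config) == 1L) attr(sets[[1L]], "config")
  write_campaigns(all, out,
                  config_file = if (length(config) == 1L)
                    paste0(sub("\\.csv$", "", out), ".yaml") else NULL)
  invisible(out)
}

#' Pipeline: water-content summary from a campaign CSV
#'
#' @param campaigns Path of a campaign CSV (dialect of
#'   [write_campaigns()]), or a campaign data frame.
#' @param out Output CSV path for the per-tissue summary
#'   (`tissue,wc_mass_mean,wc_mass_sd,wc_vol_mean,wc_vol_unc,n_samples`).
#' @inheritParams estimate_water_content
#' @param verbose Emit progress messages to stderr.
#' @return `out`, invisibly.
#' @export
run_water_content <- function(campaigns, out = "water_content.csv",
                              threshold = 0.005, readability = 0.01,
                              volume_rel_uncertainty = 0.07,
                              verbose = FALSE) {
  if (is.character(campaigns)) campaigns <- read_campaigns(campaigns)
  wc <- estimate_water_content(campaigns, threshold = threshold,
                               readability = readability,
                               volume_rel_uncertainty = volume_rel_uncertainty)
  log_msg(verbose, "estimated water content for %d tissue(s)", nrow(wc))
  utils::write.csv(wc, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Pipeline: reconstruct permittivity spectra
#'
#' Builds the water-based model either from a water-content summary CSV
#' (as written by [run_water_content()]) or from explicitly given water
#' volume fractions, and writes the spectra on the requested grid as
#' `tissue,frequency_hz,eps_real,eps_imag`.
#'
#' @param summary Path of a summary CSV, or a named numeric vector of
#'   water volume fractions.
#' @param out Output CSV path.
#' @param frequencies Frequency grid in Hz.
#' @param verbose Emit progress messages to stderr.
#' @return `out`, invisibly.
#' @export
run_reconstruct <- function(summary, out = "spectra.csv",
                            frequencies = default_frequency_grid(),
                            verbose = FALSE) {
  model <- if (is.character(summary)) {
    df <- utils::read.csv(summary, stringsAsFactors = FALSE)
    if (!all(c("tissue", "wc_vol_mean") %in% names(df)))
      abort_validation("summary CSV needs columns tissue, wc_vol_mean")
    wbm(stats::setNames(df$wc_vol_mean, df$tissue),
        wc_uncertainty = if ("wc_vol_unc" %in% names(df)) df$wc_vol_unc)
  } else {
    wbm(summary)
  }
  if (verbose)
    for (tt in names(model$params))
      log_msg(TRUE, "%s: eps_inf = %g, eps_s = %.4g", tt,
              model$params[[tt]]$eps_inf, model$params[[tt]]$eps_s)
  pred <- predict(model, frequencies)
  utils::write.csv(pred, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Pipeline: compare spectra against the embedded references
#'
#' @param spectra Path of a spectrum CSV
#'   (`tissue,frequency_hz,eps_real,eps_imag`) or such a data frame.
#' @param out Output CSV path for the comparison report
#'   (`tissue,frequency_ghz,eps_real_model,eps_real_ref,delta_real_pct,eps_imag_model,eps_imag_ref,delta_imag_pct`).
#' @param refs Reference table (default: embedded values).
#' @param verbose Emit progress messages to stderr.
#' @return `out`, invisibly.
#' @export
run_compare <- function(spectra, out = "comparison.csv",
                        refs = reference_permittivity(), verbose = FALSE) {
  if (is.character(spectra))
    spectra <- utils::read.csv(spectra, stringsAsFactors = FALSE)
  comp <- compare_spectra(spectra, refs)
  log_msg(verbose, "compared %d (tissue, frequency) points", nrow(comp))
  utils::write.csv(comp, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Read and write tissue Cole-Cole parameters as YAML
#'
#' Serializes the per-tissue water-based model parameters
#' (`eps_inf`, `eps_s`, `tau_ps`, `alpha`, `sigma_s`) to a YAML file, and
#' reads such a file back into a parameter table.
#'
#' @param object A `"wbm"` object or a data frame shaped like [coef.wbm()].
#' @param file Path of the YAML file.
#' @return `write_model_parameters()` invisibly returns `file`;
#'   `read_model_parameters()` returns a data frame with one row per
#'   tissue.
#' @export
write_model_parameters <- function(object, file) {
  cc <- if (inherits(object, "wbm")) coef(object) else object
  need <- c("tissue", "eps_inf", "eps_s", "tau_ps", "alpha")
  if (!all(need %in% names(cc)))
    abort_validation("`object` must provide columns %s", paste(need, collapse = ", "))
  if (!"sigma_s" %in% names(cc)) cc$sigma_s <- 0
  entries <- lapply(seq_len(nrow(cc)), function(i)
    as.list(cc[i, c("eps_inf", "eps_s", "tau_ps", "alpha", "sigma_s")]))
  names(entries) <- cc$tissue
  yaml::write_yaml(entries, file)
  invisible(file)
}

#' @rdname write_model_parameters
#' @export
read_model_parameters <- function(file) {
  y <- yaml::read_yaml(file)
  out <- do.call(rbind, lapply(names(y), function(nm)
    data.frame(tissue = nm, eps_inf = y[[nm]]$eps_inf, eps_s = y[[nm]]$eps_s,
               tau_ps = y[[nm]]$tau_ps, alpha = y[[nm]]$alpha,
               sigma_s = y[[nm]]$sigma_s %||% 0, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
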